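# Small neural-net primitives shared by the graph autoencoder and the GAN.
# All training here is full-batch, hand-differentiated matrix algebra.

leaky_relu <- function(x, slope = 0.2) {
  pos <- x > 0
  x * (pos + slope * !pos)
}

leaky_relu_grad <- function(pre, slope = 0.2) {
  pos <- pre > 0
  pos + slope * !pos
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax with max-shift for stability
softmax_rows <- function(logits) {
  logits <- as.matrix(logits)
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# mean cross-entropy of row-softmax(logits) against integer labels in 0..K-1
cross_entropy <- function(logits, labels) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(nrow(p)), as.integer(labels) + 1L)
  if (any(labels < 0 | labels >= ncol(p)))
    stop("labels must lie in 0..K-1 with K = ", ncol(p))
  -mean(log(pmax(p[idx], 1e-12)))
}

# Gaussian init scaled by fan-in (He-style, suits leaky rectifiers)
init_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stepped learning-rate decay: lr0 * factor^floor(epoch / every), epoch 0-based.
scheduled_lr <- function(lr0, epoch, every = 5, factor = 0.5) {
  if (every < 1) stop("`every` must be >= 1")
  lr0 * factor^(epoch %/% every)
}

# run body with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  body
}
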