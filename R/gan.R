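#' Auxiliary-classifier GAN configuration
#'
#' The generator concatenates a high-confidence cell embedding with a noise
#' vector and maps it through fully connected layers of widths 1024, 512 and
#' 256 (leaky rectification, slope 0.2, after each) into a tanh output of the
#' embedding dimension. The discriminator shares a small trunk and carries
#' two heads: a logistic real/fake probability and K class logits. Both are
#' trained with Adam, halving the learning rate every `lr_halve_every`
#' epochs.
#'
#' @param noise_dim noise vector length; `NULL` (default) means "equal to the
#'   embedding dimension d".
#' @param hidden_dims_g generator hidden widths, strictly decreasing;
#'   default `c(1024, 512, 256)`.
#' @param hidden_dims_d discriminator trunk widths; default `c(256, 128)`.
#' @param leaky_slope negative slope of the leaky rectifier (default 0.2).
#' @param epochs training epochs (default 50).
#' @param learning_rate initial Adam learning rate (default 5e-3).
#' @param lr_halve_every epochs between learning-rate halvings (default 5).
#' @param adam_betas Adam moment decay pair (default `c(0.5, 0.999)`).
#' @param batch_size cap on samples per update; the full confidence set is
#'   used when it fits (default 1024).
#' @param seed RNG seed for weight init and noise draws.
#' @return a `gan_config` list.
#' @export
gan_config <- function(noise_dim = NULL, hidden_dims_g = c(1024, 512, 256),
                       hidden_dims_d = c(256, 128), leaky_slope = 0.2,
                       epochs = 50, learning_rate = 5e-3, lr_halve_every = 5,
                       adam_betas = c(0.5, 0.999), batch_size = 1024,
                       seed = 1) {
  if (any(diff(hidden_dims_g) >= 0))
    stop("`hidden_dims_g` must be strictly decreasing")
  if (lr_halve_every < 1) stop("`lr_halve_every` must be >= 1")
  if (epochs < 1) stop("`epochs` must be >= 1")
  structure(list(noise_dim = noise_dim, hidden_dims_g = as.integer(hidden_dims_g),
                 hidden_dims_d = as.integer(hidden_dims_d),
                 leaky_slope = leaky_slope, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 lr_halve_every = as.integer(lr_halve_every),
                 adam_betas = adam_betas, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "gan_config")
}

gan_init_params <- function(d, K, cfg) {
  nd <- if (is.null(cfg$noise_dim)) d else as.integer(cfg$noise_dim)
  gdims <- c(d + nd, cfg$hidden_dims_g, d)
  gen <- list()
  for (l in seq_len(length(gdims) - 1)) {
    gen[[paste0("W", l)]] <- init_weight(gdims[l], gdims[l + 1])
    gen[[paste0("b", l)]] <- rep(0, gdims[l + 1])
  }
  ddims <- c(d, cfg$hidden_dims_d)
  disc <- list()
  for (l in seq_len(length(ddims) - 1)) {
    disc[[paste0("W", l)]] <- init_weight(ddims[l], ddims[l + 1])
    disc[[paste0("b", l)]] <- rep(0, ddims[l + 1])
  }
  top <- utils::tail(ddims, 1)
  disc$Wa <- init_weight(top, 1)
  disc$ba <- 0
  disc$Wc <- init_weight(top, K)
  disc$bc <- rep(0, K)
  list(gen = gen, disc = disc, noise_dim = nd, d = d, K = K)
}

#' Generator forward pass
#'
#' Concatenates conditioning embeddings with noise and maps them through the
#' 1024/512/256 leaky-rectified stack into a tanh-bounded pseudo-cell
#' embedding; every output entry lies in `[-1, 1]`.
#'
#' @param x_real conditioning matrix (batch x d) or a single d-vector.
#' @param z noise matrix (batch x noise_dim) or vector.
#' @param params a parameter set from [gan_init_params()]/[train_gan()].
#' @param cfg a [gan_config()].
#' @param cache keep intermediates for backprop (internal).
#' @return generated matrix (batch x d), or with `cache = TRUE` a list.
#' @export
generator_forward <- function(x_real, z, params, cfg = gan_config(),
                              cache = FALSE) {
  if (is.null(dim(x_real))) x_real <- matrix(x_real, nrow = 1)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!all(is.finite(x_real)) || !all(is.finite(z)))
    stop("non-finite generator input")
  gen <- params$gen
  inp <- cbind(x_real, z)
  nl <- length(cfg$hidden_dims_g) + 1L
  pres <- vector("list", nl); acts <- vector("list", nl)
  cur <- inp
  for (l in seq_len(nl)) {
    pre <- sweep(cur %*% gen[[paste0("W", l)]], 2, gen[[paste0("b", l)]], `+`)
    cur <- if (l < nl) leaky_relu(pre, cfg$leaky_slope) else tanh(pre)
    pres[[l]] <- pre; acts[[l]] <- cur
  }
  if (!cache) return(cur)
  list(out = cur, input = inp, pres = pres, acts = acts)
}

#' Discriminator forward pass
#'
#' Shared leaky-rectified trunk with two heads: `adv_prob`, the logistic
#' probability that the input is a real cell embedding, and `class_logits`,
#' K-way class scores.
#'
#' @param x input matrix (batch x d) or a single d-vector.
#' @param params parameter set from [gan_init_params()]/[train_gan()].
#' @param cfg a [gan_config()].
#' @param cache keep intermediates for backprop (internal).
#' @return list with `adv_prob` (vector, strictly inside (0,1)) and
#'   `class_logits` (batch x K matrix).
#' @export
discriminator_forward <- function(x, params, cfg = gan_config(), cache = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite discriminator input")
  disc <- params$disc
  nl <- length(cfg$hidden_dims_d)
  pres <- vector("list", nl); acts <- vector("list", nl)
  cur <- x
  for (l in seq_len(nl)) {
    pre <- sweep(cur %*% disc[[paste0("W", l)]], 2, disc[[paste0("b", l)]], `+`)
    cur <- leaky_relu(pre, cfg$leaky_slope)
    pres[[l]] <- pre; acts[[l]] <- cur
  }
  a <- drop(cur %*% disc$Wa) + disc$ba
  p <- sigmoid(a)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  logits <- sweep(cur %*% disc$Wc, 2, disc$bc, `+`)
  out <- list(adv_prob = p, class_logits = logits)
  if (cache) out <- c(out, list(input = x, pres = pres, acts = acts, a = a))
  out
}

#' Discriminator loss
#'
#' Batch-mean realization of the adversarial + auxiliary-classification
#' objective: `mean(-log p_real) + mean(-log(1 - p_fake)) +
#' mean(CE(class_logits_real, y_real))`.
#'
#' @param adv_real discriminator real/fake probabilities on the real batch.
#' @param adv_fake probabilities on the generated batch.
#' @param class_logits_real class logits on the real batch (batch x K).
#' @param y_real 0-based class labels of the real batch.
#' @return nonnegative scalar.
#' @export
discriminator_loss <- function(adv_real, adv_fake, class_logits_real, y_real) {
  if (length(adv_real) == 0 || length(adv_fake) == 0) stop("empty batch")
  -mean(log(adv_real)) - mean(log(1 - adv_fake)) +
    cross_entropy(class_logits_real, y_real)
}

#' Generator loss
#'
#' Non-saturating adversarial term plus classification of the generated
#' samples against their conditioning labels:
#' `mean(-log p_fake) + mean(CE(class_logits_fake, y_fake))`.
#'
#' @param adv_fake discriminator probabilities on the generated batch.
#' @param class_logits_fake class logits on the generated batch.
#' @param y_fake 0-based target labels (the conditioning cells' labels).
#' @return scalar.
#' @export
generator_loss <- function(adv_fake, class_logits_fake, y_fake) {
  if (length(adv_fake) == 0) stop("empty batch")
  -mean(log(adv_fake)) + cross_entropy(class_logits_fake, y_fake)
}

# backprop of head gradients through the discriminator trunk.
# dtop: gradient at the trunk output; returns param grads (suffixed by batch)
# and the gradient at the input.
disc_trunk_backward <- function(dtop, fwcache, params, cfg) {
  disc <- params$disc
  nl <- length(cfg$hidden_dims_d)
  grads <- list()
  dcur <- dtop
  for (l in rev(seq_len(nl))) {
    dpre <- dcur * leaky_relu_grad(fwcache$pres[[l]], cfg$leaky_slope)
    below <- if (l == 1) fwcache$input else fwcache$acts[[l - 1]]
    grads[[paste0("W", l)]] <- crossprod(below, dpre)
    grads[[paste0("b", l)]] <- colSums(dpre)
    dcur <- tcrossprod(dpre, disc[[paste0("W", l)]])
  }
  list(grads = grads, dinput = dcur)
}

# combine adversarial and class head gradients into trunk-output gradient
disc_head_backward <- function(fwcache, params, da, dlogits) {
  top <- fwcache$acts[[length(fwcache$acts)]]
  grads <- list()
  dtop <- matrix(0, nrow(top), ncol(top))
  if (!is.null(da)) {
    grads$Wa <- crossprod(top, matrix(da, ncol = 1))
    grads$ba <- sum(da)
    dtop <- dtop + matrix(da, ncol = 1) %*% t(params$disc$Wa)
  }
  if (!is.null(dlogits)) {
    grads$Wc <- crossprod(top, dlogits)
    grads$bc <- colSums(dlogits)
    dtop <- dtop + tcrossprod(dlogits, params$disc$Wc)
  }
  list(grads = grads, dtop = dtop)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# min-max rescale of embeddings to [-1, 1] per dimension so real samples
# share the generator's tanh-bounded support
embedding_scale <- function(z_ref) {
  list(mins = apply(z_ref, 2, min), maxs = apply(z_ref, 2, max))
}

apply_embedding_scale <- function(z, scale) {
  rng <- scale$maxs - scale$mins
  rng[rng == 0] <- 1
  out <- sweep(sweep(z, 2, scale$mins), 2, rng, `/`) * 2 - 1
  out[, scale$maxs == scale$mins] <- 0
  out
}

#' Train the auxiliary-classifier GAN on high-confidence cells
#'
#' Alternates one discriminator update and one generator update per epoch
#' (full batch when the confidence set fits `cfg$batch_size`) under Adam,
#' halving the learning rate every `cfg$lr_halve_every` epochs. Real samples
#' are the confidence-set embeddings rescaled per dimension to `[-1, 1]`
#' (matching the generator's tanh range); the rescaling is stored in the
#' returned model and re-applied by [relabel_all()].
#'
#' @param conf a [select_high_confidence()] result covering all K classes.
#' @param K number of classes.
#' @param cfg a [gan_config()].
#' @param scale_reference optional embedding matrix from which the `[-1, 1]`
#'   rescaling is computed (typically all cell embeddings); defaults to the
#'   confidence set itself.
#' @return a `gan_model`: list with `params` (gen + disc weights), `scale`,
#'   `K`, `cfg`, `loss_d`, `loss_g` (per-epoch traces).
#' @export
train_gan <- function(conf, K, cfg = gan_config(), scale_reference = NULL) {
  stopifnot(inherits(conf, "ConfidenceSet"), inherits(cfg, "gan_config"))
  K <- as.integer(K)
  present <- sort(unique(conf$y_real))
  missing_cls <- setdiff(seq_len(K) - 1L, present)
  if (length(missing_cls) > 0)
    stop("confidence set has no cells for class(es): ",
         paste(missing_cls, collapse = ", "))
  d <- ncol(conf$x_real)
  ref <- if (is.null(scale_reference)) conf$x_real else as.matrix(scale_reference)
  scale <- embedding_scale(ref)
  x_all <- apply_embedding_scale(conf$x_real, scale)
  y_all <- as.integer(conf$y_real)
  n <- nrow(x_all)
  with_seed(cfg$seed, {
    params <- gan_init_params(d, K, cfg)
    st_d <- adam_init(params$disc)
    st_g <- adam_init(params$gen)
    b1 <- cfg$adam_betas[1]; b2 <- cfg$adam_betas[2]
    loss_d <- numeric(cfg$epochs); loss_g <- numeric(cfg$epochs)
    for (e in seq_len(cfg$epochs)) {
      lr <- scheduled_lr(cfg$learning_rate, e - 1L, cfg$lr_halve_every)
      idx <- if (n <= cfg$batch_size) seq_len(n) else sample.int(n, cfg$batch_size)
      xb <- x_all[idx, , drop = FALSE]
      yb <- y_all[idx]
      B <- length(idx)

      # --- discriminator update ---
      z <- matrix(stats::rnorm(B * params$noise_dim), B)
      fake <- generator_forward(xb, z, params, cfg)
      fw_r <- discriminator_forward(xb, params, cfg, cache = TRUE)
      fw_f <- discriminator_forward(fake, params, cfg, cache = TRUE)
      loss_d[e] <- discriminator_loss(fw_r$adv_prob, fw_f$adv_prob,
                                      fw_r$class_logits, yb)
      if (!is.finite(loss_d[e]))
        stop("discriminator loss non-finite at epoch ", e)
      onehot <- diag(K)[yb + 1L, , drop = FALSE]
      da_r <- (fw_r$adv_prob - 1) / B
      dlog_r <- (softmax_rows(fw_r$class_logits) - onehot) / B
      hb_r <- disc_head_backward(fw_r, params, da_r, dlog_r)
      tb_r <- disc_trunk_backward(hb_r$dtop, fw_r, params, cfg)
      da_f <- fw_f$adv_prob / B
      hb_f <- disc_head_backward(fw_f, params, da_f, NULL)
      tb_f <- disc_trunk_backward(hb_f$dtop, fw_f, params, cfg)
      gd <- add_grads(add_grads(hb_r$grads, tb_r$grads),
                      add_grads(hb_f$grads, tb_f$grads))
      up <- adam_step(params$disc, gd, st_d, lr, b1, b2)
      params$disc <- up$params; st_d <- up$state

      # --- generator update (fresh noise, discriminator frozen) ---
      z2 <- matrix(stats::rnorm(B * params$noise_dim), B)
      gcache <- generator_forward(xb, z2, params, cfg, cache = TRUE)
      fw_g <- discriminator_forward(gcache$out, params, cfg, cache = TRUE)
      loss_g[e] <- generator_loss(fw_g$adv_prob, fw_g$class_logits, yb)
      if (!is.finite(loss_g[e]))
        stop("generator loss non-finite at epoch ", e)
      da_g <- (fw_g$adv_prob - 1) / B
      dlog_g <- (softmax_rows(fw_g$class_logits) - onehot) / B
      hb_g <- disc_head_backward(fw_g, params, da_g, dlog_g)
      tb_g <- disc_trunk_backward(hb_g$dtop, fw_g, params, cfg)
      dx_fake <- tb_g$dinput
      nl <- length(cfg$hidden_dims_g) + 1L
      gg <- list()
      dcur <- dx_fake * (1 - gcache$acts[[nl]]^2) # tanh'
      for (l in rev(seq_len(nl))) {
        if (l < nl)
          dcur <- dcur * leaky_relu_grad(gcache$pres[[l]], cfg$leaky_slope)
        below <- if (l == 1) gcache$input else gcache$acts[[l - 1]]
        gg[[paste0("W", l)]] <- crossprod(below, dcur)
        gg[[paste0("b", l)]] <- colSums(dcur)
        if (l > 1) dcur <- tcrossprod(dcur, params$gen[[paste0("W", l)]])
      }
      up <- adam_step(params$gen, gg, st_g, lr, b1, b2)
      params$gen <- up$params; st_g <- up$state
    }
    structure(list(params = params, scale = scale, K = K, cfg = cfg,
                   loss_d = loss_d, loss_g = loss_g),
              class = "gan_model")
  })
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("gan_model: d = %d, K = %d, %d epochs (final D loss %.4f, G loss %.4f)\n",
              x$params$d, x$K, x$cfg$epochs,
              utils::tail(x$loss_d, 1), utils::tail(x$loss_g, 1)))
  invisible(x)
}

#' Re-label every cell with the discriminator's class head
#'
#' Applies the trained discriminator's classification head to all cell
#' embeddings (after the model's stored `[-1, 1]` rescaling) and assigns
#' each cell the argmax class; exact ties resolve to the lower class index.
#'
#' @param z_cells cell embedding matrix (n x d) or an `EmbeddingMatrix`.
#' @param model a [train_gan()] result.
#' @return a `RefinedAssignment`: list with `labels` (0-based, length n) and
#'   `class_probabilities` (n x K, rows sum to 1).
#' @export
relabel_all <- function(z_cells, model) {
  stopifnot(inherits(model, "gan_model"))
  if (inherits(z_cells, "EmbeddingMatrix"))
    z_cells <- z_cells$Z[seq_len(z_cells$n_cells), , drop = FALSE]
  z_cells <- as.matrix(z_cells)
  x <- apply_embedding_scale(z_cells, model$scale)
  fw <- discriminator_forward(x, model$params, model$cfg)
  probs <- softmax_rows(fw$class_logits)
  labels <- max.col(probs, ties.method = "first") - 1L
  structure(list(labels = as.integer(labels), class_probabilities = probs),
            class = "RefinedAssignment")
}

#' @export
print.RefinedAssignment <- function(x, ...) {
  cat(sprintf("RefinedAssignment: %d cells, %d classes\n",
              length(x$labels), ncol(x$class_probabilities)))
  invisible(x)
}
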