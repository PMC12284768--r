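test_that("a single identity-like layer reduces to the pointwise nonlinearity", {
  h <- 4
  cfg <- gae_config(layer_dims = h, batch_norm = FALSE, decoder_layer = FALSE,
                    epochs = 1, seed = 1)
  params <- list(W1 = diag(h))
  x <- matrix(rnorm(6 * h), 6)
  z <- gae_encode(diag(6), x, params, cfg)
  expect_equal(z$Z, gaeclust:::leaky_relu(x, 0.2), tolerance = 1e-12)
  # slope 0.2: a pre-activation of -1 maps to -0.2
  expect_equal(gaeclust:::leaky_relu(-1, 0.2), -0.2)
})

test_that("the encoder matches an unfused per-layer reference on a toy graph", {
  set.seed(21)
  N <- 6; h <- 3
  A <- matrix(runif(N * N), N)
  x <- matrix(rnorm(N * h), N)
  cfg <- gae_config(layer_dims = c(5, 2), epochs = 1, seed = 2)
  params <- gaeclust:::with_seed(2, gaeclust:::gae_init_params(h, cfg))

  # straight-line reference: explicit loops, no fused ops
  ref <- x
  for (l in 1:2) {
    W <- params[[paste0("W", l)]]
    U <- matrix(0, N, ncol(W))
    for (i in 1:N) for (j in seq_len(ncol(W))) {
      s <- 0
      for (t in 1:N) for (q in seq_len(nrow(W)))
        s <- s + A[i, t] * ref[t, q] * W[q, j]
      U[i, j] <- s
    }
    V <- matrix(0, N, ncol(W))
    for (i in seq_along(U)) V[i] <- if (U[i] > 0) U[i] else 0.2 * U[i]
    out <- V
    for (j in seq_len(ncol(V))) {
      mu <- mean(V[, j]); va <- mean((V[, j] - mu)^2)
      out[, j] <- params[[paste0("gamma", l)]][j] *
        (V[, j] - mu) / sqrt(va + cfg$bn_eps) + params[[paste0("beta", l)]][j]
    }
    ref <- out
  }
  z <- gae_encode(A, x, params, cfg)
  expect_equal(z$Z, ref, tolerance = 1e-8)
})

test_that("the inner-product decoder is a symmetric logistic map", {
  expect_equal(decode_adjacency(matrix(0, 4, 2)), matrix(0.5, 4, 4))
  set.seed(3)
  z <- matrix(rnorm(10), 5, 2)
  ahat <- decode_adjacency(z)
  expect_equal(ahat, t(ahat))
  expect_true(all(ahat > 0 & ahat < 1))
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    ref[i, j] <- 1 / (1 + exp(-sum(z[i, ] * z[j, ])))
  expect_equal(ahat, ref, tolerance = 1e-12)
})

test_that("reconstruction loss is the Frobenius norm of the residual", {
  a <- matrix(rnorm(64), 8)
  expect_equal(reconstruction_loss(a, a), 0)
  ahat <- a; ahat[3, 5] <- a[3, 5] - 3
  expect_equal(reconstruction_loss(a, ahat), 3)
  set.seed(4)
  b <- matrix(rnorm(64), 8)
  s <- 0
  for (i in 1:8) for (j in 1:8) s <- s + (a[i, j] - b[i, j])^2
  expect_equal(reconstruction_loss(a, b), sqrt(s), tolerance = 1e-12)
  expect_error(reconstruction_loss(a, b[1:4, ]), "shape")
  # invariant under right-multiplication of Z by an orthogonal matrix
  z <- matrix(rnorm(8 * 3), 8)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(reconstruction_loss(a, decode_adjacency(z)),
               reconstruction_loss(a, decode_adjacency(z %*% q)),
               tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  N <- 9; h <- 3
  A <- matrix(runif(N * N), N)
  x <- matrix(rnorm(N * h), N)
  cfg <- gae_config(layer_dims = c(4, 2), epochs = 1, seed = 1)
  params <- gaeclust:::with_seed(1, gaeclust:::gae_init_params(h, cfg))
  lossfun <- function(p) {
    fw <- gaeclust:::gae_forward(A, x, p, cfg, cache = TRUE)
    proj <- gaeclust:::gae_project(fw$Z, p, cfg, cache = TRUE)
    reconstruction_loss(A, decode_adjacency(proj$Zd))
  }
  fw <- gaeclust:::gae_forward(A, x, params, cfg, cache = TRUE)
  proj <- gaeclust:::gae_project(fw$Z, params, cfg, cache = TRUE)
  bk <- gaeclust:::gae_backward(A, fw, proj, params, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    g <- bk$grads[[nm]]
    for (i in seq_len(min(length(params[[nm]]), 4))) {
      p <- params
      p[[nm]][i] <- params[[nm]][i] + eps; up <- lossfun(p)
      p[[nm]][i] <- params[[nm]][i] - eps; dn <- lossfun(p)
      fd <- (up - dn) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(1e-8, abs(fd) + abs(g[i])), 1e-5)
    }
  }
})

test_that("training reduces the reconstruction loss deterministically", {
  sim <- tiny_sim(seed = 31, n_cells = 20, n_genes = 30)
  g <- build_pathway_graph(preprocess(sim$expression), h = 10, k = 3)
  cfg <- gae_config(layer_dims = c(16, 4), epochs = 100, seed = 5)
  fit <- train_gae(g$adjacency, g$features, cfg)
  expect_length(fit$loss_trace, 100)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])
  expect_true(all(is.finite(fit$embedding$Z)))
  expect_equal(fit$embedding$n_cells, 20)

  fit2 <- train_gae(g$adjacency, g$features, cfg)
  expect_equal(fit$loss_trace, fit2$loss_trace, tolerance = 1e-6)
  expect_equal(fit$embedding$Z, fit2$embedding$Z)

  expect_error(gae_config(epochs = 0), "epochs")
})

test_that("k-means on separated embeddings recovers the planted partition", {
  blobs <- make_blobs(15, K = 3, d = 4, sep = 6, sd = 0.3, seed = 17)
  cl <- initial_clusters(blobs$z, 3, seed = 1)
  expect_equal(adjusted_rand_index(blobs$labels, cl$labels), 1)
  # centroids are the member means
  for (k in 0:2)
    expect_equal(cl$centroids[k + 1, ], colMeans(blobs$z[cl$labels == k, ]),
                 tolerance = 1e-9)
  # K = n: every cell its own cluster
  zsmall <- matrix(rnorm(12), 6, 2)
  own <- initial_clusters(zsmall, 6, seed = 2)
  expect_equal(sort(own$labels), 0:5)
  # determinism and the K guard
  expect_identical(cl$labels, initial_clusters(blobs$z, 3, seed = 1)$labels)
  expect_error(initial_clusters(zsmall, 7, seed = 1), "K")
})
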