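small_cfg <- function(epochs = 5, ...) {
  gan_config(hidden_dims_g = c(16, 12, 8), hidden_dims_d = c(10, 6),
             epochs = epochs, seed = 1, ...)
}

test_that("the generator maps through a 1024-wide first layer into [-1, 1]", {
  d <- 32
  cfg <- gan_config(seed = 3)
  params <- gaeclust:::with_seed(3, gaeclust:::gan_init_params(d, 4, cfg))
  expect_equal(dim(params$gen$W1), c(2L * d, 1024L))
  x <- matrix(rnorm(5 * d), 5)
  z <- matrix(rnorm(5 * d), 5)
  fw <- generator_forward(x, z, params, cfg, cache = TRUE)
  expect_equal(ncol(fw$acts[[1]]), 1024L)
  expect_equal(dim(fw$out), c(5L, d))

  # tanh clamps even extreme inputs into [-1, 1]
  ext <- generator_forward(matrix(1e6, 2, d), matrix(-1e6, 2, d), params, cfg)
  expect_true(all(ext >= -1 & ext <= 1))
  out <- generator_forward(x, z, params, cfg)
  expect_true(all(out > -1 & out < 1))
  # pure function: identical calls give identical outputs
  expect_identical(out, generator_forward(x, z, params, cfg))
  expect_error(generator_forward(x * NA, z, params, cfg), "non-finite")
})

test_that("the discriminator exposes a calibrated adversarial head", {
  cfg <- small_cfg()
  params <- gaeclust:::with_seed(4, gaeclust:::gan_init_params(6, 3, cfg))
  # zero input with zero-initialized biases: trunk outputs zero, sigma(0) = 0.5
  fw0 <- discriminator_forward(rep(0, 6), params, cfg)
  expect_equal(unname(fw0$adv_prob), 0.5)
  x <- matrix(rnorm(5 * 6), 5)
  fw <- discriminator_forward(x, params, cfg)
  expect_true(all(fw$adv_prob > 0 & fw$adv_prob < 1))
  expect_equal(rowSums(gaeclust:::softmax_rows(fw$class_logits)), rep(1, 5),
               tolerance = 1e-9)
  # batch of 5 equals 5 single-row calls
  for (i in 1:5) {
    one <- discriminator_forward(x[i, ], params, cfg)
    expect_equal(unname(one$adv_prob), unname(fw$adv_prob[i]), tolerance = 1e-12)
    expect_equal(as.vector(one$class_logits), as.vector(fw$class_logits[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("losses reproduce closed-form values and scalar-loop oracles", {
  # near-perfect discriminator: loss approaches zero
  big <- cbind(1e3, -1e3)
  expect_lt(discriminator_loss(rep(1 - 1e-12, 4), rep(1e-12, 4),
                               rbind(big, big, big, big), rep(0L, 4)), 1e-6)
  # fully fooled discriminator with correct classes: generator loss -> 0
  expect_lt(generator_loss(rep(1 - 1e-12, 4), rbind(big, big, big, big),
                           rep(0L, 4)), 1e-6)

  # uniform-posterior worked values
  expect_equal(discriminator_loss(rep(0.5, 6), rep(0.5, 6),
                                  matrix(0, 6, 2), rep(0:1, 3)),
               2 * log(2) + log(2), tolerance = 1e-12)
  expect_equal(generator_loss(rep(0.5, 8), matrix(0, 8, 4),
                              rep(0:3, 2)),
               log(2) + log(4), tolerance = 1e-12)

  # random batches match an unvectorized evaluation of the expectations
  set.seed(12)
  for (rep in 1:5) {
    B <- sample(2:16, 1); K <- sample(2:5, 1)
    pr <- runif(B, 0.01, 0.99); pf <- runif(B, 0.01, 0.99)
    lg <- matrix(rnorm(B * K), B)
    y <- sample(0:(K - 1), B, replace = TRUE)
    sd_ <- 0; sce <- 0; sg <- 0
    for (i in 1:B) {
      sd_ <- sd_ - log(pr[i]) / B - log(1 - pf[i]) / B
      pcls <- exp(lg[i, ]) / sum(exp(lg[i, ]))
      sce <- sce - log(pcls[y[i] + 1]) / B
      sg <- sg - log(pf[i]) / B
    }
    expect_equal(discriminator_loss(pr, pf, lg, y), sd_ + sce, tolerance = 1e-8)
    expect_equal(generator_loss(pf, lg, y), sg + sce, tolerance = 1e-8)
  }
  expect_error(discriminator_loss(numeric(0), numeric(0),
                                  matrix(0, 0, 2), integer(0)), "empty")
  expect_error(discriminator_loss(0.5, 0.5, matrix(0, 1, 2), 5L), "labels")
})

test_that("the learning-rate schedule halves every five epochs", {
  lr0 <- 2e-4
  # epoch 10 onset: two halvings down to 5e-5
  expect_equal(gaeclust:::scheduled_lr(lr0, 10, every = 5), 5e-5)
  lrs <- vapply(0:24, function(e) gaeclust:::scheduled_lr(lr0, e, 5), numeric(1))
  expect_true(all(diff(lrs) <= 0))
  expect_equal(unique(lrs), lr0 * 0.5^(0:4))
  expect_equal(which(diff(lrs) < 0), c(5, 10, 15, 20))
})

test_that("gan training is seeded, supervised and classification improves", {
  blobs <- make_blobs(20, K = 3, d = 4, sep = 8, sd = 0.4, seed = 23)
  a <- initial_clusters(blobs$z, 3, seed = 1)
  conf <- select_high_confidence(blobs$z, a, 0.5)
  cfg <- small_cfg(epochs = 50)
  m1 <- train_gan(conf, 3, cfg, scale_reference = blobs$z)
  m2 <- train_gan(conf, 3, cfg, scale_reference = blobs$z)
  expect_equal(m1$loss_d, m2$loss_d, tolerance = 1e-6)
  expect_equal(m1$loss_g, m2$loss_g, tolerance = 1e-6)

  # classification of the real samples improves over training
  x_scaled <- gaeclust:::apply_embedding_scale(conf$x_real, m1$scale)
  params0 <- gaeclust:::with_seed(cfg$seed,
                                  gaeclust:::gan_init_params(4, 3, cfg))
  ce0 <- gaeclust:::cross_entropy(
    discriminator_forward(x_scaled, params0, cfg)$class_logits, conf$y_real)
  ce1 <- gaeclust:::cross_entropy(
    discriminator_forward(x_scaled, m1$params, cfg)$class_logits, conf$y_real)
  expect_lt(ce1, ce0)

  # a class missing from the confidence set is an error
  conf_bad <- conf
  conf_bad$y_real[conf_bad$y_real == 2L] <- 1L
  expect_error(train_gan(conf_bad, 3, cfg), "class")
  expect_error(gan_config(hidden_dims_g = c(8, 16, 4)), "decreasing")
})

test_that("relabeling scores all cells and breaks ties to the lower class", {
  blobs <- make_blobs(20, K = 3, d = 4, sep = 8, sd = 0.4, seed = 29)
  a <- initial_clusters(blobs$z, 3, seed = 1)
  conf <- select_high_confidence(blobs$z, a, 0.5)
  # the deliberately small test net needs a coarser step to converge in
  # 50 full-batch updates
  model <- train_gan(conf, 3, small_cfg(epochs = 50, learning_rate = 2e-2),
                     scale_reference = blobs$z)
  ref <- relabel_all(blobs$z, model)
  expect_length(ref$labels, 60)
  expect_equal(rowSums(ref$class_probabilities), rep(1, 60), tolerance = 1e-9)
  expect_equal(ref$labels,
               max.col(ref$class_probabilities, ties.method = "first") - 1L)
  # refinement reproduces the (already clean) blob structure
  expect_gte(adjusted_rand_index(blobs$labels, ref$labels), 0.95)

  # hand-built degenerate discriminator: constant equal logits tie to class 0
  cfg <- small_cfg()
  params <- gaeclust:::with_seed(1, gaeclust:::gan_init_params(2, 3, cfg))
  params$disc$W1[] <- 0; params$disc$W2[] <- 0; params$disc$Wc[] <- 0
  params$disc$bc <- c(0.5, 0.5, 0.1)
  toy <- structure(list(params = params,
                        scale = list(mins = c(-1, -1), maxs = c(1, 1)),
                        K = 3L, cfg = cfg, loss_d = 0, loss_g = 0),
                   class = "gan_model")
  out <- relabel_all(matrix(rnorm(10), 5, 2), toy)
  expect_true(all(out$labels == 0L)) # tie between classes 0 and 1 -> 0
})
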