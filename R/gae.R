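#' Graph autoencoder configuration
#'
#' @param layer_dims output width of each graph-convolution layer; the last
#'   entry is the embedding dimension d. Default `c(256, 32)`.
#' @param leaky_slope negative slope of the leaky rectifier (default 0.2).
#' @param epochs training epochs (full-batch; default 200).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed RNG seed for weight init (and nothing else).
#' @param batch_norm apply feature-wise standardization with learned
#'   scale/shift after each rectified graph convolution (default TRUE).
#' @param decoder_layer apply one linear + leaky-rectified d -> d layer to Z
#'   before the inner-product decoder (default TRUE).
#' @param bn_eps numerical floor inside the standardization (default 1e-5).
#' @return a `gae_config` list.
#' @export
gae_config <- function(layer_dims = c(256, 32), leaky_slope = 0.2,
                       epochs = 200, learning_rate = 1e-3, seed = 1,
                       batch_norm = TRUE, decoder_layer = TRUE,
                       bn_eps = 1e-5) {
  if (length(layer_dims) < 1 || any(layer_dims < 1))
    stop("`layer_dims` must be a nonempty vector of positive integers")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  structure(list(layer_dims = as.integer(layer_dims),
                 leaky_slope = leaky_slope, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 batch_norm = isTRUE(batch_norm),
                 decoder_layer = isTRUE(decoder_layer), bn_eps = bn_eps),
            class = "gae_config")
}

gae_init_params <- function(h, cfg) {
  dims <- c(h, cfg$layer_dims)
  params <- list()
  for (l in seq_along(cfg$layer_dims)) {
    params[[paste0("W", l)]] <- init_weight(dims[l], dims[l + 1])
    if (cfg$batch_norm) {
      params[[paste0("gamma", l)]] <- rep(1, dims[l + 1])
      params[[paste0("beta", l)]] <- rep(0, dims[l + 1])
    }
  }
  if (cfg$decoder_layer) {
    d <- utils::tail(cfg$layer_dims, 1)
    params$Wd <- init_weight(d, d)
    params$bd <- rep(0, d)
  }
  params
}

# Forward pass through the stacked graph convolutions:
# X^(l+1) = BatchNorm(LeakyReLU(A X^(l) W^(l))). Returns Z and, when
# `cache = TRUE`, the per-layer intermediates needed for backprop.
# A (X W) and (A X) W are associatively equal; each layer multiplies in the
# order that keeps the expensive N x N product at the narrower width.
gae_forward <- function(A, x, params, cfg, cache = FALSE) {
  L <- length(cfg$layer_dims)
  caches <- if (cache) vector("list", L) else NULL
  out <- as.matrix(x)
  N <- nrow(out)
  for (l in seq_len(L)) {
    Xin <- out
    W <- params[[paste0("W", l)]]
    narrow_out <- ncol(W) < ncol(Xin)
    if (narrow_out) {
      S <- NULL
      U <- as.matrix(A %*% (Xin %*% W))
    } else {
      S <- as.matrix(A %*% Xin)
      U <- S %*% W
    }
    V <- leaky_relu(U, cfg$leaky_slope)
    if (cfg$batch_norm) {
      mu <- colMeans(V)
      va <- colMeans(sweep(V, 2, mu)^2)
      istd <- 1 / sqrt(va + cfg$bn_eps)
      xhat <- sweep(sweep(V, 2, mu), 2, istd, `*`)
      out <- sweep(sweep(xhat, 2, params[[paste0("gamma", l)]], `*`),
                   2, params[[paste0("beta", l)]], `+`)
    } else {
      xhat <- NULL; mu <- NULL; istd <- NULL
      out <- V
    }
    if (!all(is.finite(out)))
      stop("non-finite activation in graph-conv layer ", l)
    if (cache) caches[[l]] <- list(Xin = Xin, S = S, U = U, V = V,
                                   mu = mu, istd = istd, xhat = xhat)
  }
  list(Z = out, caches = caches)
}

# decoder-side projection of Z (identity when decoder_layer is off)
gae_project <- function(z, params, cfg, cache = FALSE) {
  if (!cfg$decoder_layer) return(list(Zd = z, pre = NULL))
  pre <- sweep(z %*% params$Wd, 2, params$bd, `+`)
  list(Zd = leaky_relu(pre, cfg$leaky_slope), pre = if (cache) pre else NULL)
}

#' Encode node features into embeddings
#'
#' Runs the stacked graph-convolution encoder
#' `X^(l+1) = BatchNorm(LeakyReLU(A X^(l) W^(l)))` and returns the node
#' embedding matrix Z, whose first `n_cells` rows are the cell embeddings.
#'
#' @param a a [assemble_adjacency()] result (or any matrix).
#' @param x node feature matrix, cells stacked above genes (`rbind(X2, X1)`).
#' @param params layer weights as produced by [train_gae()].
#' @param cfg a [gae_config()].
#' @return an `EmbeddingMatrix`: list with `Z` ((n+m) x d) and `n_cells`.
#' @export
gae_encode <- function(a, x, params, cfg) {
  A <- if (inherits(a, "BlockAdjacency")) a$A else a
  n_cells <- if (inherits(a, "BlockAdjacency")) a$n_cells else nrow(x)
  if (nrow(x) != nrow(A))
    stop("feature matrix has ", nrow(x), " rows but adjacency is ", nrow(A), " x ", ncol(A))
  z <- gae_forward(A, x, params, cfg)$Z
  structure(list(Z = z, n_cells = n_cells), class = "EmbeddingMatrix")
}

#' Inner-product decoder
#'
#' Reconstructs the adjacency as the elementwise logistic of `Z %*% t(Z)`;
#' the output is symmetric with every entry strictly inside (0, 1) —
#' saturated values are nudged off the boundary by 1e-12 so the open
#' interval holds in floating point as well.
#'
#' @param z an `EmbeddingMatrix` or a plain numeric matrix.
#' @return dense reconstructed adjacency matrix.
#' @export
decode_adjacency <- function(z) {
  m <- if (inherits(z, "EmbeddingMatrix")) z$Z else as.matrix(z)
  pmin(pmax(sigmoid(tcrossprod(m)), 1e-12), 1 - 1e-12)
}

#' Adjacency reconstruction loss
#'
#' The Frobenius norm of `A - A_hat` (square root of the sum of squared
#' entrywise differences).
#'
#' @param a the target adjacency (`BlockAdjacency` or matrix).
#' @param a_hat the reconstruction.
#' @return a nonnegative scalar.
#' @export
reconstruction_loss <- function(a, a_hat) {
  A <- if (inherits(a, "BlockAdjacency")) as.matrix(a$A) else as.matrix(a)
  a_hat <- as.matrix(a_hat)
  if (!all(dim(A) == dim(a_hat)))
    stop("shape mismatch: ", paste(dim(A), collapse = "x"), " vs ",
         paste(dim(a_hat), collapse = "x"))
  sqrt(sum((A - a_hat)^2))
}

# gradient of the full reconstruction objective wrt every parameter
gae_backward <- function(Adense, fw, proj, params, cfg) {
  Zd <- proj$Zd
  Ahat <- sigmoid(tcrossprod(Zd))
  R <- Adense - Ahat
  loss <- sqrt(sum(R^2))
  grads <- list()
  if (loss == 0) return(list(loss = 0, grads = grads))
  dAhat <- -R / loss
  dM <- dAhat * Ahat * (1 - Ahat)
  dZd <- (dM + t(dM)) %*% Zd
  if (cfg$decoder_layer) {
    dpre <- dZd * leaky_relu_grad(proj$pre, cfg$leaky_slope)
    grads$Wd <- crossprod(fw$Z, dpre)
    grads$bd <- colSums(dpre)
    dOut <- tcrossprod(dpre, params$Wd)
  } else {
    dOut <- dZd
  }
  L <- length(cfg$layer_dims)
  for (l in rev(seq_len(L))) {
    cc <- fw$caches[[l]]
    N <- nrow(cc$V)
    if (cfg$batch_norm) {
      gamma <- params[[paste0("gamma", l)]]
      grads[[paste0("gamma", l)]] <- colSums(dOut * cc$xhat)
      grads[[paste0("beta", l)]] <- colSums(dOut)
      dxhat <- sweep(dOut, 2, gamma, `*`)
      vc <- sweep(cc$V, 2, cc$mu) # centered V
      dvar <- colSums(dxhat * vc) * (-0.5) * cc$istd^3
      dmu <- -colSums(dxhat) * cc$istd
      dV <- sweep(dxhat, 2, cc$istd, `*`) +
        sweep(vc, 2, 2 * dvar / N, `*`) +
        matrix(dmu / N, N, length(dmu), byrow = TRUE)
    } else {
      dV <- dOut
    }
    dU <- dV * leaky_relu_grad(cc$U, cfg$leaky_slope)
    W <- params[[paste0("W", l)]]
    if (is.null(cc$S)) { # layer ran in A (X W) order
      T_ <- crossprod(Adense, dU)
      grads[[paste0("W", l)]] <- crossprod(cc$Xin, T_)
      if (l > 1) dOut <- tcrossprod(T_, W)
    } else {
      grads[[paste0("W", l)]] <- crossprod(cc$S, dU)
      if (l > 1) dOut <- crossprod(Adense, tcrossprod(dU, W))
    }
  }
  list(loss = loss, grads = grads)
}

#' Train the graph autoencoder
#'
#' Full-batch Adam minimization of the adjacency reconstruction loss
#' (Frobenius norm of `A - sigmoid(Z Z^T)`) for `cfg$epochs` epochs.
#' Deterministic given `cfg$seed`.
#'
#' @param a a [assemble_adjacency()] result.
#' @param x node feature matrix (`rbind(X2, X1)`, cells first).
#' @param cfg a [gae_config()].
#' @return list with `params` (trained weights), `embedding`
#'   (`EmbeddingMatrix` from the final weights) and `loss_trace`
#'   (loss evaluated at the start of each epoch).
#' @export
train_gae <- function(a, x, cfg = gae_config()) {
  stopifnot(inherits(a, "BlockAdjacency"), inherits(cfg, "gae_config"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(a$A))
    stop("feature matrix rows (", nrow(x), ") != adjacency size (", nrow(a$A), ")")
  with_seed(cfg$seed, {
    params <- gae_init_params(ncol(x), cfg)
    state <- adam_init(params)
    Adense <- as.matrix(a$A) # dense pays off: the bipartite blocks are dense
    trace <- numeric(cfg$epochs)
    for (e in seq_len(cfg$epochs)) {
      fw <- gae_forward(Adense, x, params, cfg, cache = TRUE)
      proj <- gae_project(fw$Z, params, cfg, cache = TRUE)
      bk <- gae_backward(Adense, fw, proj, params, cfg)
      if (!is.finite(bk$loss))
        stop("graph autoencoder diverged (non-finite loss) at epoch ", e)
      trace[e] <- bk$loss
      upd <- adam_step(params, bk$grads, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    z <- gae_encode(a, x, params, cfg)
    list(params = params, embedding = z, loss_trace = trace)
  })
}

#' Preliminary K-means clustering of the cell embeddings
#'
#' Runs K-means (10 restarts, best within-cluster sum of squares) on the
#' first `n_cells` rows of the embedding. Deterministic given `seed`.
#'
#' @param z_cells cell embedding matrix (or an `EmbeddingMatrix`, in which
#'   case its cell rows are used).
#' @param K number of clusters, `2 <= K <= n_cells`.
#' @param seed RNG seed.
#' @param nstart K-means restarts (default 10).
#' @return a `ClusterAssignment`: list with `labels` (0-based integers,
#'   length n), `centroids` (K x d) and `K`.
#' @export
initial_clusters <- function(z_cells, K, seed = 1, nstart = 10) {
  if (inherits(z_cells, "EmbeddingMatrix"))
    z_cells <- z_cells$Z[seq_len(z_cells$n_cells), , drop = FALSE]
  z_cells <- as.matrix(z_cells)
  n <- nrow(z_cells)
  if (!is.numeric(K) || length(K) != 1 || K < 2 || K > n)
    stop("`K` must satisfy 2 <= K <= n_cells (= ", n, ")")
  if (K == n) # trivial partition: each cell its own cluster, inertia 0
    return(structure(list(labels = seq_len(n) - 1L, centroids = z_cells,
                          K = as.integer(K)),
                     class = "ClusterAssignment"))
  km <- with_seed(seed,
    suppressWarnings(stats::kmeans(z_cells, centers = as.integer(K),
                                   nstart = nstart, iter.max = 100)))
  structure(list(labels = as.integer(km$cluster) - 1L,
                 centroids = unname(km$centers), K = as.integer(K)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (sizes: %s)\n",
              length(x$labels), x$K,
              paste(tabulate(x$labels + 1L, x$K), collapse = ", ")))
  invisible(x)
}
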