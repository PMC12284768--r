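norm_expr <- function(m, stage = "normalized") {
  expression_matrix(m, sprintf("g%03d", seq_len(nrow(m))),
                    sprintf("c%03d", seq_len(ncol(m))), stage = stage)
}

test_that("column normalization yields per-cell relevance distributions", {
  m <- matrix(c(1, 1, 2,   # plain nonnegative column sums to one
                0, 0, 0,   # untouched zero column
                -1, 0, 1), # negative column is min-shifted first
              nrow = 3)
  b <- column_normalize(norm_expr(m))
  expect_equal(unname(b$B[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(unname(b$B[, 2]), c(0, 0, 0))
  expect_equal(unname(b$B[, 3]), c(0, 1/3, 2/3)) # shifted by +1 then scaled by 1/3

  set.seed(4)
  r <- column_normalize(norm_expr(matrix(rnorm(60), 10, 6)))
  expect_true(all(abs(colSums(r$B) - 1) < 1e-12 | colSums(r$B) == 0))
  expect_true(min(r$B) >= 0)
})

test_that("gene PCA features reproduce a direct eigen-decomposition", {
  set.seed(9)
  B <- matrix(runif(30 * 20), 30, 20)
  B <- sweep(B, 2, colSums(B), `/`)
  b <- structure(list(B = B, gene_ids = paste0("g", 1:30),
                      cell_ids = paste0("c", 1:20)),
                 class = "BipartiteRelevance")
  x1 <- gene_features(b, 5)
  expect_equal(dim(x1), c(30L, 5L))

  # oracle: eigen-decomposition of the gene-row covariance
  ctr <- scale(B, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(ctr) / (nrow(B) - 1), symmetric = TRUE)
  scores <- ctr %*% ev$vectors[, 1:5]
  expect_equal(abs(unname(x1)), abs(unname(scores)), tolerance = 1e-8)
  # deterministic sign convention: largest-magnitude loading positive
  expect_identical(x1, gene_features(b, 5))

  # rank-2 relevance: two components carry all the variance
  low <- tcrossprod(matrix(rnorm(30 * 2), 30), matrix(rnorm(20 * 2), 20))
  b2 <- structure(list(B = low), class = "BipartiteRelevance")
  sc <- gene_features(b2, 20)
  total <- sum(apply(scale(low, center = TRUE, scale = FALSE), 2, var))
  expect_equal(sum(apply(sc[, 1:2], 2, var)) / total, 1, tolerance = 1e-8)
  expect_error(gene_features(b, 25), "h")
})

test_that("cell features are the exact relevance-weighted product", {
  # identity relevance: cells inherit the gene features verbatim
  bI <- structure(list(B = diag(4)), class = "BipartiteRelevance")
  x1 <- matrix(rnorm(4 * 3), 4)
  expect_equal(cell_features(bI, x1), x1)

  # naive triple-loop oracle
  set.seed(5)
  B <- matrix(runif(8 * 5), 8, 5)
  b <- structure(list(B = B), class = "BipartiteRelevance")
  x1 <- matrix(rnorm(8 * 3), 8)
  x2 <- cell_features(b, x1)
  ref <- matrix(0, 5, 3)
  for (i in 1:5) for (j in 1:3) for (g in 1:8)
    ref[i, j] <- ref[i, j] + B[g, i] * x1[g, j]
  expect_equal(x2, ref, tolerance = 1e-12)
  expect_error(cell_features(b, x1[1:3, ]), "genes")
})

test_that("knn cell graph connects nearest neighbours with uniform rows", {
  # collinear points: the middle one picks its nearer endpoint,
  # equidistant ties resolve to the lower index
  x <- matrix(c(0, 1.4, 3), ncol = 1)
  g <- knn_cell_graph(x, k = 1)
  expect_equal(g$neighbors[2, ], 1L)
  tie <- knn_cell_graph(matrix(c(0, 1, 2), ncol = 1), k = 1)
  expect_equal(tie$neighbors[2, ], 1L)
  expect_equal(unname(as.vector(g$C[2, ])), c(0.5, 0.5, 0))

  set.seed(8)
  blobs <- make_blobs(20, K = 2, d = 2, sep = 8, sd = 0.4, seed = 8)
  g2 <- knn_cell_graph(blobs$z, k = 5)
  expect_true(all(abs(Matrix::rowSums(g2$C) - 1) < 1e-12))
  expect_true(all(Matrix::rowSums(g2$C != 0) <= 6))

  # neighbours match an exhaustive pairwise-distance sort, and stay
  # within the planted blob
  dm <- as.matrix(dist(blobs$z))
  within <- 0
  for (i in 1:40) {
    d <- dm[i, ]; d[i] <- Inf
    expect_equal(sort(g2$neighbors[i, ]), sort(order(d)[1:5]))
    within <- within + sum(blobs$labels[g2$neighbors[i, ]] == blobs$labels[i])
  }
  expect_gte(within / (40 * 5), 0.95)

  # rigid rotation preserves the neighbour sets
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g3 <- knn_cell_graph(blobs$z %*% R, k = 5)
  expect_equal(g3$neighbors, g2$neighbors)

  expect_error(knn_cell_graph(blobs$z, k = 40), "k")
})

test_that("block adjacency has the lambda-weighted layout", {
  set.seed(3)
  D <- norm_expr(matrix(rnorm(6 * 4), 6, 4)) # m = 6 genes, n = 4 cells
  b <- column_normalize(D)
  x1 <- gene_features(b, 3)
  cg <- knn_cell_graph(cell_features(b, x1), k = 2)
  adj <- assemble_adjacency(cg, b, lam = 0.3)
  A <- as.matrix(adj$A)
  expect_equal(dim(A), c(10L, 10L))
  expect_equal(A[1:4, 1:4], 0.3 * as.matrix(cg$C), ignore_attr = TRUE)
  expect_equal(A[1:4, 5:10], 0.7 * t(b$B), ignore_attr = TRUE)
  expect_equal(A[5:10, 1:4], 0.7 * b$B, ignore_attr = TRUE)
  expect_true(all(A[5:10, 5:10] == 0))

  # cell rows sum to lam + (1 - lam) = 1; gene rows to (1-lam) * rowSums(B)
  expect_true(all(abs(rowSums(A)[1:4] - 1) < 1e-9))
  expect_equal(rowSums(A)[5:10], 0.7 * rowSums(b$B), ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_error(assemble_adjacency(cg, b, lam = 0), "lam")
  expect_error(assemble_adjacency(cg, b, lam = 1), "lam")
  expect_s4_class(assemble_adjacency(cg, b, lam = 1,
                                     allow_boundary = TRUE)$A, "CsparseMatrix")
})

test_that("adjacency scales linearly in lambda", {
  set.seed(13)
  D <- norm_expr(matrix(rnorm(8 * 5), 8, 5))
  b <- column_normalize(D)
  cg <- knn_cell_graph(cell_features(b, gene_features(b, 3)), k = 2)
  A1 <- as.matrix(assemble_adjacency(cg, b, 0.2)$A)
  A2 <- as.matrix(assemble_adjacency(cg, b, 0.5)$A)
  expect_equal((A1 + A2)[1:5, 1:5], 0.7 * as.matrix(cg$C),
               ignore_attr = TRUE, tolerance = 1e-12)

  # bipartite mass decays as (1 - lambda)
  mass <- vapply(c(0.1, 0.5, 0.9), function(l) {
    A <- as.matrix(assemble_adjacency(cg, b, l)$A)
    norm(A[6:13, 1:5], "F")
  }, numeric(1))
  expect_equal(mass / mass[1], (1 - c(0.1, 0.5, 0.9)) / 0.9, tolerance = 1e-9)
})
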