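#' Column-normalized cell-gene relevance matrix
#'
#' Converts the normalized expression matrix D (genes x cells) into a
#' nonnegative relevance matrix B whose entry `B[i, j]` is read as the edge
#' weight between gene i and cell j. Because D is z-scored it can be
#' negative, so each column is first shifted by its own minimum (when that
#' minimum is negative) and then scaled to sum to one. Columns with no mass
#' after shifting are left at zero.
#'
#' @param d ExpressionMatrix at stage `"normalized"`.
#' @return an object of class `BipartiteRelevance`: list with `B`
#'   (genes x cells, columns sum to 0 or 1), `gene_ids`, `cell_ids`.
#' @export
column_normalize <- function(d) {
  require_stage(d, "normalized", "column_normalize")
  m <- as.matrix(d$values)
  mins <- apply(m, 2, min)
  shift <- pmin(mins, 0)
  m <- sweep(m, 2, shift, `-`)
  cs <- colSums(m)
  pos <- cs > 0
  m[, pos] <- sweep(m[, pos, drop = FALSE], 2, cs[pos], `/`)
  m[, !pos] <- 0
  structure(list(B = m, gene_ids = d$gene_ids, cell_ids = d$cell_ids),
            class = "BipartiteRelevance")
}

#' @export
print.BipartiteRelevance <- function(x, ...) {
  cat(sprintf("BipartiteRelevance: %d genes x %d cells\n", nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Gene node features by PCA
#'
#' Reduces each gene row of B to `h` dimensions by principal component
#' analysis (genes are the observations, cells the variables). Component
#' signs follow the convention that the largest-magnitude loading of each
#' component is positive, making the scores deterministic.
#'
#' @param b a [column_normalize()] result.
#' @param h target dimension, `h <= min(n_genes, n_cells)`.
#' @return numeric matrix X1 (genes x h) of PCA scores.
#' @export
gene_features <- function(b, h) {
  stopifnot(inherits(b, "BipartiteRelevance"))
  m <- nrow(b$B); n <- ncol(b$B)
  if (!is.numeric(h) || length(h) != 1 || h < 1 || h > min(m, n))
    stop("`h` must be in [1, min(n_genes, n_cells)] = [1, ", min(m, n), "]")
  pc <- stats::prcomp(b$B, center = TRUE, scale. = FALSE, rank. = h)
  flip <- apply(pc$rotation, 2, function(r) sign(r[which.max(abs(r))]))
  flip[flip == 0] <- 1
  x1 <- sweep(pc$x, 2, flip, `*`)
  got <- ncol(x1)
  if (got < h) # rank-deficient input: pad with zero directions
    x1 <- cbind(x1, matrix(0, m, h - got))
  unname(x1)
}

#' Cell node features
#'
#' Each cell's feature vector is the relevance-weighted combination of the
#' gene features: `X2 = t(B) %*% X1`.
#'
#' @param b a [column_normalize()] result.
#' @param x1 gene feature matrix from [gene_features()].
#' @return numeric matrix X2 (cells x h).
#' @export
cell_features <- function(b, x1) {
  stopifnot(inherits(b, "BipartiteRelevance"))
  if (nrow(x1) != nrow(b$B))
    stop("x1 has ", nrow(x1), " rows but B has ", nrow(b$B), " genes")
  unname(crossprod(b$B, x1))
}

#' Row-normalized k-nearest-neighbour cell graph
#'
#' Connects each cell to its k nearest neighbours under Euclidean distance in
#' feature space, plus itself, then row-normalizes so each cell's row sums to
#' one (uniform weight 1/(k+1) on self + neighbours). Distance ties are
#' broken by lower cell index.
#'
#' @param x2 cell feature matrix (cells x h).
#' @param k neighbour count, `1 <= k < n_cells`; default 15.
#' @return an object of class `CellGraph`: list with sparse `C`
#'   (cells x cells, rows sum to 1), `k`, and `neighbors` (cells x k index
#'   matrix, self excluded).
#' @export
knn_cell_graph <- function(x2, k = 15) {
  x2 <- as.matrix(x2)
  n <- nrow(x2)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= n)
    stop("`k` must satisfy 1 <= k < n_cells (= ", n, ")")
  k <- as.integer(k)
  dm <- as.matrix(stats::dist(x2))
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- dm[i, ]
    d[i] <- Inf
    nb[i, ] <- order(d)[seq_len(k)] # order() breaks ties by lower index
  }
  ii <- rep(seq_len(n), each = k + 1L)
  jj <- as.integer(t(cbind(seq_len(n), nb)))
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / (k + 1), dims = c(n, n))
  structure(list(C = C, k = k, neighbors = nb), class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  cat(sprintf("CellGraph: %d cells, k = %d\n", nrow(x$C), x$k))
  invisible(x)
}

#' Composite cell-gene block adjacency
#'
#' Assembles the (n + m) x (n + m) adjacency over n cell nodes followed by m
#' gene nodes:
#' \preformatted{
#'   A = | lambda * C        (1 - lambda) * t(B) |
#'       | (1 - lambda) * B  0                   |
#' }
#' `lambda` trades cell-cell structure against cell-gene structure; the
#' gene-gene block is identically zero.
#'
#' @param cg a [knn_cell_graph()] result.
#' @param b a [column_normalize()] result.
#' @param lam mixing weight, in (0, 1) for normal runs. `allow_boundary = TRUE`
#'   additionally admits `lam = 1` (cell graph only), used by the
#'   lambda-sweep ablation.
#' @param allow_boundary see `lam`.
#' @return an object of class `BlockAdjacency`: list with sparse `A`,
#'   `n_cells`, `n_genes`, `lam`.
#' @export
assemble_adjacency <- function(cg, b, lam = 0.3, allow_boundary = FALSE) {
  stopifnot(inherits(cg, "CellGraph"), inherits(b, "BipartiteRelevance"))
  ok <- is.numeric(lam) && length(lam) == 1 &&
    (lam > 0 && (lam < 1 || (allow_boundary && lam == 1)))
  if (!ok) stop("`lam` must lie in (0, 1)",
                if (allow_boundary) " (or equal 1 in sweep mode)" else "")
  n <- nrow(cg$C); m <- nrow(b$B)
  if (ncol(b$B) != n) stop("cell graph has ", n, " cells but B has ", ncol(b$B))
  Bs <- methods::as(methods::as(b$B, "dMatrix"), "CsparseMatrix")
  A <- rbind(
    cbind(lam * cg$C, (1 - lam) * Matrix::t(Bs)),
    cbind((1 - lam) * Bs, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0), dims = c(m, m)))
  )
  structure(list(A = methods::as(A, "CsparseMatrix"), n_cells = n, n_genes = m,
                 lam = lam),
            class = "BlockAdjacency")
}

#' @export
print.BlockAdjacency <- function(x, ...) {
  cat(sprintf("BlockAdjacency: %d cells + %d genes, lambda = %g\n",
              x$n_cells, x$n_genes, x$lam))
  invisible(x)
}

#' Build the composite graph from a normalized expression matrix
#'
#' Convenience wrapper chaining [column_normalize()], [gene_features()],
#' [cell_features()], [knn_cell_graph()] and [assemble_adjacency()].
#'
#' @param d ExpressionMatrix at stage `"normalized"`.
#' @param h PCA dimension (default 50, capped at `min(m, n) - 1`).
#' @param k KNN neighbour count (default 15).
#' @param lam adjacency mixing weight (default 0.3).
#' @param allow_boundary admit `lam = 1` (sweep mode).
#' @return list with `adjacency` (BlockAdjacency), `features` (the stacked
#'   node feature matrix `X = rbind(X2, X1)`, cells first), `relevance`,
#'   `cell_graph`, `X1`, `X2`, `h`.
#' @export
build_pathway_graph <- function(d, h = 50, k = 15, lam = 0.3,
                                allow_boundary = FALSE) {
  b <- column_normalize(d)
  h <- min(h, min(nrow(b$B), ncol(b$B)) - 1L)
  x1 <- gene_features(b, h)
  x2 <- cell_features(b, x1)
  cg <- knn_cell_graph(x2, k)
  adj <- assemble_adjacency(cg, b, lam, allow_boundary = allow_boundary)
  list(adjacency = adj, features = rbind(x2, x1), relevance = b,
       cell_graph = cg, X1 = x1, X2 = x2, h = h)
}
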