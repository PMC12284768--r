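#' Configuration for the synthetic count simulator
#'
#' Describes a planted-partition scRNA-seq experiment: K cell groups, each
#' marked by a block of up-regulated marker genes, negative-binomial counts
#' with log-normal library-size variation, and independent dropout-style
#' zero-masking.
#'
#' @param n_cells number of cells (default 600).
#' @param n_genes number of genes (default 600).
#' @param K number of planted groups (default 3, must be >= 2).
#' @param marker_genes_per_cluster marker genes per group (default 40);
#'   `K * marker_genes_per_cluster` must not exceed `n_genes`.
#' @param fold_change marker up-regulation factor (> 1 for signal; 1 means no
#'   group structure; default 8).
#' @param base_mean mean expression of a background gene (default 1).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.3.
#' @param dropout_rate probability that any entry is zero-masked after
#'   sampling, in `[0, 1)` (default 0.3).
#' @param libsize_sigma sd of the log-normal per-cell library-size factor
#'   (default 0.3).
#' @param seed RNG seed (default 1).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cells = 600, n_genes = 600, K = 3,
                         marker_genes_per_cluster = 40, fold_change = 8,
                         base_mean = 1, dispersion = 0.3, dropout_rate = 0.3,
                         libsize_sigma = 0.3, seed = 1) {
  if (K < 2) stop("`K` must be >= 2")
  if (marker_genes_per_cluster * K > n_genes)
    stop("K * marker_genes_per_cluster exceeds n_genes")
  if (fold_change < 1) stop("`fold_change` must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 K = as.integer(K),
                 marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
                 fold_change = fold_change, base_mean = base_mean,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 libsize_sigma = libsize_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a planted-partition scRNA-seq count matrix
#'
#' Cells are split near-evenly into K groups (then shuffled). Gene g in cell
#' c has mean `base_g * fold^(marker of c's group) * lib_c` where `base_g`
#' is a log-normal gene-level baseline around `base_mean` and `lib_c` a
#' log-normal library factor; counts are negative-binomial at the given
#' dispersion, then independently zero-masked at `dropout_rate`.
#' Deterministic per `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `expression` (an [expression_matrix()] at stage `"raw"`,
#'   sparse), `labels` (0-based planted group per cell), `marker_genes`
#'   (list of marker gene-index vectors per group), `baseline_means`
#'   (per-gene baseline expression) and `library_factors` (per-cell size
#'   factors).
#' @export
simulate_counts <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells; m <- cfg$n_genes; K <- cfg$K
    labels <- sample(rep_len(seq_len(K) - 1L, n))
    base <- cfg$base_mean * exp(stats::rnorm(m, 0, 0.5) - 0.5^2 / 2)
    lib <- exp(stats::rnorm(n, 0, cfg$libsize_sigma) - cfg$libsize_sigma^2 / 2)
    markers <- lapply(seq_len(K), function(k)
      ((k - 1) * cfg$marker_genes_per_cluster + 1):(k * cfg$marker_genes_per_cluster))
    fold <- matrix(1, m, K)
    for (k in seq_len(K)) fold[markers[[k]], k] <- cfg$fold_change
    mu <- sweep(base * fold[, labels + 1L, drop = FALSE], 2, lib, `*`)
    counts <- if (cfg$dispersion > 0) {
      matrix(stats::rnbinom(m * n, mu = mu, size = 1 / cfg$dispersion), m, n)
    } else {
      matrix(stats::rpois(m * n, lambda = mu), m, n)
    }
    if (cfg$dropout_rate > 0) {
      mask <- matrix(stats::runif(m * n) < cfg$dropout_rate, m, n)
      counts[mask] <- 0L
    }
    gene_ids <- sprintf("gene%04d", seq_len(m))
    cell_ids <- sprintf("cell%04d", seq_len(n))
    sm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    list(expression = expression_matrix(sm, gene_ids, cell_ids, stage = "raw"),
         labels = labels, marker_genes = markers, baseline_means = base,
         library_factors = lib)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the counts as a Matrix Market directory (matrix.mtx +
#' features.tsv + barcodes.tsv) and the planted labels as
#' `truth_labels.csv` (columns cell_id, label).
#'
#' @param sim a [simulate_counts()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_expression(sim$expression, dir, format = "mtx_dir")
  utils::write.csv(data.frame(cell_id = sim$expression$cell_ids,
                              label = sim$labels),
                   file.path(dir, "truth_labels.csv"), row.names = FALSE)
  invisible(dir)
}
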