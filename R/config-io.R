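#' Read a pipeline configuration from YAML
#'
#' The file mirrors the [pipeline_config()] blocks, e.g.:
#' \preformatted{
#' K: 3
#' seed: 1
#' preprocess:
#'   min_cell_fraction: 0.01
#'   n_top_genes: 2000
#' graph:
#'   h: 50
#'   k: 15
#'   lambda: 0.3
#' gae:
#'   epochs: 100
#' confidence:
#'   fraction: 0.3
#' gan:
#'   epochs: 30
#' }
#' Omitted keys keep their defaults. `K` may instead be passed to the caller.
#'
#' @param path YAML file.
#' @param K overrides/supplies the cluster count.
#' @param seed overrides the seed.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, K = NULL, seed = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(K)) y$K <- K
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$K)) stop("`K` must be given in the config file or as an argument")
  pipeline_config(K = y$K,
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  preprocess = if (is.null(y$preprocess)) list() else y$preprocess,
                  graph = if (is.null(y$graph)) list() else y$graph,
                  gae = if (is.null(y$gae)) list() else y$gae,
                  confidence = if (is.null(y$confidence)) list() else y$confidence,
                  gan = if (is.null(y$gan)) list() else y$gan)
}

#' Read cell labels from a CSV file
#'
#' Accepts either a single-column file of labels or a two-column file with
#' `cell_id` first and the label second (as written by [write_simulation()]).
#'
#' @param path CSV file.
#' @return label vector.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) == 1) tab[[1]] else tab[[2]]
}
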