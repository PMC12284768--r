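#' Distance of each cell to its own cluster centroid
#'
#' @param z_cells cell embedding matrix (n x d).
#' @param assign a `ClusterAssignment` over the same cells.
#' @return numeric vector of Euclidean distances, length n.
#' @export
centroid_distances <- function(z_cells, assign) {
  stopifnot(inherits(assign, "ClusterAssignment"))
  z_cells <- as.matrix(z_cells)
  if (nrow(z_cells) != length(assign$labels))
    stop("embedding has ", nrow(z_cells), " cells but assignment has ",
         length(assign$labels))
  sizes <- tabulate(assign$labels + 1L, assign$K)
  if (any(sizes == 0))
    stop("empty cluster(s): ", paste(which(sizes == 0) - 1L, collapse = ", "))
  diff <- z_cells - assign$centroids[assign$labels + 1L, , drop = FALSE]
  sqrt(rowSums(diff^2))
}

#' Select high-confidence cells near each cluster centroid
#'
#' Within every cluster, cells are ranked by distance to the cluster
#' centroid (ties broken by lower cell index) and the nearest
#' `max(1, round(fraction * cluster_size))` are kept as high-confidence
#' training samples for the adversarial refinement stage. The recommended
#' fraction lies between 0.3 and 0.5; the default is the conservative 0.3.
#'
#' @param z_cells cell embedding matrix (n x d).
#' @param assign a `ClusterAssignment`.
#' @param fraction per-cluster fraction in (0, 1]; default 0.3.
#' @return a `ConfidenceSet`: list with `indices` (1-based cell indices),
#'   `x_real` (their embedding rows), `y_real` (their 0-based cluster
#'   labels), `distances` (their centroid distances) and `fraction`.
#' @export
select_high_confidence <- function(z_cells, assign, fraction = 0.3) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be a single number in (0, 1]")
  z_cells <- as.matrix(z_cells)
  d <- centroid_distances(z_cells, assign)
  keep <- integer(0)
  for (k in seq_len(assign$K) - 1L) {
    members <- which(assign$labels == k)
    n_keep <- max(1L, as.integer(round(fraction * length(members))))
    ord <- members[order(d[members])] # order(): distance asc, index asc on ties
    keep <- c(keep, ord[seq_len(n_keep)])
  }
  keep <- sort(keep)
  structure(list(indices = keep,
                 x_real = z_cells[keep, , drop = FALSE],
                 y_real = assign$labels[keep],
                 distances = d[keep],
                 fraction = fraction),
            class = "ConfidenceSet")
}

#' @export
print.ConfidenceSet <- function(x, ...) {
  cat(sprintf("ConfidenceSet: %d cells (fraction %.2f) over %d clusters\n",
              length(x$indices), x$fraction, length(unique(x$y_real))))
  invisible(x)
}

#' Export a confidence selection as a data frame
#'
#' One row per cell with its cluster, centroid distance and selection flag;
#' suitable for writing to CSV.
#'
#' @param z_cells cell embedding matrix.
#' @param assign a `ClusterAssignment`.
#' @param conf a [select_high_confidence()] result.
#' @param cell_ids optional cell identifiers.
#' @return data.frame with columns cell_id, cluster, distance, selected.
#' @export
confidence_table <- function(z_cells, assign, conf, cell_ids = NULL) {
  d <- centroid_distances(z_cells, assign)
  n <- length(assign$labels)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  data.frame(cell_id = cell_ids, cluster = assign$labels, distance = d,
             selected = seq_len(n) %in% conf$indices)
}
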