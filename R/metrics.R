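# External clustering-agreement metrics, implemented from the standard
# pair-counting / information-theoretic definitions.

label_pair <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length: ", length(truth), " vs ",
         length(predicted))
  list(truth = as.integer(factor(truth)), pred = as.integer(factor(predicted)))
}

contingency <- function(truth, predicted) {
  p <- label_pair(truth, predicted)
  r <- max(p$truth); c <- max(p$pred)
  matrix(tabulate((p$pred - 1L) * r + p$truth, nbins = r * c), r, c)
}

choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand Index
#'
#' Pair-counting agreement between two labelings, adjusted for chance:
#' `(RI - E[RI]) / (max RI - E[RI])` computed from the contingency table.
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones, and can be negative.
#'
#' @param truth,predicted label vectors of equal length (any atomic type).
#' @return scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(truth, predicted) {
  ct <- contingency(truth, predicted)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  sum_ij <- sum(choose2(ct))
  sum_a <- sum(choose2(rowSums(ct)))
  sum_b <- sum(choose2(colSums(ct)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1) # both partitions degenerate and equal
  (sum_ij - expected) / (maximum - expected)
}

#' Clustering accuracy under optimal label matching
#'
#' The largest achievable fraction of agreeing items over all one-to-one
#' mappings between predicted and true labels, found by solving a linear
#' assignment problem on the confusion matrix (handles differing numbers of
#' clusters by padding).
#'
#' @param truth,predicted label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
clustering_accuracy <- function(truth, predicted) {
  ct <- contingency(truth, predicted)
  n <- sum(ct)
  if (n < 1) stop("empty labelings")
  k <- max(dim(ct))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  sum(sq[cbind(hungarian_max(sq), seq_len(k))]) / n
}

# Maximum-weight perfect matching on a square matrix via the O(k^3)
# shortest-augmenting-path (potentials) form of the Hungarian algorithm.
# Returns for each column the matched row index.
hungarian_max <- function(w) {
  k <- nrow(w)
  stopifnot(k == ncol(w))
  cost <- max(w) - w # convert to minimization
  u <- numeric(k) # row potentials
  v <- numeric(k + 1) # column potentials, index 1 = virtual column 0
  p <- integer(k + 1) # p[j+1] = row currently matched to column j (0 = none)
  way <- integer(k + 1) # predecessor column on the augmenting path
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, k)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(k)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:k) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1]
}

#' Normalized Mutual Information
#'
#' Mutual information between the two labelings normalized by a mean of the
#' two entropies. The default normalizer is the arithmetic mean
#' (`2 I / (H_u + H_v)`); `"min"`, `"geometric"` and `"max"` are also
#' available. Two identical partitions score 1; a single-block partition
#' against anything non-identical scores 0.
#'
#' @param truth,predicted label vectors of equal length.
#' @param normalizer `"arithmetic"` (default), `"min"`, `"geometric"`, `"max"`.
#' @return scalar in `[0, 1]`.
#' @export
normalized_mutual_information <- function(truth, predicted,
                                          normalizer = c("arithmetic", "min",
                                                         "geometric", "max")) {
  normalizer <- match.arg(normalizer)
  ct <- contingency(truth, predicted)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  pj <- ct / n
  pr <- rowSums(pj); pc <- colSums(pj)
  nzr <- pr > 0; nzc <- pc > 0
  hu <- -sum(pr[nzr] * log(pr[nzr]))
  hv <- -sum(pc[nzc] * log(pc[nzc]))
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pr, pc)[nz]))
  if (hu == 0 && hv == 0) return(1) # both single-block: identical partitions
  denom <- switch(normalizer,
                  arithmetic = (hu + hv) / 2,
                  min = min(hu, hv),
                  geometric = sqrt(hu * hv),
                  max = max(hu, hv))
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Fowlkes-Mallows Index
#'
#' Geometric mean of pairwise precision and recall over same-cluster pairs:
#' `TP / sqrt((TP + FP) (TP + FN))`. Defined as 0 when either partition has
#' no same-cluster pair.
#'
#' @param truth,predicted label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
fowlkes_mallows_index <- function(truth, predicted) {
  ct <- contingency(truth, predicted)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  tp <- sum(choose2(ct))
  p1 <- sum(choose2(rowSums(ct))) # same-pair count in truth (TP + FN)
  p2 <- sum(choose2(colSums(ct))) # same-pair count in prediction (TP + FP)
  if (p1 == 0 || p2 == 0) return(0)
  tp / sqrt(p1 * p2)
}

#' All four clustering metrics at once
#'
#' @param truth,predicted label vectors of equal length.
#' @return named list with `ari`, `acc`, `nmi`, `fmi`.
#' @export
clustering_metrics <- function(truth, predicted) {
  list(ari = adjusted_rand_index(truth, predicted),
       acc = clustering_accuracy(truth, predicted),
       nmi = normalized_mutual_information(truth, predicted),
       fmi = fowlkes_mallows_index(truth, predicted))
}
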