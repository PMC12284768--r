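# Shared fixtures and independent oracles used across the suite.

# tiny planted-partition simulation for fast end-to-end tests
tiny_sim <- function(seed = 1, fold_change = 8, n_cells = 120, n_genes = 200) {
  simulate_counts(synth_config(n_cells = n_cells, n_genes = n_genes, K = 3,
                               marker_genes_per_cluster =
                                 max(2, min(20, n_genes %/% 6)),
                               fold_change = fold_change, seed = seed))
}

tiny_config <- function(seed = 1, gae = list(), gan = list(), ...) {
  pipeline_config(K = 3, seed = seed, graph = list(h = 30),
                  gae = utils::modifyList(list(epochs = 40), gae),
                  gan = utils::modifyList(list(epochs = 15), gan), ...)
}

# well-separated Gaussian blobs in embedding space
make_blobs <- function(n_per, K = 3, d = 2, sep = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(K * d), K) * sep
  z <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(stats::rnorm(n_per * d, sd = sd), n_per), 2, centers[k, ], `+`)))
  list(z = z, labels = rep(seq_len(K) - 1L, each = n_per))
}

# --- pair-counting oracles (enumerate all item pairs) ------------------

pair_counts <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) tp <- tp + 1
    else if (!st && sp) fp <- fp + 1
    else if (st && !sp) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_ari <- function(truth, pred) {
  pc <- pair_counts(truth, pred)
  n2 <- sum(pc)
  a <- pc["tp"] + pc["fn"]; b <- pc["tp"] + pc["fp"]
  expected <- a * b / n2
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)
  unname((pc["tp"] - expected) / (maximum - expected))
}

oracle_fmi <- function(truth, pred) {
  pc <- pair_counts(truth, pred)
  a <- pc["tp"] + pc["fn"]; b <- pc["tp"] + pc["fp"]
  if (a == 0 || b == 0) return(0)
  unname(pc["tp"] / sqrt(a * b))
}

oracle_nmi <- function(truth, pred) {
  ct <- table(truth, pred)
  n <- sum(ct)
  hu <- hv <- mi <- 0
  pr <- rowSums(ct) / n; pc <- colSums(ct) / n
  for (p in pr) if (p > 0) hu <- hu - p * log(p)
  for (p in pc) if (p > 0) hv <- hv - p * log(p)
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct)))
    if (ct[i, j] > 0)
      mi <- mi + ct[i, j] / n * log(ct[i, j] / n / (pr[i] * pc[j]))
  if (hu == 0 && hv == 0) return(1)
  if (hu + hv == 0) return(0)
  max(0, min(1, mi / ((hu + hv) / 2)))
}

# exhaustive best-permutation accuracy (factorial oracle)
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    m <- matrix(0L, nrow(sub), k)
    m[, 1] <- i
    m[, -1] <- sub + (sub >= i)
    m
  }))
}

oracle_acc <- function(truth, pred) {
  ct <- unclass(table(truth, pred))
  k <- max(dim(ct))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  pm <- all_perms(k)
  best <- 0
  for (r in seq_len(nrow(pm)))
    best <- max(best, sum(sq[cbind(pm[r, ], seq_len(k))]))
  best / sum(ct)
}

# all set partitions of n items as 1-based block labels
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}
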