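#' Pipeline configuration
#'
#' Nested configuration for the full two-stage pipeline. Any subset of the
#' defaults can be overridden by the matching argument; `K` (the number of
#' clusters) must always be supplied, mirroring standard practice of running
#' with the known number of cell types.
#'
#' @param K number of clusters (required).
#' @param seed master seed; stage seeds are derived from it (default 1).
#' @param preprocess list: `min_cell_fraction` (0.01), `n_top_genes` (2000),
#'   `normalization` = list(size_factor, log1p, zscore).
#' @param graph list: `h` (50), `k` (15), `lambda` (0.3).
#' @param gae list passed to [gae_config()] (minus seed).
#' @param confidence list: `fraction` (0.3).
#' @param gan list passed to [gan_config()] (minus seed); set
#'   `gan = list(enabled = FALSE)` to stop after stage one.
#' @return a `pipeline_config` nested list.
#' @export
pipeline_config <- function(K, seed = 1, preprocess = list(), graph = list(),
                            gae = list(), confidence = list(), gan = list()) {
  if (missing(K) || !is.numeric(K) || K < 2)
    stop("`K` (number of clusters, >= 2) is required")
  merge_block <- function(defaults, user) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  cfg <- list(
    K = as.integer(K),
    seed = as.integer(seed),
    preprocess = merge_block(list(min_cell_fraction = 0.01, n_top_genes = 2000,
                                  normalization = list(size_factor = TRUE,
                                                       log1p = TRUE,
                                                       zscore = TRUE)),
                             preprocess),
    graph = merge_block(list(h = 50, k = 15, lambda = 0.3), graph),
    gae = merge_block(list(layer_dims = c(256, 32), leaky_slope = 0.2,
                           epochs = 200, learning_rate = 1e-3,
                           batch_norm = TRUE, decoder_layer = TRUE),
                      gae),
    confidence = merge_block(list(fraction = 0.3), confidence),
    gan = merge_block(list(enabled = TRUE, noise_dim = NULL,
                           hidden_dims_g = c(1024, 512, 256),
                           hidden_dims_d = c(256, 128), leaky_slope = 0.2,
                           epochs = 50, learning_rate = 5e-3,
                           lr_halve_every = 5, adam_betas = c(0.5, 0.999),
                           batch_size = 1024),
                      gan)
  )
  structure(cfg, class = "pipeline_config")
}

#' Canonical desk-scale benchmark configuration
#'
#' The configuration used by the package's synthetic benchmarks: the model
#' defaults with training lengths sized for repeated desk-scale runs
#' (100 autoencoder epochs, 30 GAN epochs).
#'
#' @param K number of clusters (default 3, matching [synth_config()]).
#' @param seed master seed.
#' @param gae,gan,... further overrides forwarded to [pipeline_config()]
#'   (merged over the benchmark's shortened training lengths).
#' @return a `pipeline_config`.
#' @export
benchmark_config <- function(K = 3, seed = 1, gae = list(), gan = list(), ...) {
  gae <- utils::modifyList(list(epochs = 100), gae)
  gan <- utils::modifyList(list(epochs = 30), gan)
  pipeline_config(K = K, seed = seed, gae = gae, gan = gan, ...)
}

load_pipeline_input <- function(input) {
  if (inherits(input, "ExpressionMatrix")) return(input)
  if (is.character(input) && length(input) == 1) return(load_expression(input))
  stop("`input` must be an ExpressionMatrix or a path")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# short stable hex digest (polynomial rolling hash) for manifests
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full two-stage clustering pipeline
#'
#' Executes preprocess -> pathway graph -> graph autoencoder -> K-means ->
#' high-confidence selection -> adversarial refinement (-> metrics when
#' truth labels are given). When `outdir` is set, every intermediate
#' artifact is persisted (relevance/cell-graph/adjacency as Matrix Market,
#' labels and loss traces as CSV, embeddings and model as RDS, plus a JSON
#' manifest with the config hash and seed).
#'
#' @param input an `ExpressionMatrix` (stage raw) or a path readable by
#'   [load_expression()].
#' @param config a [pipeline_config()].
#' @param truth optional ground-truth label vector for evaluation only.
#' @param outdir optional output directory.
#' @param verbose print one line per stage (default FALSE).
#' @param .allow_lambda_boundary internal: admit `lambda = 1` (used by
#'   [lambda_sweep()] for its cells-only endpoint).
#' @return list with `initial` (`ClusterAssignment`), `refined`
#'   (`RefinedAssignment` or NULL when the GAN is disabled), `labels_initial`,
#'   `labels_refined`, `embedding`, `confidence`, `gae_loss`, `gan_model`,
#'   `metrics` (list with `initial` and `refined` metric sets, when truth
#'   given), `config`.
#' @export
run_pipeline <- function(input, config, truth = NULL, outdir = NULL,
                         verbose = FALSE, .allow_lambda_boundary = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  x <- run_stage("load", load_pipeline_input(input))
  if (!is.null(truth) && length(truth) != ncol(x$values))
    stop("truth labels (", length(truth), ") do not match cell count (",
         ncol(x$values), ")")
  pp <- config$preprocess
  d <- run_stage("preprocess",
                 preprocess(x, min_cell_fraction = pp$min_cell_fraction,
                            n_top = pp$n_top_genes,
                            size_factor = pp$normalization$size_factor,
                            log1p = pp$normalization$log1p,
                            zscore = pp$normalization$zscore))
  say("preprocess: %d x %d -> %d x %d", nrow(x$values), ncol(x$values),
      nrow(d$values), ncol(d$values))
  g <- run_stage("pathway_graph",
                 build_pathway_graph(d, h = config$graph$h, k = config$graph$k,
                                     lam = config$graph$lambda,
                                     allow_boundary = .allow_lambda_boundary))
  say("graph: %d cell + %d gene nodes, h = %d, lambda = %g",
      g$adjacency$n_cells, g$adjacency$n_genes, g$h, config$graph$lambda)
  gcfg <- gae_config(layer_dims = config$gae$layer_dims,
                     leaky_slope = config$gae$leaky_slope,
                     epochs = config$gae$epochs,
                     learning_rate = config$gae$learning_rate,
                     batch_norm = config$gae$batch_norm,
                     decoder_layer = config$gae$decoder_layer,
                     seed = config$seed)
  fit <- run_stage("graph_autoencoder", train_gae(g$adjacency, g$features, gcfg))
  say("gae: loss %.3f -> %.3f over %d epochs", fit$loss_trace[1],
      utils::tail(fit$loss_trace, 1), gcfg$epochs)
  z_cells <- fit$embedding$Z[seq_len(fit$embedding$n_cells), , drop = FALSE]
  init <- run_stage("kmeans",
                    initial_clusters(z_cells, config$K, seed = config$seed + 1L))
  refined <- NULL; model <- NULL; conf <- NULL
  if (isTRUE(config$gan$enabled)) {
    conf <- run_stage("confidence",
                      select_high_confidence(z_cells, init,
                                             fraction = config$confidence$fraction))
    say("confidence: %d / %d cells selected", length(conf$indices), nrow(z_cells))
    ncfg <- gan_config(noise_dim = config$gan$noise_dim,
                       hidden_dims_g = config$gan$hidden_dims_g,
                       hidden_dims_d = config$gan$hidden_dims_d,
                       leaky_slope = config$gan$leaky_slope,
                       epochs = config$gan$epochs,
                       learning_rate = config$gan$learning_rate,
                       lr_halve_every = config$gan$lr_halve_every,
                       adam_betas = config$gan$adam_betas,
                       batch_size = config$gan$batch_size,
                       seed = config$seed + 2L)
    model <- run_stage("adversarial_refine",
                       train_gan(conf, config$K, ncfg, scale_reference = z_cells))
    refined <- run_stage("relabel", relabel_all(z_cells, model))
    say("gan: D loss %.3f, G loss %.3f at epoch %d",
        utils::tail(model$loss_d, 1), utils::tail(model$loss_g, 1), ncfg$epochs)
  }
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- list(initial = clustering_metrics(truth, init$labels))
    if (!is.null(refined))
      metrics$refined <- clustering_metrics(truth, refined$labels)
  }
  result <- list(initial = init, refined = refined,
                 labels_initial = init$labels,
                 labels_refined = if (!is.null(refined)) refined$labels else NULL,
                 embedding = fit$embedding, confidence = conf,
                 gae_loss = fit$loss_trace, gan_model = model,
                 metrics = metrics, config = config,
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(outdir)) persist_run(result, g, d, outdir)
  result
}

persist_run <- function(result, graph, d, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(graph$relevance$B, sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(outdir, "relevance_B.mtx"))
  Matrix::writeMM(graph$cell_graph$C, file.path(outdir, "cell_graph_C.mtx"))
  Matrix::writeMM(graph$adjacency$A, file.path(outdir, "adjacency_A.mtx"))
  saveRDS(result$embedding, file.path(outdir, "embedding.rds"))
  if (!is.null(result$gan_model))
    saveRDS(result$gan_model, file.path(outdir, "gan_model.rds"))
  labs <- data.frame(cell_id = d$cell_ids,
                     initial_label = result$labels_initial)
  if (!is.null(result$labels_refined)) {
    labs$refined_label <- result$labels_refined
    labs$max_class_probability <-
      apply(result$refined$class_probabilities, 1, max)
  }
  utils::write.csv(labs, file.path(outdir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(epoch = seq_along(result$gae_loss),
                              loss = result$gae_loss),
                   file.path(outdir, "gae_loss.csv"), row.names = FALSE)
  manifest <- list(config_hash = config_hash(unclass(result$config)),
                   seed = result$config$seed,
                   n_cells = length(result$labels_initial),
                   K = result$config$K,
                   package_version = as.character(utils::packageVersion("gaeclust")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Sweep the cell/gene mixing weight lambda
#'
#' Runs the full pipeline once per `lambda` value (shared seed and
#' configuration) and reports the refined-label ARI against the truth.
#' `lambda = 1` (cell graph only) is admitted here as an ablation endpoint
#' even though normal runs require `lambda` strictly inside (0, 1).
#'
#' @param input as in [run_pipeline()].
#' @param config a [pipeline_config()].
#' @param truth ground-truth labels (required).
#' @param grid lambda values, each in (0, 1]; default `seq(0.1, 1, by = 0.1)`.
#' @return data.frame with columns `lambda`, `ari` (refined; stage-one ARI
#'   when the GAN is disabled) and `ari_initial`.
#' @export
lambda_sweep <- function(input, config, truth, grid = seq(0.1, 1, by = 0.1)) {
  if (length(grid) == 0) stop("`grid` must be nonempty")
  if (any(grid <= 0 | grid > 1)) stop("lambda values must lie in (0, 1]")
  if (is.null(truth)) stop("`truth` labels are required for the sweep")
  x <- load_pipeline_input(input)
  rows <- lapply(grid, function(lam) {
    cfg <- config
    cfg$graph$lambda <- lam
    # lambda = 1 (cell graph only) is legal only as this ablation's endpoint
    res <- run_pipeline(x, cfg, truth = truth,
                        .allow_lambda_boundary = lam == 1)
    data.frame(lambda = lam,
               ari = if (!is.null(res$metrics$refined))
                 res$metrics$refined$ari else res$metrics$initial$ari,
               ari_initial = res$metrics$initial$ari)
  })
  do.call(rbind, rows)
}

#' Stage-one vs stage-two ablation
#'
#' Runs the pipeline once and reports the ARI of the preliminary K-means
#' labels (`no_gan`) and of the adversarially refined labels (`with_gan`)
#' from the same run.
#'
#' @param input as in [run_pipeline()].
#' @param config a [pipeline_config()] with the GAN enabled.
#' @param truth ground-truth labels (required).
#' @return data.frame with columns `variant` and `ari`.
#' @export
gan_ablation <- function(input, config, truth) {
  if (is.null(truth)) stop("`truth` labels are required for the ablation")
  if (!isTRUE(config$gan$enabled))
    stop("the ablation needs the GAN enabled")
  res <- run_pipeline(input, config, truth = truth)
  data.frame(variant = c("no_gan", "with_gan"),
             ari = c(res$metrics$initial$ari, res$metrics$refined$ari))
}
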