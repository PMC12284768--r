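#' Gene-by-cell expression matrix
#'
#' Lightweight container for a genes-by-cells expression matrix with row
#' (gene) and column (cell) identifiers and a `stage` flag recording how far
#' through the preprocessing pipeline the values have travelled:
#' `raw` -> `filtered` -> `selected` -> `normalized`.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, genes in rows,
#'   cells in columns. Must be nonnegative at stages before `normalized`.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per column.
#' @param stage one of `"raw"`, `"filtered"`, `"selected"`, `"normalized"`.
#'
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `stage`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, stage = "raw") {
  stage <- match.arg(stage, c("raw", "filtered", "selected", "normalized"))
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a base matrix or a Matrix sparse matrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") != length(gene_ids) (", length(gene_ids), ")")
  if (ncol(values) != length(cell_ids))
    stop("column count (", ncol(values), ") != length(cell_ids) (", length(cell_ids), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (stage != "normalized" && min_value(values) < 0)
    stop("negative entries are not allowed at stage '", stage, "'")
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids, stage = stage),
    class = "ExpressionMatrix"
  )
}

min_value <- function(v) {
  if (methods::is(v, "sparseMatrix")) {
    x <- v@x
    if (length(x) == 0) 0 else min(0, min(x))
  } else if (length(v) == 0) 0 else min(v)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [stage: %s, %s]\n",
              nrow(x$values), ncol(x$values), x$stage,
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

require_stage <- function(x, stage, op) {
  if (!inherits(x, "ExpressionMatrix"))
    stop(op, "() expects an ExpressionMatrix")
  if (x$stage != stage)
    stop(op, "() requires stage '", stage, "' but got '", x$stage,
         "'; the pipeline order is filter -> select -> normalize")
  invisible(x)
}

#' Load an expression matrix from disk
#'
#' Reads a genes-by-cells count matrix from one of the common plain-text
#' formats used for scRNA-seq:
#' \describe{
#'   \item{`mtx_dir`}{a directory holding `matrix.mtx` (Matrix Market
#'     triplets, genes x cells), `features.tsv` (or `genes.tsv`; first column
#'     = gene id) and `barcodes.tsv` (one cell barcode per line); `.gz`
#'     variants are accepted.}
#'   \item{`csv` / `tsv`}{a delimited table, first column gene ids, first row
#'     cell ids, remaining entries the expression values.}
#' }
#'
#' @param path file (csv/tsv) or directory (mtx_dir).
#' @param format `"mtx_dir"`, `"csv"` or `"tsv"`. Default guesses from `path`.
#' @return an [expression_matrix()] at stage `"raw"`; Matrix Market input is
#'   kept sparse.
#' @export
load_expression <- function(path, format = c("auto", "mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
    else if (grepl("\\.tsv(\\.gz)?$", path)) "tsv"
    else "csv"
  }
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("not a directory: ", path)
    locate <- function(names) {
      for (nm in names) {
        for (cand in file.path(path, c(nm, paste0(nm, ".gz")))) {
          if (file.exists(cand)) return(cand)
        }
      }
      stop("none of [", paste(names, collapse = ", "), "] found in ", path)
    }
    m <- Matrix::readMM(locate("matrix.mtx"))
    m <- methods::as(m, "CsparseMatrix")
    feat <- utils::read.delim(locate(c("features.tsv", "genes.tsv")),
                              header = FALSE, stringsAsFactors = FALSE)
    bc <- utils::read.delim(locate("barcodes.tsv"),
                            header = FALSE, stringsAsFactors = FALSE)
    if (nrow(feat) != nrow(m) || nrow(bc) != ncol(m))
      stop("annotation sizes (", nrow(feat), " features, ", nrow(bc),
           " barcodes) do not match matrix ", nrow(m), " x ", ncol(m),
           "; orientation cannot be resolved")
    expression_matrix(m, feat[[1]], bc[[1]], stage = "raw")
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (format == "tsv") "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    expression_matrix(m, rownames(tab), colnames(tab), stage = "raw")
  }
}

#' Write an expression matrix
#'
#' Inverse of [load_expression()]: `csv`/`tsv` write a dense delimited table;
#' `mtx_dir` writes `matrix.mtx` + `features.tsv` + `barcodes.tsv`.
#'
#' @param x an ExpressionMatrix.
#' @param path output file (csv/tsv) or directory (mtx_dir, created).
#' @param format `"mtx_dir"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(x$values, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(x$gene_ids, x$gene_ids),
                       file.path(path, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(x$cell_ids), file.path(path, "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    m <- as.matrix(x$values)
    df <- data.frame(gene = x$gene_ids, m, check.names = FALSE)
    colnames(df) <- c("gene", x$cell_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Remove genes expressed in too few cells
#'
#' Drops genes whose expression is nonzero in fewer than
#' `ceiling(min_cell_fraction * n_cells)` cells; genes exactly at the
#' threshold are retained. The default removes genes seen in less than 1% of
#' cells, which strips low-coverage noise genes before feature selection.
#'
#' @param x ExpressionMatrix at stage `"raw"`.
#' @param min_cell_fraction fraction of cells in (0, 1); default 0.01.
#' @return ExpressionMatrix at stage `"filtered"` with the same cells.
#' @export
filter_low_genes <- function(x, min_cell_fraction = 0.01) {
  require_stage(x, "raw", "filter_low_genes")
  if (!is.numeric(min_cell_fraction) || length(min_cell_fraction) != 1 ||
      min_cell_fraction <= 0 || min_cell_fraction >= 1)
    stop("`min_cell_fraction` must be a single number in (0, 1)")
  n <- ncol(x$values)
  thr <- ceiling(min_cell_fraction * n)
  nz <- gene_nonzero_counts(x$values)
  keep <- nz >= thr
  if (!any(keep))
    stop("all genes fall below the ", min_cell_fraction,
         " cell-fraction threshold; lower `min_cell_fraction`")
  expression_matrix(x$values[keep, , drop = FALSE], x$gene_ids[keep],
                    x$cell_ids, stage = "filtered")
}

gene_nonzero_counts <- function(v) {
  if (methods::is(v, "CsparseMatrix")) {
    # count stored nonzero entries per row (explicit zeros removed first)
    v <- Matrix::drop0(v)
    tabulate(v@i + 1L, nbins = nrow(v))
  } else {
    rowSums(as.matrix(v) != 0)
  }
}

#' Keep the most variable genes
#'
#' Retains the `n_top` genes with the largest per-gene variance across cells
#' (computed on the filtered values, before normalization), ordered by
#' descending variance. Variance ties at the boundary are broken by gene id
#' (lexicographic) so the selection is deterministic. If fewer than `n_top`
#' genes are present all are kept.
#'
#' @param x ExpressionMatrix at stage `"filtered"`.
#' @param n_top number of genes to keep; default 2000.
#' @return ExpressionMatrix at stage `"selected"`.
#' @export
select_top_variance_genes <- function(x, n_top = 2000) {
  require_stage(x, "filtered", "select_top_variance_genes")
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top < 1)
    stop("`n_top` must be a single integer >= 1")
  v <- gene_variances(x$values)
  ord <- order(-v, x$gene_ids)
  keep <- ord[seq_len(min(length(ord), n_top))]
  expression_matrix(x$values[keep, , drop = FALSE], x$gene_ids[keep],
                    x$cell_ids, stage = "selected")
}

gene_variances <- function(v) {
  n <- ncol(v)
  if (n < 2) return(rep(0, nrow(v)))
  if (methods::is(v, "sparseMatrix")) {
    mu <- Matrix::rowMeans(v)
    ex2 <- Matrix::rowMeans(v^2)
    (ex2 - mu^2) * n / (n - 1)
  } else {
    mu <- rowMeans(v)
    rowSums((v - mu)^2) / (n - 1)
  }
}

#' Normalize a selected expression matrix
#'
#' Applies the standard scRNA-seq normalization stack to the
#' variance-selected genes: (i) per-cell library-size scaling to the median
#' library size, (ii) `log1p`, (iii) per-gene z-score across cells (genes
#' with zero variance become all-zero rows). Each step can be switched off,
#' e.g. to substitute an alternative convention.
#'
#' @param x ExpressionMatrix at stage `"selected"`.
#' @param size_factor scale each cell to the median library size? default TRUE.
#' @param log1p apply `log(1 + v)`? default TRUE.
#' @param zscore per-gene standardization? default TRUE.
#' @return ExpressionMatrix at stage `"normalized"` (dense).
#' @export
normalize_expression <- function(x, size_factor = TRUE, log1p = TRUE, zscore = TRUE) {
  require_stage(x, "selected", "normalize_expression")
  m <- as.matrix(x$values)
  if (size_factor) {
    lib <- colSums(m)
    bad <- lib <= 0
    if (any(bad))
      stop("cells with zero total count: ", paste(x$cell_ids[bad], collapse = ", "))
    m <- sweep(m, 2, stats::median(lib) / lib, `*`)
  }
  if (log1p) m <- log1p(m)
  if (zscore) {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    m <- m - mu
    nz <- sd > 0
    m[nz, ] <- m[nz, , drop = FALSE] / sd[nz]
    m[!nz, ] <- 0
  }
  expression_matrix(m, x$gene_ids, x$cell_ids, stage = "normalized")
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper: [filter_low_genes()] then
#' [select_top_variance_genes()] then [normalize_expression()].
#'
#' @param x ExpressionMatrix at stage `"raw"`.
#' @param min_cell_fraction see [filter_low_genes()].
#' @param n_top see [select_top_variance_genes()].
#' @param size_factor,log1p,zscore see [normalize_expression()].
#' @return ExpressionMatrix at stage `"normalized"`.
#' @export
preprocess <- function(x, min_cell_fraction = 0.01, n_top = 2000,
                       size_factor = TRUE, log1p = TRUE, zscore = TRUE) {
  x |>
    filter_low_genes(min_cell_fraction) |>
    select_top_variance_genes(n_top) |>
    normalize_expression(size_factor = size_factor, log1p = log1p, zscore = zscore)
}
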