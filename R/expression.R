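#' Construct a validated expression matrix
#'
#' The pipeline's universal input: a genes x samples table of non-negative
#' abundances (FPKM-like; units are treated as opaque), a per-gene biotype,
#' and per-sample metadata assigning each sample to a patient and a time
#' point in hours after reperfusion (time 0 is the pre-intervention
#' baseline).
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). All entries must be
#'   finite and `>= 0`.
#' @param biotype character vector naming each gene's class, one of
#'   `"mRNA"`, `"lncRNA"`, `"miRNA"`; either named by gene id or in row
#'   order.
#' @param sample_meta data.frame with columns `sample`, `patient`,
#'   `time_hours`; one row per column of `values`.
#' @return an object of class `"ExpressionMatrix"`: a list with elements
#'   `values`, `biotype` (named), and `sample_meta`.
#' @export
expression_matrix <- function(values, biotype, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  gid <- rownames(values)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "non-finite or negative expression value at gene '%s', sample '%s'",
      gid[bad[1, 1]], colnames(values)[bad[1, 2]]), call. = FALSE)

  if (is.null(names(biotype))) {
    if (length(biotype) != nrow(values))
      stop("`biotype` length must match the number of genes", call. = FALSE)
    names(biotype) <- gid
  }
  missing_bt <- setdiff(gid, names(biotype))
  if (length(missing_bt) > 0)
    stop("genes without a biotype: ",
         paste(utils::head(missing_bt, 5), collapse = ", "), call. = FALSE)
  biotype <- biotype[gid]
  ok <- biotype %in% c("mRNA", "lncRNA", "miRNA")
  if (!all(ok))
    stop("unknown biotype '", biotype[!ok][1], "' for gene '",
         gid[!ok][1], "'", call. = FALSE)

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample", "patient", "time_hours")
  if (!all(need %in% names(sample_meta)))
    stop("`sample_meta` must have columns sample, patient, time_hours",
         call. = FALSE)
  sample_meta$sample <- as.character(sample_meta$sample)
  sample_meta$patient <- as.character(sample_meta$patient)
  sample_meta$time_hours <- as.numeric(sample_meta$time_hours)
  unknown <- setdiff(colnames(values), sample_meta$sample)
  if (length(unknown) > 0)
    stop("samples missing from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  key <- paste(sample_meta$patient, sample_meta$time_hours)
  if (anyDuplicated(key))
    stop("duplicate (patient, time) sample keys: ",
         key[duplicated(key)][1], call. = FALSE)

  structure(list(values = values, biotype = biotype,
                 sample_meta = sample_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  bt <- table(x$biotype)
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  biotypes:",
      paste(sprintf("%s=%d", names(bt), as.integer(bt)), collapse = ", "),
      "\n")
  cat("  patients:",
      paste(unique(x$sample_meta$patient), collapse = ", "), "\n")
  cat("  time points (h):",
      paste(sort(unique(x$sample_meta$time_hours)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene ids of an expression matrix, optionally restricted by biotype
#' @param expr an `ExpressionMatrix`.
#' @param biotype optional biotype to filter on.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(expr, biotype = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(biotype)) return(rownames(expr$values))
  names(expr$biotype)[expr$biotype == biotype]
}

#' Subset an expression matrix to a gene set
#' @param expr an `ExpressionMatrix`.
#' @param genes gene ids to keep (order preserved as given).
#' @return an `ExpressionMatrix` restricted to `genes`.
#' @export
subset_genes <- function(expr, genes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing) > 0)
    stop("genes not in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  expression_matrix(expr$values[genes, , drop = FALSE],
                    expr$biotype[genes], expr$sample_meta)
}

#' Encode the reperfusion-injury trait as a per-sample numeric vector
#'
#' The study design gives each sample a time in hours after reperfusion;
#' the trait quantifies reperfusion exposure for module-trait correlation.
#' The default `"binary"` encoding is 0 at the pre-intervention baseline
#' (time 0) and 1 at every post-reperfusion time point. Alternatives:
#' `"hours"` (the time itself) and `"log_hours"` (`log1p` of the time).
#'
#' @param expr an `ExpressionMatrix` (or its `sample_meta` data.frame).
#' @param encoding one of `"binary"`, `"hours"`, `"log_hours"`.
#' @return named numeric vector, one value per sample, with attribute
#'   `encoding_name`.
#' @export
trait_vector <- function(expr, encoding = c("binary", "hours", "log_hours")) {
  encoding <- match.arg(encoding)
  meta <- if (inherits(expr, "ExpressionMatrix")) expr$sample_meta else expr
  t <- meta$time_hours
  v <- switch(encoding,
              binary = as.numeric(t > 0),
              hours = t,
              log_hours = log1p(t))
  names(v) <- meta$sample
  if (stats::sd(v) == 0)
    stop("trait vector is constant under encoding '", encoding, "'",
         call. = FALSE)
  attr(v, "encoding_name") <- encoding
  v
}

# log(x + 1): the variance-stabilising transform used for all correlation
# computations on abundances.
log1 <- function(x) log(x + 1)
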