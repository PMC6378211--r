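#' Per-patient coefficient of variation across the time course
#'
#' For each gene, the sample standard deviation (n - 1 denominator) of
#' that patient's time-ordered abundances divided by their mean. CV is
#' computed on the raw abundance scale: it is scale-free there, which is
#' the property the screening relies on. Genes whose mean over the
#' patient's time points is zero have an undefined CV and are returned as
#' `NA` (downstream screening drops them with a logged count).
#'
#' @param expr an `ExpressionMatrix`.
#' @param patient_id one of the patients in `expr$sample_meta$patient`.
#' @return named numeric vector, gene id -> CV (`NA` where mean = 0).
#' @export
compute_cv <- function(expr, patient_id) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  meta <- expr$sample_meta
  if (!patient_id %in% meta$patient)
    stop("unknown patient '", patient_id, "'", call. = FALSE)
  sel <- meta$patient == patient_id
  if (sum(sel) < 2)
    stop("patient '", patient_id, "' has fewer than 2 time points",
         call. = FALSE)
  cols <- meta$sample[sel][order(meta$time_hours[sel])]
  x <- expr$values[, cols, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  stats::setNames(cv, rownames(x))
}

#' Screen genes by coefficient of variation, per patient
#'
#' Stage 1 of the pipeline. For every patient, genes with CV strictly
#' greater than `threshold` are retained and split by biotype into DELs
#' (lncRNAs) and DEMs (mRNAs); the strict inequality follows the
#' screening rule CV > 0.6. Genes with undefined CV (zero mean) are
#' dropped from that patient's candidate list.
#'
#' @param expr an `ExpressionMatrix`.
#' @param threshold non-negative CV cutoff (default 0.6).
#' @param verbose log per-patient counts with `message()`.
#' @return object of class `"CVReport"`: list with `cv` (per-patient named
#'   CV vectors), `retained` (per-patient lists with `DEL`, `DEM`, `all`),
#'   `n_undefined` (per patient), and `threshold`.
#' @export
screen_by_cv <- function(expr, threshold = 0.6, verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  patients <- unique(expr$sample_meta$patient)
  cv <- lapply(patients, function(p) compute_cv(expr, p))
  names(cv) <- patients
  retained <- lapply(cv, function(v) {
    keep <- names(v)[!is.na(v) & v > threshold]
    list(DEL = keep[expr$biotype[keep] == "lncRNA"],
         DEM = keep[expr$biotype[keep] == "mRNA"],
         all = keep)
  })
  n_undef <- vapply(cv, function(v) sum(is.na(v)), 0L)
  if (verbose)
    for (p in patients)
      message(sprintf(
        "patient %s: %d DELs, %d DEMs retained at CV > %g (%d undefined)",
        p, length(retained[[p]]$DEL), length(retained[[p]]$DEM),
        threshold, n_undef[[p]]))
  structure(list(cv = cv, retained = retained, n_undefined = n_undef,
                 threshold = threshold),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport (threshold CV > %g)\n", x$threshold))
  for (p in names(x$retained))
    cat(sprintf("  patient %s: %d DELs, %d DEMs\n", p,
                length(x$retained[[p]]$DEL), length(x$retained[[p]]$DEM)))
  invisible(x)
}

#' Intersect per-patient retained gene sets
#'
#' The cross-patient Venn step: genes retained in every enrolled patient,
#' reported separately for lncRNAs (shared DELs) and mRNAs (shared DEMs).
#'
#' @param report a `CVReport` from [screen_by_cv()] covering at least two
#'   patients.
#' @return list with `shared_DELs` and `shared_DEMs` (character vectors).
#' @export
intersect_patients <- function(report) {
  stopifnot(inherits(report, "CVReport"))
  if (length(report$retained) < 2)
    stop("intersection needs >= 2 patients; ",
         "with a single patient use its retained set directly",
         call. = FALSE)
  dels <- Reduce(intersect, lapply(report$retained, `[[`, "DEL"))
  dems <- Reduce(intersect, lapply(report$retained, `[[`, "DEM"))
  list(shared_DELs = dels, shared_DEMs = dems)
}

#' Pairwise sample correlation QC
#'
#' Squared Pearson correlation between every pair of samples on
#' log(x + 1)-transformed abundances; the matrix is symmetric with unit
#' diagonal. A zero-variance sample yields `NA` against every other
#' sample.
#'
#' @param expr an `ExpressionMatrix` with at least 2 samples.
#' @return samples x samples matrix of R-squared values.
#' @export
sample_correlation_qc <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (ncol(expr$values) < 2) stop("need >= 2 samples", call. = FALSE)
  lx <- log1(expr$values)
  r2 <- suppressWarnings(stats::cor(lx))^2
  diag(r2) <- 1
  r2
}
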