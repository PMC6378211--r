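#' @title Weighted co-expression network stage
#' @description Stage 2 of the pipeline: soft-threshold power selection
#'   against a scale-free topology criterion, unsigned topological
#'   overlap, module detection by average-linkage clustering with a
#'   static tree cut, module eigengenes and module-trait association.
#'   All correlations are Pearson on log(x + 1)-transformed abundances.
#' @name coexpression
NULL

# genes x genes absolute Pearson correlation on log1 scale; constant
# genes removed first (correlation undefined).
abs_cor_matrix <- function(expr, warn = TRUE) {
  lx <- log1(expr$values)
  sds <- apply(lx, 1, stats::sd)
  if (any(sds == 0)) {
    if (warn)
      warning(sum(sds == 0),
              " constant gene(s) removed before correlation",
              call. = FALSE)
    lx <- lx[sds > 0, , drop = FALSE]
  }
  abs(stats::cor(t(lx)))
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` for i != j (Pearson on log(x + 1)
#' values), zero diagonal. Unsigned, so positively and negatively
#' co-varying genes are connected alike.
#'
#' @param expr an `ExpressionMatrix`.
#' @param power soft-threshold exponent (>= 1).
#' @return symmetric genes x genes matrix with entries in `[0, 1]` and
#'   zero diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  ac <- abs_cor_matrix(expr)
  a <- ac^power
  diag(a) <- 0
  a
}

# Scale-free topology fit: R^2 of log10(mean k) vs log10(p(k)) over
# equal-width connectivity bins (the standard scale-free fit index).
scale_free_r2 <- function(k, n_bins = 10) {
  if (length(k) < 2 || stats::sd(k) == 0) return(0)
  bins <- cut(k, n_bins)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  ok <- !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 2) return(0)
  stats::cor(log10(mean_k[ok]), log10(freq[ok]))^2
}

#' Select the soft-threshold power
#'
#' Scans candidate powers; for each, builds the unsigned adjacency,
#' computes per-gene connectivity `k_i = sum_j a_ij`, and measures how
#' well the connectivity distribution follows a power law (scale-free
#' fit R-squared on the log-log bin plot). The selected power is the
#' smallest candidate reaching `target_r2`; if none does, the power with
#' the maximum R-squared is returned and the scan is flagged.
#'
#' @param expr an `ExpressionMatrix` (>= 10 genes, >= 3 samples).
#' @param powers integer candidates (default 1:20).
#' @param target_r2 scale-free fit target (default 0.9).
#' @return object of class `"PowerScan"`: list with `scan` (data.frame of
#'   `power`, `r2`, `mean_k`), `selected`, `flagged`, `target_r2`.
#' @export
select_power <- function(expr, powers = 1:20, target_r2 = 0.9) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (nrow(expr$values) < 10) stop("need >= 10 genes", call. = FALSE)
  if (ncol(expr$values) < 3) stop("need >= 3 samples", call. = FALSE)
  ac <- abs_cor_matrix(expr)
  diag(ac) <- 0
  scan <- data.frame(power = powers, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(ac^powers[i])
    scan$r2[i] <- scale_free_r2(k)
    scan$mean_k[i] <- mean(k)
  }
  hit <- which(scan$r2 >= target_r2)
  if (length(hit) > 0) {
    selected <- powers[hit[1]]
    flagged <- FALSE
  } else {
    selected <- powers[which.max(scan$r2)]
    flagged <- TRUE
  }
  structure(list(scan = scan, selected = selected, flagged = flagged,
                 target_r2 = target_r2),
            class = "PowerScan")
}

#' @export
print.PowerScan <- function(x, ...) {
  cat(sprintf("PowerScan: selected power = %d (target R^2 = %g%s)\n",
              x$selected, x$target_r2,
              if (x$flagged) ", target not reached - max-R^2 fallback"
              else ""))
  print(x$scan, row.names = FALSE)
  invisible(x)
}

#' Topological overlap matrix
#'
#' The neighbour-sharing-smoothed similarity of an unsigned weighted
#' adjacency:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j and `TOM_ii = 1`, where `k_i = sum_u a_iu`.
#'
#' @param adjacency square symmetric matrix, entries in `[0, 1]`, zero
#'   diagonal.
#' @return symmetric matrix with entries in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-12)
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(a < 0) || any(a > 1))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  if (any(diag(a) != 0))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  (tom + t(tom)) / 2  # symmetrise away floating-point drift
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`; the tree is cut statically at `cut_height` and branches
#' with at least `min_size` genes become modules, labelled `"M1"`,
#' `"M2"`, ... by decreasing size. Genes on smaller branches go to the
#' unassigned pool. This is a static simplification of the
#' dynamic-hybrid tree cut; the PAM-like refinement stage is
#' deliberately not implemented.
#'
#' @param tom topological overlap matrix with gene ids as dimnames.
#' @param min_size minimum module size (default 20).
#' @param cut_height static cut height on 1 - TOM (default 0.95).
#' @return object of class `"ModuleSet"`: list with `modules` (named list
#'   of member-id vectors), `unassigned`, `order` (dendrogram leaf
#'   order), `min_size`, `cut_height`.
#' @export
detect_modules <- function(tom, min_size = 20, cut_height = 0.95) {
  if (min_size < 2) stop("`min_size` must be >= 2", call. = FALSE)
  ids <- rownames(tom)
  if (is.null(ids)) stop("TOM must carry gene ids as dimnames",
                         call. = FALSE)
  if (nrow(tom) < 2) {
    return(structure(list(modules = list(), unassigned = ids,
                          order = ids, min_size = min_size,
                          cut_height = cut_height),
                     class = "ModuleSet"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  branch <- stats::cutree(hc, h = cut_height)
  sizes <- table(branch)
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big], as.integer(big))]
  modules <- stats::setNames(
    lapply(big, function(b) ids[branch == b]),
    if (length(big) > 0) paste0("M", seq_along(big)) else character(0))
  unassigned <- ids[!branch %in% as.integer(big)]
  structure(list(modules = modules, unassigned = unassigned,
                 order = ids[hc$order], min_size = min_size,
                 cut_height = cut_height),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d module(s) (min size %d, cut height %g)\n",
              length(x$modules), x$min_size, x$cut_height))
  for (m in names(x$modules))
    cat(sprintf("  %s: %d genes\n", m, length(x$modules[[m]])))
  cat(sprintf("  unassigned: %d genes\n", length(x$unassigned)))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression
#' submatrix: each member's log(x + 1) profile is centred and scaled to
#' unit variance across samples, and the eigengene is the first right
#' singular vector (one value per sample, unit Euclidean norm). The
#' sign is fixed so that the eigengene correlates non-negatively with
#' the mean standardized member profile; when that mean is numerically
#' zero (e.g. two perfectly anti-correlated members) the first member's
#' profile breaks the tie.
#'
#' @param expr an `ExpressionMatrix`.
#' @param members gene ids of the module (all present in `expr`).
#' @return list with `eigengene` (named per-sample vector, unit norm) and
#'   `var_explained` (share of variance carried by the first component).
#' @export
module_eigengene <- function(expr, members) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  x <- log1(subset_genes(expr, members)$values)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) x <- x[sds > 0, , drop = FALSE]
  if (nrow(x) == 0) stop("all module members are constant", call. = FALSE)
  z <- t(scale(t(x)))
  if (nrow(z) == 1) {
    v <- z[1, ] / sqrt(sum(z[1, ]^2))
    return(list(eigengene = stats::setNames(v, colnames(x)),
                var_explained = 1))
  }
  sv <- svd(z)
  v <- sv$v[, 1]
  mp <- colMeans(z)
  orient <- sum(v * mp)
  if (abs(orient) < 1e-10) orient <- sum(v * z[1, ])
  if (orient < 0) v <- -v
  list(eigengene = stats::setNames(v, colnames(x)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

# two-sided p for a Pearson correlation via the t distribution, n - 2 df
cor_p_value <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with the trait vector,
#' with a two-sided p-value from the t distribution on n - 2 degrees of
#' freedom. Modules are ranked by `|r|`. P-values are reported raw by
#' default, mirroring single-module significance reporting; set
#' `adjust = TRUE` for Benjamini-Hochberg adjustment across modules.
#'
#' @param expr an `ExpressionMatrix`.
#' @param modules a `ModuleSet` from [detect_modules()].
#' @param trait per-sample numeric trait (see [trait_vector()]); must not
#'   be constant.
#' @param adjust add a BH-adjusted `q` column (default FALSE).
#' @return data.frame with columns `module`, `size`, `r`, `p` (and `q`),
#'   ordered by decreasing `|r|`; eigengenes attached as the
#'   `"eigengenes"` attribute.
#' @export
module_trait_association <- function(expr, modules, trait,
                                     adjust = FALSE) {
  stopifnot(inherits(modules, "ModuleSet"))
  if (length(trait) != ncol(expr$values))
    stop("trait length must equal the sample count", call. = FALSE)
  if (stats::sd(trait) == 0) stop("trait is constant", call. = FALSE)
  n <- length(trait)
  egs <- lapply(modules$modules, function(m) module_eigengene(expr, m))
  r <- vapply(egs, function(e) stats::cor(e$eigengene, trait), 0)
  p <- vapply(r, cor_p_value, 0, n = n)
  out <- data.frame(module = names(modules$modules),
                    size = lengths(modules$modules),
                    r = unname(r), p = unname(p),
                    stringsAsFactors = FALSE)
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eigengenes") <- lapply(egs, `[[`, "eigengene")
  out
}
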