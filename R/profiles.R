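#' @title Short time-series model-profile clustering
#' @description Stage 3 of the pipeline: genes measured at a handful of
#'   ordered time points are clustered against an enumerable family of
#'   integer "model profiles" (anchored at 0, bounded unit changes), a
#'   deterministic subset of maximally distinct representatives is kept,
#'   each gene is assigned to its best-correlated representative, and
#'   profile significance is assessed by permuting every gene's
#'   time-point order.
#' @name timecourse_profiles
NULL

#' Enumerate candidate model profiles
#'
#' All integer time-course templates of length `T` starting at 0 whose
#' successive differences lie in `-c..c`, excluding the all-flat
#' profile; there are `(2c+1)^(T-1) - 1` of them. Profiles are ordered
#' lexicographically by their difference vectors and given ids
#' `"P001"`, `"P002"`, ...
#'
#' @param T number of time points (>= 2).
#' @param c unit-change bound (>= 1).
#' @return object of class `"ModelProfileSet"`: list with `profiles`
#'   (count x T integer matrix, rownames = profile ids), `T`, `c`.
#' @export
enumerate_profiles <- function(T = 5, c = 1) {
  if (T < 2) stop("`T` must be >= 2", call. = FALSE)
  if (c < 1) stop("`c` must be >= 1", call. = FALSE)
  steps <- -c:c
  diffs <- as.matrix(expand.grid(rep(list(steps), T - 1),
                                 KEEP.OUT.ATTRS = FALSE))
  # lexicographic order on the difference vectors, first step major
  ord <- do.call(order, as.data.frame(diffs))
  diffs <- diffs[ord, , drop = FALSE]
  flat <- rowSums(diffs != 0) == 0
  diffs <- diffs[!flat, , drop = FALSE]
  cums <- diffs
  if (ncol(cums) > 1)
    for (j in 2:ncol(cums)) cums[, j] <- cums[, j - 1] + diffs[, j]
  profiles <- cbind(0L, cums)
  storage.mode(profiles) <- "integer"
  rownames(profiles) <- sprintf("P%03d", seq_len(nrow(profiles)))
  colnames(profiles) <- NULL
  structure(list(profiles = profiles, T = T, c = c),
            class = "ModelProfileSet")
}

#' @export
print.ModelProfileSet <- function(x, ...) {
  cat(sprintf("ModelProfileSet: %d profiles (T = %d, c = %d)\n",
              nrow(x$profiles), x$T, x$c))
  invisible(x)
}

# 1 - Pearson correlation between profile vectors (all are non-constant)
profile_distance_matrix <- function(profiles) {
  1 - stats::cor(t(profiles))
}

#' Select maximally distinct representative profiles
#'
#' Greedy max-min selection under the distance `1 - cor`: start from the
#' most distant pair, then repeatedly add the profile whose minimum
#' distance to the chosen set is largest. Fully deterministic; ties are
#' broken by lexicographic profile id. If `m` is at least the number of
#' available profiles, all are returned.
#'
#' @param profile_set a `ModelProfileSet`.
#' @param m number of representatives to keep (default 50).
#' @return a `ModelProfileSet` restricted to the representatives, in id
#'   order.
#' @export
select_representatives <- function(profile_set, m = 50) {
  stopifnot(inherits(profile_set, "ModelProfileSet"))
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  p <- profile_set$profiles
  n <- nrow(p)
  if (m >= n) return(profile_set)
  d <- profile_distance_matrix(p)
  # seed pair: maximum distance, smallest (i, j) on ties
  best <- -Inf; bi <- bj <- 1L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] > best + 1e-12) { best <- d[i, j]; bi <- i; bj <- j }
  chosen <- c(bi, bj)
  while (length(chosen) < m) {
    rest <- setdiff(seq_len(n), chosen)
    mind <- apply(d[rest, chosen, drop = FALSE], 1, min)
    chosen <- c(chosen, rest[which.max(mind)])  # first max = lowest id
  }
  out <- profile_set
  out$profiles <- p[sort(chosen), , drop = FALSE]
  out
}

#' Per-gene mean time courses
#'
#' One series per gene: the mean over patients of log(x + 1) abundance
#' at each study time point, in time order.
#'
#' @param expr an `ExpressionMatrix`.
#' @return genes x T numeric matrix; colnames are the time points.
#' @export
gene_timecourses <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  meta <- expr$sample_meta
  tps <- sort(unique(meta$time_hours))
  lx <- log1(expr$values)
  tc <- vapply(tps, function(tp) {
    rowMeans(lx[, meta$sample[meta$time_hours == tp], drop = FALSE])
  }, numeric(nrow(lx)))
  colnames(tc) <- tps
  tc
}

# subtract the time-0 (first-column) value so series describe change
# relative to the pre-reperfusion baseline
anchor_series <- function(tc) tc - tc[, 1]

# correlation of each anchored series (rows of s) with each profile
# (rows of p); rows with zero variance get NA
series_profile_cor <- function(s, p) {
  rs <- function(m) {
    mu <- rowMeans(m)
    ctr <- m - mu
    nrm <- sqrt(rowSums(ctr^2))
    list(z = ctr / ifelse(nrm > 0, nrm, 1), ok = nrm > 0)
  }
  a <- rs(s); b <- rs(p)
  cc <- a$z %*% t(b$z)
  cc[!a$ok, ] <- NA_real_
  cc
}

#' Assign genes to model profiles
#'
#' Each gene's anchored mean time course is assigned to the
#' representative profile with the highest Pearson correlation; ties go
#' to the lowest profile id; genes with zero-variance series are
#' excluded.
#'
#' @param expr an `ExpressionMatrix` (or a precomputed
#'   [gene_timecourses()] matrix).
#' @param representatives a `ModelProfileSet` of representatives whose
#'   `T` matches the number of study time points.
#' @return data.frame with columns `gene_id`, `profile_id`, `cor`.
#' @export
assign_genes <- function(expr, representatives) {
  stopifnot(inherits(representatives, "ModelProfileSet"))
  tc <- if (inherits(expr, "ExpressionMatrix")) gene_timecourses(expr)
        else expr
  if (is.null(rownames(tc)))
    rownames(tc) <- paste0("gene", seq_len(nrow(tc)))
  p <- representatives$profiles
  if (ncol(tc) != ncol(p))
    stop(sprintf("series have %d time points but profiles have %d",
                 ncol(tc), ncol(p)), call. = FALSE)
  s <- anchor_series(tc)
  cc <- series_profile_cor(s, p)
  ok <- !is.na(cc[, 1])
  cc <- cc[ok, , drop = FALSE]
  if (nrow(cc) == 0)
    return(data.frame(gene_id = character(0), profile_id = character(0),
                      cor = numeric(0), stringsAsFactors = FALSE))
  best <- max.col(cc, ties.method = "first")  # columns are in id order
  data.frame(gene_id = rownames(cc),
             profile_id = rownames(p)[best],
             cor = cc[cbind(seq_len(nrow(cc)), best)],
             stringsAsFactors = FALSE)
}

# assignment counts per representative profile, in profile order
assignment_counts <- function(assignments, representatives) {
  ids <- rownames(representatives$profiles)
  cnt <- table(factor(assignments$profile_id, levels = ids))
  stats::setNames(as.integer(cnt), ids)
}

#' Permutation significance of profile assignments
#'
#' The null hypothesis is that a gene's temporal order is arbitrary:
#' each gene's time-point order is permuted independently, series are
#' re-anchored and re-assigned, and each profile's observed member
#' count is compared with its null counts. The one-sided p-value uses
#' add-one smoothing, `p = (#{null >= observed} + 1) / (B + 1)`, so
#' p-values lie in (0, 1].
#'
#' @param expr an `ExpressionMatrix` (or a [gene_timecourses()] matrix).
#' @param representatives a `ModelProfileSet`.
#' @param n_permutations number of permutations B (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05, on the raw permutation p).
#' @return data.frame of class `"ProfileSignificance"` with one row per
#'   representative: `profile_id`, `profile` (comma-joined template),
#'   `count`, `expected`, `p`, `significant`; gene assignments attached
#'   as the `"assignments"` attribute.
#' @export
profile_significance <- function(expr, representatives,
                                 n_permutations = 1000, seed = NULL,
                                 alpha = 0.05) {
  if (n_permutations < 1) stop("`n_permutations` must be >= 1",
                               call. = FALSE)
  tc <- if (inherits(expr, "ExpressionMatrix")) gene_timecourses(expr)
        else expr
  obs_assign <- assign_genes(tc, representatives)
  obs <- assignment_counts(obs_assign, representatives)
  if (!is.null(seed)) set.seed(seed)
  Tn <- ncol(tc)
  G <- nrow(tc)
  ge <- matrix(0L, nrow = n_permutations, ncol = length(obs))
  null_sum <- numeric(length(obs))
  for (b in seq_len(n_permutations)) {
    perm <- t(apply(tc, 1, function(row) row[sample.int(Tn)]))
    cnt <- assignment_counts(assign_genes(perm, representatives),
                             representatives)
    null_sum <- null_sum + cnt
    ge[b, ] <- as.integer(cnt >= obs)
  }
  p <- (colSums(ge) + 1) / (n_permutations + 1)
  out <- data.frame(
    profile_id = names(obs),
    profile = apply(representatives$profiles, 1, paste, collapse = ","),
    count = as.integer(obs),
    expected = null_sum / n_permutations,
    p = p,
    significant = p < alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "assignments") <- obs_assign
  class(out) <- c("ProfileSignificance", "data.frame")
  out
}

#' One-call time-profile clustering
#'
#' Convenience wrapper: enumerate the profile family, select
#' representatives, assign genes and compute permutation significance.
#'
#' @param expr an `ExpressionMatrix`.
#' @param c unit-change bound (default 1).
#' @param m number of representatives (default 50).
#' @param n_permutations permutations for significance (default 1000).
#' @param seed optional integer seed.
#' @param alpha significance level (default 0.05).
#' @return a [profile_significance()] table.
#' @export
cluster_profiles <- function(expr, c = 1, m = 50, n_permutations = 1000,
                             seed = NULL, alpha = 0.05) {
  tc <- gene_timecourses(expr)
  reps <- select_representatives(enumerate_profiles(T = ncol(tc), c = c),
                                 m = m)
  profile_significance(tc, reps, n_permutations = n_permutations,
                       seed = seed, alpha = alpha)
}
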