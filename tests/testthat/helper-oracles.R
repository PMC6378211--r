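# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use the slowest, most literal
# formulation of each quantity.

# triple-loop topological overlap, the literal formula
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# triple loop over every (lncRNA, miRNA, mRNA) combination
assemble_brute <- function(coexpressed, pairs) {
  lm <- pairs[pairs$type == "lncRNA-miRNA", ]
  mm <- pairs[pairs$type == "miRNA-mRNA", ]
  Ls <- unique(c(coexpressed$lncRNA_id, lm$source))
  mis <- unique(c(lm$target, mm$source))
  Ms <- unique(c(coexpressed$mRNA_id, mm$target))
  co_key <- paste(coexpressed$lncRNA_id, coexpressed$mRNA_id)
  lm_key <- paste(lm$source, lm$target)
  mm_key <- paste(mm$source, mm$target)
  rows <- list()
  for (L in Ls) for (mi in mis) for (M in Ms) {
    if (paste(L, M) %in% co_key && paste(L, mi) %in% lm_key &&
        paste(mi, M) %in% mm_key)
      rows[[length(rows) + 1]] <- c(L, mi, M)
  }
  if (length(rows) == 0)
    return(data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                      mRNA_id = character(0), stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("lncRNA_id", "miRNA_id", "mRNA_id")
  df
}

# canonical sorted key set for triplet tables
triplet_keys <- function(df)
  sort(paste(df$lncRNA_id, df$miRNA_id, df$mRNA_id))

# hypergeometric upper tail by enumerating every size-n draw
hyper_brute <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # universe ordered so the first K are "in"
  mean(hits >= k)
}

# count profiles anchored at 0 with steps in -c..c, flat excluded, by
# explicit recursion over the remaining positions
count_profiles_rec <- function(T, c) {
  rec <- function(remaining, any_step) {
    if (remaining == 0) return(as.integer(any_step))
    total <- 0L
    for (s in -c:c) total <- total + rec(remaining - 1, any_step || s != 0)
    total
  }
  rec(T - 1, FALSE)
}

# build a small ExpressionMatrix from a genes x samples matrix of
# values, two patients, equally many time points per patient
make_expr <- function(values, biotype = NULL,
                      time_points = c(0, 2, 12, 24, 72)) {
  S <- ncol(values)
  stopifnot(S %% length(time_points) == 0)
  n_pat <- S / length(time_points)
  meta <- data.frame(
    sample = paste0("s", seq_len(S)),
    patient = rep(paste0("P", seq_len(n_pat)),
                  each = length(time_points)),
    time_hours = rep(time_points, n_pat), stringsAsFactors = FALSE)
  colnames(values) <- meta$sample
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(biotype))
    biotype <- stats::setNames(rep("mRNA", nrow(values)),
                               rownames(values))
  expression_matrix(values, biotype, meta)
}

# random non-negative expression values (log-normal-ish)
random_values <- function(n_genes, n_samples)
  matrix(exp(stats::rnorm(n_genes * n_samples, 2, 1)),
         nrow = n_genes)

# exact null distribution of a profile's assigned count when every
# gene's time order is permuted independently and uniformly:
# Poisson-binomial over per-gene assignment probabilities
profile_null_exact <- function(tc, representatives) {
  Tn <- ncol(tc)
  perms <- gtools_permutations(Tn)
  ids <- rownames(representatives$profiles)
  prob <- matrix(0, nrow(tc), length(ids),
                 dimnames = list(rownames(tc), ids))
  for (g in seq_len(nrow(tc))) {
    for (r in seq_len(nrow(perms))) {
      s <- matrix(tc[g, perms[r, ]], nrow = 1)
      a <- assign_genes(s, representatives)
      if (nrow(a) == 1)
        prob[g, a$profile_id] <- prob[g, a$profile_id] + 1 / nrow(perms)
    }
  }
  prob
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# P(X >= k) for a Poisson-binomial with success probabilities p, by
# convolution
pois_binom_upper <- function(p, k) {
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  sum(dist[(k + 1):length(dist)])
}
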