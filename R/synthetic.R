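#' @title Synthetic time-course ceRNA datasets
#' @description A seeded generator that emulates the study design the
#'   pipeline targets: a small patient cohort sampled at a handful of
#'   time points around a reperfusion event, a mixed
#'   mRNA/lncRNA/miRNA gene universe, a planted trait-correlated
#'   co-expression module, planted temporal model profiles, and planted
#'   ceRNA triplets wired into the emitted pair files. Everything the
#'   pipeline needs is produced in one call, together with the ground
#'   truth needed to score recovery.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the target study design: 2 patients sampled at 0
#' (pre-reperfusion baseline), 2, 12, 24 and 72 hours, an FPKM-like
#' right-skewed abundance distribution, one planted 30-gene module
#' whose summary profile correlates 0.8 with reperfusion exposure, and
#' 5 planted ceRNA triplets.
#'
#' @param n_patients number of patients (default 2).
#' @param time_points strictly increasing hours, first element 0
#'   (default `c(0, 2, 12, 24, 72)`).
#' @param n_mrna,n_lncrna,n_mirna gene-universe sizes (defaults 300,
#'   100, 50).
#' @param n_planted_modules planted co-expression modules (default 1).
#' @param planted_module_size genes per planted module, >= 20
#'   (default 30).
#' @param planted_trait_correlation target |correlation| between each
#'   planted module's latent trajectory and the trait, in `[0, 1]`
#'   (default 0.8).
#' @param n_planted_triplets planted (lncRNA, miRNA, mRNA) triplets
#'   (default 5). Their lncRNA/mRNA endpoints live inside the first
#'   planted module so they are both co-expressed and trait-associated.
#' @param n_planted_profile_genes genes following planted temporal
#'   model profiles (default 40).
#' @param noise_sigma std-dev of the log-scale noise, >= 0
#'   (default 0.4).
#' @param baseline_log_mean,baseline_log_sd log-scale baseline abundance
#'   distribution (defaults 2 and 1).
#' @param n_decoy_pairs random non-planted pairs added per pair type
#'   (default 200).
#' @param trait_encoding trait encoding used for calibration and in the
#'   emitted trait vector (default `"binary"`; see [trait_vector()]).
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return validated list of class `"SimulationConfig"`.
#' @export
sim_config <- function(n_patients = 2,
                       time_points = c(0, 2, 12, 24, 72),
                       n_mrna = 300, n_lncrna = 100, n_mirna = 50,
                       n_planted_modules = 1,
                       planted_module_size = 30,
                       planted_trait_correlation = 0.8,
                       n_planted_triplets = 5,
                       n_planted_profile_genes = 40,
                       noise_sigma = 0.4,
                       baseline_log_mean = 2, baseline_log_sd = 1,
                       n_decoy_pairs = 200,
                       trait_encoding = "binary",
                       seed = 1) {
  cfg <- list(n_patients = n_patients, time_points = time_points,
              n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_planted_modules = n_planted_modules,
              planted_module_size = planted_module_size,
              planted_trait_correlation = planted_trait_correlation,
              n_planted_triplets = n_planted_triplets,
              n_planted_profile_genes = n_planted_profile_genes,
              noise_sigma = noise_sigma,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              n_decoy_pairs = n_decoy_pairs,
              trait_encoding = trait_encoding,
              seed = seed)
  if (length(time_points) < 2 || time_points[1] != 0 ||
      any(diff(time_points) <= 0))
    stop("time_points must be strictly increasing and start at 0",
         call. = FALSE)
  counts <- c(n_patients, n_mrna, n_lncrna, n_mirna, n_planted_modules,
              n_planted_triplets, n_planted_profile_genes, n_decoy_pairs)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (n_planted_modules > 0 && planted_module_size < 20)
    stop("planted_module_size must be >= 20", call. = FALSE)
  if (planted_trait_correlation < 0 || planted_trait_correlation > 1)
    stop("planted_trait_correlation must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  n_mod_lnc <- if (n_planted_modules > 0) n_planted_triplets else 0
  need_lnc <- n_mod_lnc + if (n_planted_modules == 0) n_planted_triplets
                          else 0
  need_mrna <- n_planted_modules * planted_module_size - n_mod_lnc +
    if (n_planted_modules == 0) n_planted_triplets else 0
  if (need_lnc > n_lncrna || need_mrna + n_planted_profile_genes > n_mrna ||
      n_planted_triplets > n_mirna)
    stop("planted counts exceed the gene universe", call. = FALSE)
  if (n_planted_modules > 0 &&
      2 * n_planted_triplets > planted_module_size)
    stop("planted_module_size too small to host the planted triplets",
         call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

# planted log-scale signal genes sit this far above the baseline mean,
# keeping their latent abundance positive so the signal survives the
# non-negativity floor of the abundance scale
SIGNAL_BASELINE_BOOST <- 4

# z-score with exact zero mean / unit sample sd
zscore <- function(v) as.numeric(scale(v))

#' Generate a complete synthetic dataset
#'
#' Abundances are built on the log(1 + x) scale: each gene's latent
#' series is baseline + planted signal + Gaussian noise
#' (`noise_sigma`), floored at 0 and mapped through `expm1`, giving
#' non-negative right-skewed values whose log(1 + x) transform - the
#' scale every downstream correlation uses - recovers the latent
#' series wherever it is positive. Background genes have constant
#' expectation over time. Planted-module genes share a latent
#' trajectory built as `rho * z(trait) + sqrt(1 - rho^2) * u` with `u`
#' orthogonalised against the trait, so the trajectory's sample
#' correlation with the trait equals `planted_trait_correlation`
#' exactly. Planted-profile genes follow integer model profiles
#' (unit-change bound 1) scaled per gene. Planted triplets appear in
#' the emitted pair files and their lncRNA/mRNA endpoints share a
#' latent trajectory (the first module's, when a module exists).
#'
#' @param config a [sim_config()].
#' @return list of class `"SyntheticDataset"` with elements `expr`
#'   (`ExpressionMatrix`), `pairs` (`TargetPairSet`), `annotation`
#'   (`AnnotationMap`), `trait` (named numeric), and `truth` (list:
#'   `planted_module_members`, `planted_profiles`, `planted_triplets`,
#'   `trait`).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  tp <- config$time_points
  patients <- sprintf("P%d", seq_len(config$n_patients))
  meta <- data.frame(
    sample = as.vector(t(outer(patients, tp,
                               function(p, t) sprintf("%s_T%03d", p, t)))),
    patient = rep(patients, each = length(tp)),
    time_hours = rep(tp, times = config$n_patients),
    stringsAsFactors = FALSE)
  S <- nrow(meta)

  mrna <- sprintf("MRNA_%04d", seq_len(config$n_mrna))
  lnc <- sprintf("LNC_%04d", seq_len(config$n_lncrna))
  mir <- sprintf("MIR_%04d", seq_len(config$n_mirna))
  genes <- c(mrna, lnc, mir)
  biotype <- stats::setNames(
    rep(c("mRNA", "lncRNA", "miRNA"),
        c(config$n_mrna, config$n_lncrna, config$n_mirna)), genes)

  trait <- trait_vector(meta, config$trait_encoding)
  tz <- zscore(trait)
  rho <- config$planted_trait_correlation

  eta <- matrix(stats::rnorm(length(genes), config$baseline_log_mean,
                             config$baseline_log_sd),
                nrow = length(genes), ncol = S,
                dimnames = list(genes, meta$sample))

  # --- planted trait-correlated modules -------------------------------
  k_trip <- config$n_planted_triplets
  module_members <- list()
  next_mrna <- 1L
  latent1 <- NULL
  for (m in seq_len(config$n_planted_modules)) {
    n_lnc_m <- if (m == 1) k_trip else 0L
    n_mrna_m <- config$planted_module_size - n_lnc_m
    members <- c(if (n_lnc_m > 0) lnc[seq_len(n_lnc_m)],
                 mrna[next_mrna:(next_mrna + n_mrna_m - 1)])
    next_mrna <- next_mrna + n_mrna_m
    u <- stats::rnorm(S)
    u <- u - mean(u)
    u <- u - tz * sum(u * tz) / sum(tz * tz)   # orthogonal to the trait
    if (sqrt(sum(u^2)) < 1e-8) u <- rep(0, S) else u <- zscore(u)
    latent <- rho * tz + sqrt(1 - rho^2) * u
    if (m == 1) latent1 <- latent
    loading <- stats::runif(length(members), 0.8, 1.6)
    eta[members, ] <- config$baseline_log_mean + SIGNAL_BASELINE_BOOST +
      outer(loading, latent)
    module_members[[m]] <- members
  }

  # --- planted temporal profiles --------------------------------------
  planted_profiles <- list()
  if (config$n_planted_profile_genes > 0) {
    fam <- enumerate_profiles(T = length(tp), c = 1)$profiles
    prof_genes <- mrna[next_mrna:(next_mrna +
                                    config$n_planted_profile_genes - 1)]
    next_mrna <- next_mrna + config$n_planted_profile_genes
    pick <- sample.int(nrow(fam), length(prof_genes), replace = TRUE)
    amp <- stats::runif(length(prof_genes), 0.5, 1.0)
    time_of <- match(meta$time_hours, tp)
    for (i in seq_along(prof_genes)) {
      planted_profiles[[prof_genes[i]]] <- fam[pick[i], ]
      eta[prof_genes[i], ] <- config$baseline_log_mean +
        SIGNAL_BASELINE_BOOST + amp[i] * fam[pick[i], time_of]
    }
  }

  # --- planted triplets ------------------------------------------------
  # The lncRNA and mRNA of a triplet follow one and the same latent
  # series (baseline + trajectory + temporal noise), the idealised ceRNA
  # co-expression signature; attrition of planted triplets downstream
  # comes from the CV screen and the trait-association gate, not from
  # decoupled measurement noise within a pair.
  trip_latent <- list()
  if (k_trip > 0) {
    trip <- data.frame(lncRNA_id = lnc[seq_len(k_trip)],
                       miRNA_id = mir[seq_len(k_trip)],
                       mRNA_id = mrna[seq_len(k_trip)],
                       stringsAsFactors = FALSE)
    for (i in seq_len(k_trip)) {
      v <- if (config$n_planted_modules > 0) latent1
           else zscore(stats::rnorm(S))
      b <- stats::runif(1, 1.0, 1.6)
      series <- config$baseline_log_mean + SIGNAL_BASELINE_BOOST +
        b * v + stats::rnorm(S, 0, config$noise_sigma)
      trip_latent[[trip$lncRNA_id[i]]] <- series
      trip_latent[[trip$mRNA_id[i]]] <- series
    }
  } else {
    trip <- data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                       mRNA_id = character(0), stringsAsFactors = FALSE)
  }

  # --- noise and mapping to the abundance scale ------------------------
  if (config$noise_sigma > 0)
    eta <- eta + matrix(stats::rnorm(length(eta), 0, config$noise_sigma),
                        nrow = nrow(eta))
  for (g in names(trip_latent)) eta[g, ] <- trip_latent[[g]]
  values <- expm1(pmax(eta, 0))
  expr <- expression_matrix(values, biotype, meta)

  # --- pair files: planted edges plus random decoys --------------------
  decoy <- function(src_pool, tgt_pool, n, type) {
    if (n == 0 || length(src_pool) == 0 || length(tgt_pool) == 0)
      return(NULL)
    data.frame(source = sample(src_pool, n, replace = TRUE),
               target = sample(tgt_pool, n, replace = TRUE),
               type = type, stringsAsFactors = FALSE)
  }
  nd <- config$n_decoy_pairs
  pr <- rbind(
    data.frame(source = trip$lncRNA_id, target = trip$mRNA_id,
               type = rep("lncRNA-mRNA", nrow(trip)),
               stringsAsFactors = FALSE),
    decoy(lnc, mrna, nd, "lncRNA-mRNA"),
    data.frame(source = trip$lncRNA_id, target = trip$miRNA_id,
               type = rep("lncRNA-miRNA", nrow(trip)),
               stringsAsFactors = FALSE),
    decoy(lnc, mir, nd, "lncRNA-miRNA"),
    data.frame(source = trip$miRNA_id, target = trip$mRNA_id,
               type = rep("miRNA-mRNA", nrow(trip)),
               stringsAsFactors = FALSE),
    decoy(mir, mrna, nd, "miRNA-mRNA"))
  pairs <- suppressWarnings(target_pairs(pr$source, pr$target, pr$type))

  # --- annotation map: a designated stress-response term on two planted
  #     mRNAs, plus random background terms ----------------------------
  terms <- list()
  term_names <- character(0)
  stress_genes <- if (nrow(trip) >= 2) trip$mRNA_id[1:2] else
    mrna[seq_len(min(2, length(mrna)))]
  terms[["T0001"]] <- unique(c(stress_genes,
                               sample(mrna, min(8, length(mrna)))))
  term_names["T0001"] <- "cellular response to stress"
  for (i in 2:20) {
    id <- sprintf("T%04d", i)
    terms[[id]] <- sample(mrna, min(sample(5:25, 1), length(mrna)))
    term_names[id] <- sprintf("background process %d", i - 1)
  }
  annotation <- annotation_map(terms, term_names, universe = genes)

  truth <- list(planted_module_members = module_members,
                planted_profiles = planted_profiles,
                planted_triplets = trip,
                trait = trait)
  structure(list(expr = expr, pairs = pairs, annotation = annotation,
                 trait = trait, truth = truth, config = config),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset (seed ", x$config$seed, ")\n", sep = "")
  print(x$expr)
  cat(sprintf("  planted: %d module(s), %d profile gene(s), %d triplet(s)\n",
              length(x$truth$planted_module_members),
              length(x$truth$planted_profiles),
              nrow(x$truth$planted_triplets)))
  invisible(x)
}

#' Write a synthetic dataset to a directory in the pipeline's formats
#'
#' Emits `expression.tsv`, `samples.tsv`, `pairs.tsv`,
#' `annotation.gmt`, `trait.tsv` and a `ground_truth.tsv` sidecar
#' (planted gene roles in long form).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  write_pairs(dataset$pairs, file.path(dir, "pairs.tsv"))
  write_annotation(dataset$annotation, file.path(dir, "annotation.gmt"))
  utils::write.table(
    data.frame(sample = names(dataset$trait),
               trait = as.numeric(dataset$trait)),
    file.path(dir, "trait.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- dataset$truth
  rows <- rbind(
    if (length(truth$planted_module_members) > 0)
      do.call(rbind, lapply(seq_along(truth$planted_module_members),
        function(i) data.frame(role = sprintf("module_%d", i),
                               gene_id = truth$planted_module_members[[i]],
                               detail = "",
                               stringsAsFactors = FALSE))),
    if (length(truth$planted_profiles) > 0)
      data.frame(role = "profile",
                 gene_id = names(truth$planted_profiles),
                 detail = vapply(truth$planted_profiles, paste, "",
                                 collapse = ","),
                 stringsAsFactors = FALSE),
    if (nrow(truth$planted_triplets) > 0)
      data.frame(role = "triplet",
                 gene_id = truth$planted_triplets$lncRNA_id,
                 detail = paste(truth$planted_triplets$miRNA_id,
                                truth$planted_triplets$mRNA_id,
                                sep = ","),
                 stringsAsFactors = FALSE))
  utils::write.table(rows, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Hand-checkable toy dataset
#'
#' A hard-coded 14-gene, 2-patient x 5-time-point dataset used in
#' documentation and exact-value tests: a constant gene (`flat1`, CV
#' 0), a ramp gene (`ramp1`, per-patient values 1, 2, 3, 4, 10; sample
#' CV 0.8839 to 4 d.p.), one obvious co-expression module, and exactly
#' two planted ceRNA triplets (`L1`-`mi1`-`M1`, `L2`-`mi2`-`M2`) wired
#' into the pair file.
#'
#' @return list with `expr`, `pairs`, `annotation`, `trait`.
#' @export
toy_fixture <- function() {
  tp <- c(0, 2, 12, 24, 72)
  meta <- data.frame(
    sample = as.vector(t(outer(c("P1", "P2"), tp,
                               function(p, t) sprintf("%s_T%03d", p, t)))),
    patient = rep(c("P1", "P2"), each = 5),
    time_hours = rep(tp, 2), stringsAsFactors = FALSE)
  per_patient <- function(v) rep(v, 2)
  rows <- rbind(
    flat1 = per_patient(c(5, 5, 5, 5, 5)),
    ramp1 = per_patient(c(1, 2, 3, 4, 10)),
    L1    = per_patient(c(1, 2, 4, 8, 16)),
    M1    = per_patient(c(1, 2, 4, 8, 16)),
    L2    = per_patient(c(10, 5, 2, 1, 1)),
    M2    = per_patient(c(10, 5, 2, 1, 1)),
    M3    = per_patient(c(2, 4, 8, 16, 32)),
    M4    = per_patient(c(20, 10, 4, 2, 2)),
    M5    = per_patient(c(3, 3, 3, 3, 4)),
    bg1   = per_patient(c(7, 6, 7, 6, 7)),
    bg2   = per_patient(c(2, 2, 3, 2, 2)),
    mi1   = per_patient(c(1, 1, 1, 1, 1)),
    mi2   = per_patient(c(1, 1, 1, 1, 1)),
    mi3   = per_patient(c(1, 1, 1, 1, 1)))
  colnames(rows) <- meta$sample
  biotype <- c(flat1 = "mRNA", ramp1 = "mRNA", L1 = "lncRNA",
               M1 = "mRNA", L2 = "lncRNA", M2 = "mRNA", M3 = "mRNA",
               M4 = "mRNA", M5 = "mRNA", bg1 = "mRNA", bg2 = "lncRNA",
               mi1 = "miRNA", mi2 = "miRNA", mi3 = "miRNA")
  expr <- expression_matrix(rows, biotype, meta)
  pairs <- target_pairs(
    source = c("L1", "L2", "L2", "L1", "L2", "mi1", "mi2", "mi3"),
    target = c("M1", "M2", "M3", "mi1", "mi2", "M1", "M2", "M4"),
    type = c("lncRNA-mRNA", "lncRNA-mRNA", "lncRNA-mRNA",
             "lncRNA-miRNA", "lncRNA-miRNA",
             "miRNA-mRNA", "miRNA-mRNA", "miRNA-mRNA"))
  annotation <- annotation_map(
    terms = list(T0001 = c("M1", "M2"),
                 T0002 = c("M3", "M4", "M5", "ramp1")),
    term_names = c(T0001 = "cellular response to stress",
                   T0002 = "background process"),
    universe = rownames(rows))
  list(expr = expr, pairs = pairs, annotation = annotation,
       trait = trait_vector(expr))
}
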