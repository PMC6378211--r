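#' Run the full ceRNA time-course inference pipeline in memory
#'
#' The package's main entry point. Executes the five analysis stages in
#' order on a single expression matrix:
#' \enumerate{
#'   \item per-patient CV screening and cross-patient intersection
#'     (shared DELs/DEMs), plus sample-correlation QC;
#'   \item weighted co-expression analysis of the shared set: power
#'     selection, topological overlap, module detection, module-trait
#'     association;
#'   \item short time-series model-profile clustering with permutation
#'     significance;
#'   \item ceRNA network assembly restricted to trait-associated RNAs
#'     (members of a trait-significant module and/or genes on a
#'     significant time profile, per `association_rule`);
#'   \item hypergeometric enrichment of the network's mRNAs.
#' }
#'
#' @param expr an [expression_matrix()].
#' @param pairs a [target_pairs()] set with all three edge types.
#' @param annotation optional [annotation_map()] for the enrichment
#'   stage.
#' @param trait optional per-sample trait; defaults to
#'   `trait_vector(expr, trait_encoding)`.
#' @param cv_threshold CV screening cutoff (default 0.6, strict `>`).
#' @param target_r2 scale-free fit target for power selection
#'   (default 0.9).
#' @param min_module_size,cut_height module detection parameters
#'   (defaults 20 and 0.95).
#' @param trait_encoding trait encoding when `trait` is NULL
#'   (default `"binary"`).
#' @param c,m profile family unit-change bound and number of
#'   representatives (defaults 1 and 50).
#' @param n_permutations permutations for profile significance
#'   (default 1000).
#' @param min_abs_r co-expression cutoff for candidate lncRNA-mRNA
#'   pairs (default 0.9).
#' @param alpha significance level used for module-trait association,
#'   profile significance and enrichment (default 0.05).
#' @param association_rule how module- and profile-significant gene
#'   sets combine into the trait-associated candidate set: `"union"`
#'   (default) or `"intersection"`.
#' @param seed integer seed for the permutation stream (default 1).
#' @param verbose log set sizes at each stage (default FALSE).
#' @return object of class `"cerna_run"`; see [summary.cerna_run()].
#' @export
cerna_pipeline <- function(expr, pairs, annotation = NULL, trait = NULL,
                           cv_threshold = 0.6, target_r2 = 0.9,
                           min_module_size = 20, cut_height = 0.95,
                           trait_encoding = "binary", c = 1, m = 50,
                           n_permutations = 1000, min_abs_r = 0.9,
                           alpha = 0.05,
                           association_rule = c("union", "intersection"),
                           seed = 1, verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  association_rule <- match.arg(association_rule)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(trait)) trait <- trait_vector(expr, trait_encoding)

  # stage 1: QC + CV screening + intersection
  qc <- sample_correlation_qc(expr)
  cv_report <- screen_by_cv(expr, cv_threshold, verbose = verbose)
  if (length(cv_report$retained) >= 2) {
    shared <- intersect_patients(cv_report)
  } else {
    shared <- list(shared_DELs = cv_report$retained[[1]]$DEL,
                   shared_DEMs = cv_report$retained[[1]]$DEM)
  }
  shared_genes <- c(shared$shared_DELs, shared$shared_DEMs)
  say("shared: %d DELs, %d DEMs", length(shared$shared_DELs),
      length(shared$shared_DEMs))

  # stage 2: co-expression modules on the shared set
  power_scan <- NULL
  modules <- structure(list(modules = list(),
                            unassigned = shared_genes,
                            order = shared_genes,
                            min_size = min_module_size,
                            cut_height = cut_height),
                       class = "ModuleSet")
  module_trait <- data.frame(module = character(0), size = integer(0),
                             r = numeric(0), p = numeric(0),
                             stringsAsFactors = FALSE)
  if (length(shared_genes) >= 10) {
    sub <- subset_genes(expr, shared_genes)
    power_scan <- select_power(sub, target_r2 = target_r2)
    a <- adjacency_matrix(sub, power_scan$selected)
    tom <- topological_overlap(a)
    modules <- detect_modules(tom, min_size = min_module_size,
                              cut_height = cut_height)
    if (length(modules$modules) > 0)
      module_trait <- module_trait_association(sub, modules, trait)
    say("power = %d; %d module(s) detected",
        power_scan$selected, length(modules$modules))
  } else {
    say("shared set too small (%d genes): co-expression stage skipped",
        length(shared_genes))
  }

  # stage 3: time-profile clustering on the shared set
  profiles <- NULL
  profile_genes <- character(0)
  if (length(shared_genes) >= 1) {
    profiles <- cluster_profiles(subset_genes(expr, shared_genes),
                                 c = c, m = m,
                                 n_permutations = n_permutations,
                                 seed = seed, alpha = alpha)
    asg <- attr(profiles, "assignments")
    sig_profiles <- profiles$profile_id[profiles$significant]
    profile_genes <- asg$gene_id[asg$profile_id %in% sig_profiles]
    say("%d significant profile(s), %d genes on them",
        length(sig_profiles), length(profile_genes))
  }

  # trait-associated candidate RNAs
  module_genes <- unlist(
    modules$modules[module_trait$module[module_trait$p < alpha]],
    use.names = FALSE)
  iri_genes <- if (association_rule == "union")
    union(module_genes, profile_genes)
  else intersect(module_genes, profile_genes)
  say("trait-associated RNAs (%s rule): %d", association_rule,
      length(iri_genes))

  # stage 4: ceRNA network on trait-associated RNAs
  cand <- pairs[pairs$type == "lncRNA-mRNA" &
                  pairs$source %in% iri_genes &
                  pairs$target %in% iri_genes, , drop = FALSE]
  coexp <- coexpressed_pairs(expr, cand, min_abs_r = min_abs_r)
  network <- assemble_cerna(coexp, pairs)
  say("network: %d nodes, %d edges, %d triplets",
      nrow(network$nodes), nrow(network$edges), nrow(network$triplets))
  node_profiles <- node_trait_profile(expr, network, trait)

  # stage 5: enrichment of network mRNAs
  enrichment <- NULL
  net_mrnas <- network$nodes$id[network$nodes$biotype == "mRNA"]
  if (!is.null(annotation) && length(net_mrnas) > 0)
    enrichment <- hypergeom_enrich(net_mrnas, annotation, alpha = alpha)

  structure(list(
    qc = qc, cv_report = cv_report, shared = shared,
    power_scan = power_scan, modules = modules,
    module_trait = module_trait, profiles = profiles,
    iri_genes = iri_genes, coexpressed = coexp, network = network,
    node_profiles = node_profiles, enrichment = enrichment,
    trait = trait,
    params = list(cv_threshold = cv_threshold, target_r2 = target_r2,
                  min_module_size = min_module_size,
                  cut_height = cut_height,
                  trait_encoding = attr(trait, "encoding_name"),
                  c = c, m = m, n_permutations = n_permutations,
                  min_abs_r = min_abs_r, alpha = alpha,
                  association_rule = association_rule, seed = seed)),
    class = "cerna_run")
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("ceRNA time-course inference run\n")
  cat(sprintf("  shared DELs/DEMs: %d / %d\n",
              length(x$shared$shared_DELs),
              length(x$shared$shared_DEMs)))
  if (!is.null(x$power_scan))
    cat(sprintf("  soft-threshold power: %d%s\n", x$power_scan$selected,
                if (x$power_scan$flagged) " (flagged)" else ""))
  cat(sprintf("  modules: %d; trait-associated RNAs: %d\n",
              length(x$modules$modules), length(x$iri_genes)))
  cat(sprintf("  ceRNA network: %d nodes, %d edges, %d triplets\n",
              nrow(x$network$nodes), nrow(x$network$edges),
              nrow(x$network$triplets)))
  invisible(x)
}

#' Summarise a pipeline run
#'
#' @param object a `cerna_run`.
#' @param ... unused.
#' @return the run, invisibly; prints stage-by-stage set sizes, the
#'   module-trait table, significant profiles and top enrichment rows.
#' @export
summary.cerna_run <- function(object, ...) {
  print(object)
  r2 <- object$qc[upper.tri(object$qc)]
  cat(sprintf("  sample R^2 range: %.3f - %.3f (mean %.3f)\n",
              min(r2, na.rm = TRUE), max(r2, na.rm = TRUE),
              mean(r2, na.rm = TRUE)))
  if (nrow(object$module_trait) > 0) {
    cat("  module-trait association:\n")
    print(object$module_trait, row.names = FALSE)
  }
  if (!is.null(object$profiles)) {
    sig <- object$profiles[object$profiles$significant, , drop = FALSE]
    cat(sprintf("  significant time profiles: %d\n", nrow(sig)))
    if (nrow(sig) > 0)
      print(sig[, c("profile_id", "profile", "count", "expected", "p")],
            row.names = FALSE)
  }
  if (!is.null(object$enrichment)) {
    cat("  top enrichment terms:\n")
    print(utils::head(object$enrichment[, c("term_id", "term_name", "k",
                                            "K", "p", "q")], 5),
          row.names = FALSE)
  }
  invisible(object)
}

#' Diagnostic plots for a pipeline run
#'
#' Base-graphics panel: the scale-free fit across candidate powers,
#' module-trait correlations, and observed vs expected profile counts.
#'
#' @param x a `cerna_run`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.cerna_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$power_scan)) {
    s <- x$power_scan$scan
    plot(s$power, s$r2, type = "b", xlab = "soft-threshold power",
         ylab = expression(scale - free ~ fit ~ R^2),
         main = "Power selection", ...)
    graphics::abline(h = x$power_scan$target_r2, col = "red", lty = 2)
    graphics::abline(v = x$power_scan$selected, col = "blue", lty = 3)
  } else plot.new()
  if (nrow(x$module_trait) > 0) {
    graphics::barplot(abs(x$module_trait$r),
                      names.arg = x$module_trait$module,
                      ylab = "|r| with trait", main = "Module-trait")
  } else plot.new()
  if (!is.null(x$profiles)) {
    plot(x$profiles$expected, x$profiles$count,
         xlab = "expected count (null)", ylab = "observed count",
         main = "Profile counts",
         col = ifelse(x$profiles$significant, "red", "grey30"),
         pch = 19)
    graphics::abline(0, 1, lty = 2)
  } else plot.new()
  invisible(x)
}

#' Run the pipeline from a configuration file and write a run directory
#'
#' Reads a YAML configuration naming the input files and stage
#' parameters, validates it, runs [cerna_pipeline()], and writes every
#' stage's outputs plus a machine-readable manifest
#' (`manifest.json`: package version, parameters, seed, input
#' checksums, stage set sizes). Outputs are a deterministic function of
#' the configuration and seed, so re-running produces byte-identical
#' files.
#'
#' Config keys: `expression`, `samples`, `pairs` (paths; required),
#' `annotation`, `trait` (paths; optional), `out_dir` (required unless
#' given as argument), and any parameter of [cerna_pipeline()].
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return the `cerna_run`, invisibly; side effect: the run directory.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("expression", "samples", "pairs")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop("config is missing required keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  in_paths <- unlist(config[intersect(names(config),
                                      c(need, "annotation", "trait"))])
  absent <- in_paths[!file.exists(in_paths)]
  if (length(absent) > 0)
    stop("input file(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)

  expr <- read_expression(config$expression, config$samples)
  pairs <- read_pairs(config$pairs)
  annotation <- if (!is.null(config$annotation))
    read_annotation(config$annotation,
                    universe = rownames(expr$values)) else NULL
  trait <- if (!is.null(config$trait)) {
    tt <- utils::read.delim(config$trait, stringsAsFactors = FALSE)
    v <- stats::setNames(tt$trait, tt$sample)[colnames(expr$values)]
    attr(v, "encoding_name") <- "file"
    v
  } else NULL

  par_names <- setdiff(names(formals(cerna_pipeline)),
                       c("expr", "pairs", "annotation", "trait",
                         "verbose"))
  pars <- config[intersect(names(config), par_names)]
  run <- do.call(cerna_pipeline,
                 c(list(expr = expr, pairs = pairs,
                        annotation = annotation, trait = trait), pars))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (p in names(run$cv_report$cv))
    wtsv(data.frame(gene_id = names(run$cv_report$cv[[p]]),
                    cv = unname(run$cv_report$cv[[p]])),
         sprintf("cv_%s.tsv", p))
  writeLines(run$shared$shared_DELs,
             file.path(out_dir, "shared_DELs.txt"))
  writeLines(run$shared$shared_DEMs,
             file.path(out_dir, "shared_DEMs.txt"))
  if (!is.null(run$power_scan)) wtsv(run$power_scan$scan,
                                     "power_scan.tsv")
  if (length(run$modules$modules) > 0)
    wtsv(data.frame(
      gene_id = unlist(run$modules$modules, use.names = FALSE),
      module = rep(names(run$modules$modules),
                   lengths(run$modules$modules))),
      "module_membership.tsv")
  wtsv(run$module_trait, "module_trait.tsv")
  if (!is.null(run$profiles))
    wtsv(as.data.frame(run$profiles), "profiles.tsv")
  writeLines(sort(run$iri_genes),
             file.path(out_dir, "trait_associated_rnas.txt"))
  wtsv(as.data.frame(run$coexpressed), "coexpressed_pairs.tsv")
  write_network(run$network, file.path(out_dir, "network.sif"), "SIF")
  write_network(run$network, file.path(out_dir, "network.graphml"),
                "GraphML")
  write_network(run$network, file.path(out_dir, "network.tsv"), "TSV")
  wtsv(run$network$triplets, "triplets.tsv")
  cnt <- network_counts(run$network)
  wtsv(data.frame(kind = c(paste0("nodes_", names(cnt$nodes)),
                           paste0("edges_", names(cnt$edges)),
                           "nodes_total", "edges_total", "triplets"),
                  count = c(as.integer(cnt$nodes),
                            as.integer(cnt$edges), cnt$n_nodes,
                            cnt$n_edges, cnt$n_triplets)),
       "network_counts.tsv")
  if (!is.null(run$enrichment))
    wtsv(as.data.frame(run$enrichment), "enrichment.tsv")

  manifest <- list(
    package = "ceRNAti",
    version = as.character(utils::packageVersion("ceRNAti")),
    parameters = run$params,
    inputs = {
      sums <- tools::md5sum(in_paths)
      names(sums) <- basename(names(sums))
      as.list(sums)
    },
    sizes = list(
      genes = nrow(expr$values), samples = ncol(expr$values),
      shared_DELs = length(run$shared$shared_DELs),
      shared_DEMs = length(run$shared$shared_DEMs),
      modules = length(run$modules$modules),
      trait_associated = length(run$iri_genes),
      coexpressed_pairs = nrow(run$coexpressed),
      network_nodes = nrow(run$network$nodes),
      network_edges = nrow(run$network$edges),
      triplets = nrow(run$network$triplets)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run)
}
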