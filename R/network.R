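#' @title ceRNA network assembly
#' @description Stage 4 of the pipeline: filter candidate lncRNA-mRNA
#'   pairs by expression correlation, assemble lncRNA-miRNA-mRNA
#'   triplets by shared-miRNA joining, and extract gene-centred
#'   functional submodules.
#' @name cerna_network
NULL

#' Co-expression filter for candidate lncRNA-mRNA pairs
#'
#' Retains candidate pairs whose Pearson correlation across all samples
#' (on log(x + 1) abundances) satisfies `|r| >= min_abs_r`; both signs
#' are admitted and the direction is recorded. Pairs with an endpoint
#' missing from the expression matrix are skipped and counted.
#'
#' @param expr an `ExpressionMatrix`.
#' @param candidate_pairs a `TargetPairSet`; only rows of type
#'   `"lncRNA-mRNA"` are considered.
#' @param min_abs_r absolute-correlation cutoff (default 0.9). The
#'   default is deliberately strict so that retained pairs are sparse.
#' @return data.frame of class `"CoexpressedPairs"` with columns
#'   `lncRNA_id`, `mRNA_id`, `r`, `direction`; the number of skipped
#'   pairs is attached as attribute `"n_skipped"`.
#' @export
coexpressed_pairs <- function(expr, candidate_pairs, min_abs_r = 0.9) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  cand <- candidate_pairs[candidate_pairs$type == "lncRNA-mRNA", ,
                          drop = FALSE]
  present <- cand$source %in% rownames(expr$values) &
             cand$target %in% rownames(expr$values)
  n_skipped <- sum(!present)
  if (n_skipped > 0)
    message(n_skipped,
            " candidate pair(s) skipped: endpoint not in matrix")
  cand <- cand[present, , drop = FALSE]
  lx <- log1(expr$values)
  r <- vapply(seq_len(nrow(cand)), function(i) {
    a <- lx[cand$source[i], ]; b <- lx[cand$target[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  keep <- !is.na(r) & abs(r) >= min_abs_r
  out <- data.frame(lncRNA_id = cand$source[keep],
                    mRNA_id = cand$target[keep],
                    r = r[keep],
                    direction = ifelse(r[keep] >= 0, "positive",
                                       "negative"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("CoexpressedPairs", "data.frame")
  out
}

# internal constructor: nodes/edges/triplets with the closure invariant
new_cerna_network <- function(nodes, edges, triplets) {
  structure(list(nodes = nodes, edges = edges, triplets = triplets),
            class = "CeRNANetwork")
}

#' Assemble the ceRNA network from co-expressed pairs and targeting pairs
#'
#' A triplet (lncRNA, miRNA, mRNA) is formed whenever the lncRNA-mRNA
#' pair is retained as co-expressed and the shared miRNA targets both:
#' (lncRNA, miRNA) appears among the lncRNA-miRNA pairs and
#' (miRNA, mRNA) among the miRNA-mRNA pairs. The network is the union of
#' the three typed edge sets restricted to triplet members, with nodes
#' and edges deduplicated. Empty inputs produce an empty network. miRNA
#' expression is not required: the targeting edges come from databases.
#'
#' @param coexpressed a `CoexpressedPairs` table (or any data.frame with
#'   columns `lncRNA_id`, `mRNA_id`).
#' @param pairs a `TargetPairSet` holding the lncRNA-miRNA and
#'   miRNA-mRNA edges.
#' @return object of class `"CeRNANetwork"`: list with `nodes`
#'   (data.frame `id`, `biotype`), `edges` (data.frame `source`,
#'   `target`, `type`), `triplets` (data.frame `lncRNA_id`, `miRNA_id`,
#'   `mRNA_id`).
#' @export
assemble_cerna <- function(coexpressed, pairs) {
  lm <- pairs[pairs$type == "lncRNA-miRNA", c("source", "target")]
  mm <- pairs[pairs$type == "miRNA-mRNA", c("source", "target")]
  trip <- list()
  if (nrow(coexpressed) > 0 && nrow(lm) > 0 && nrow(mm) > 0) {
    for (i in seq_len(nrow(coexpressed))) {
      L <- coexpressed$lncRNA_id[i]; M <- coexpressed$mRNA_id[i]
      shared <- intersect(lm$target[lm$source == L],
                          mm$source[mm$target == M])
      if (length(shared) > 0)
        trip[[length(trip) + 1]] <-
          data.frame(lncRNA_id = L, miRNA_id = shared, mRNA_id = M,
                     stringsAsFactors = FALSE)
    }
  }
  triplets <- if (length(trip) > 0) do.call(rbind, trip) else
    data.frame(lncRNA_id = character(0), miRNA_id = character(0),
               mRNA_id = character(0), stringsAsFactors = FALSE)
  triplets <- unique(triplets)
  rownames(triplets) <- NULL
  nt <- nrow(triplets)
  edges <- unique(rbind(
    data.frame(source = triplets$lncRNA_id, target = triplets$mRNA_id,
               type = rep("lncRNA-mRNA", nt), stringsAsFactors = FALSE),
    data.frame(source = triplets$lncRNA_id, target = triplets$miRNA_id,
               type = rep("lncRNA-miRNA", nt), stringsAsFactors = FALSE),
    data.frame(source = triplets$miRNA_id, target = triplets$mRNA_id,
               type = rep("miRNA-mRNA", nt), stringsAsFactors = FALSE)))
  rownames(edges) <- NULL
  nodes <- unique(rbind(
    data.frame(id = triplets$lncRNA_id,
               biotype = rep("lncRNA", nt), stringsAsFactors = FALSE),
    data.frame(id = triplets$miRNA_id,
               biotype = rep("miRNA", nt), stringsAsFactors = FALSE),
    data.frame(id = triplets$mRNA_id,
               biotype = rep("mRNA", nt), stringsAsFactors = FALSE)))
  rownames(nodes) <- NULL
  new_cerna_network(nodes, edges, triplets)
}

#' @export
print.CeRNANetwork <- function(x, ...) {
  nb <- table(factor(x$nodes$biotype,
                     levels = c("lncRNA", "miRNA", "mRNA")))
  eb <- table(factor(x$edges$type, levels = PAIR_TYPES))
  cat(sprintf("CeRNANetwork: %d nodes, %d edges, %d triplets\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$triplets)))
  cat("  nodes:",
      paste(sprintf("%s=%d", names(nb), as.integer(nb)), collapse = ", "),
      "\n")
  cat("  edges:",
      paste(sprintf("%s=%d", names(eb), as.integer(eb)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-type node and edge counts of a ceRNA network
#' @param net a `CeRNANetwork`.
#' @return list with `nodes` and `edges` count tables plus totals.
#' @export
network_counts <- function(net) {
  stopifnot(inherits(net, "CeRNANetwork"))
  list(nodes = table(factor(net$nodes$biotype,
                            levels = c("lncRNA", "miRNA", "mRNA"))),
       edges = table(factor(net$edges$type, levels = PAIR_TYPES)),
       n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       n_triplets = nrow(net$triplets))
}

#' Extract the submodule centred on focus mRNAs
#'
#' The subnetwork induced by every triplet containing a focus mRNA:
#' those triplets' lncRNAs, miRNAs and typed edges. Focus mRNAs that
#' sit in no triplet are kept as isolated nodes. Idempotent for a fixed
#' focus set.
#'
#' @param net a `CeRNANetwork`.
#' @param focus_mrnas mRNA node ids; all must be mRNA nodes of `net`.
#' @return a `CeRNANetwork`.
#' @export
extract_gene_module <- function(net, focus_mrnas) {
  stopifnot(inherits(net, "CeRNANetwork"))
  mr <- net$nodes$id[net$nodes$biotype == "mRNA"]
  missing <- setdiff(focus_mrnas, mr)
  if (length(missing) > 0)
    stop("focus genes absent from the network's mRNA nodes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  trip <- net$triplets[net$triplets$mRNA_id %in% focus_mrnas, ,
                       drop = FALSE]
  tp <- unique(data.frame(
    source = c(trip$lncRNA_id, trip$miRNA_id),
    target = c(trip$miRNA_id, trip$mRNA_id),
    type = rep(c("lncRNA-miRNA", "miRNA-mRNA"), each = nrow(trip)),
    stringsAsFactors = FALSE))
  sub <- assemble_cerna(
    unique(data.frame(lncRNA_id = trip$lncRNA_id,
                      mRNA_id = trip$mRNA_id,
                      stringsAsFactors = FALSE)),
    target_pairs(tp$source, tp$target, tp$type))
  # focus mRNAs with no triplet remain as isolated nodes
  lone <- setdiff(focus_mrnas, sub$nodes$id)
  if (length(lone) > 0) {
    sub$nodes <- rbind(sub$nodes,
                       data.frame(id = lone, biotype = "mRNA",
                                  stringsAsFactors = FALSE))
    rownames(sub$nodes) <- NULL
  }
  sub
}

#' Node time-course summary and trait-correlation sign
#'
#' For each measured network node: its mean expression (log(x + 1),
#' averaged over patients) at each study time point, the sign of its
#' correlation with the trait vector, and the time point at which the
#' mean course peaks. Unmeasured nodes (typically miRNAs) are skipped.
#'
#' @param expr an `ExpressionMatrix`.
#' @param net a `CeRNANetwork`.
#' @param trait per-sample numeric trait vector.
#' @return data.frame with `id`, `biotype`, `trait_sign`
#'   (`"positive"`/`"negative"`), `peak_time_hours`, and one `t<h>`
#'   column per time point.
#' @export
node_trait_profile <- function(expr, net, trait) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(net, "CeRNANetwork"))
  ids <- intersect(net$nodes$id, rownames(expr$values))
  if (length(ids) == 0)
    return(data.frame(id = character(0), biotype = character(0),
                      trait_sign = character(0),
                      peak_time_hours = numeric(0)))
  sub <- subset_genes(expr, ids)
  tc <- gene_timecourses(sub)
  lx <- log1(sub$values)
  r <- apply(lx, 1, function(v)
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, trait))
  tps <- as.numeric(colnames(tc))
  out <- data.frame(
    id = ids,
    biotype = net$nodes$biotype[match(ids, net$nodes$id)],
    trait_sign = ifelse(is.na(r), NA_character_,
                        ifelse(r >= 0, "positive", "negative")),
    peak_time_hours = tps[max.col(tc, ties.method = "first")],
    stringsAsFactors = FALSE)
  tcdf <- as.data.frame(tc)
  names(tcdf) <- paste0("t", colnames(tc))
  cbind(out, tcdf, row.names = NULL)
}
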