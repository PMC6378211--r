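#' Offline hypergeometric functional enrichment
#'
#' For each annotated term, tests over-representation of the query gene
#' set in the term's gene set against the annotation universe with the
#' hypergeometric upper tail: with `N` universe genes, `K` of them
#' annotated to the term, and a query of size `n` containing `k`
#' annotated genes, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Benjamini-Hochberg-adjusted values are always reported alongside,
#' but the significance call uses the raw p at `alpha`, mirroring the
#' common single-threshold convention of online enrichment tools.
#' Query genes outside the universe are dropped with a message.
#'
#' @param query character vector of gene ids.
#' @param annot an [annotation_map()].
#' @param alpha raw-p significance level (default 0.05).
#' @return data.frame of class `"EnrichmentResult"`, sorted by `p`:
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, `genes` (comma-joined query hits).
#' @export
hypergeom_enrich <- function(query, annot, alpha = 0.05) {
  stopifnot(inherits(annot, "AnnotationMap"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query", call. = FALSE)
  N <- length(annot$universe)
  if (N == 0) stop("empty annotation universe", call. = FALSE)
  outside <- setdiff(query, annot$universe)
  if (length(outside) > 0) {
    message(length(outside),
            " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("no query genes in the universe",
                               call. = FALSE)
  n <- length(query)
  rows <- lapply(names(annot$terms), function(id) {
    g <- annot$terms[[id]]
    K <- length(g)
    hits <- intersect(query, g)
    k <- length(hits)
    # upper tail P(X >= k): phyper counts P(X <= q), so q = k - 1
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = annot$term_names[[id]],
               k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "k", "K", "n", "N", "p", "q",
               "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
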