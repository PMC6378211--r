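#' @title File formats
#' @description Readers and writers for every file the pipeline touches.
#'   All tabular formats are tab-separated UTF-8 with a header row. Gene
#'   identifier matching is exact, case-sensitive string match throughout;
#'   no alias resolution is attempted.
#' @name io_formats
NULL

PAIR_TYPES <- c("lncRNA-mRNA", "lncRNA-miRNA", "miRNA-mRNA")

# endpoint biotypes implied by each edge type
pair_endpoint_biotypes <- function(type) {
  switch(type,
         "lncRNA-mRNA"  = c("lncRNA", "mRNA"),
         "lncRNA-miRNA" = c("lncRNA", "miRNA"),
         "miRNA-mRNA"   = c("miRNA", "mRNA"),
         stop("unknown edge type '", type, "'", call. = FALSE))
}

#' Construct a typed regulatory pair set
#'
#' Candidate regulatory pairs of three types: lncRNA-mRNA (co-expression
#' candidates), lncRNA-miRNA and miRNA-mRNA (database-sourced targeting
#' pairs). Duplicate (source, target, type) rows are removed with a
#' warning. If an expression matrix is supplied, endpoint biotypes are
#' checked against the declared edge type.
#'
#' @param source,target character vectors of gene ids.
#' @param type character vector of edge types, each one of
#'   `"lncRNA-mRNA"`, `"lncRNA-miRNA"`, `"miRNA-mRNA"`.
#' @param expr optional `ExpressionMatrix` used to validate endpoint
#'   biotypes (endpoints absent from the matrix are not checked; miRNAs
#'   are typically unmeasured).
#' @return data.frame of class `"TargetPairSet"` with columns `source`,
#'   `target`, `type`.
#' @export
target_pairs <- function(source, target, type, expr = NULL) {
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   type = as.character(type),
                   stringsAsFactors = FALSE)
  bad <- !df$type %in% PAIR_TYPES
  if (any(bad))
    stop("unknown edge type token '", df$type[bad][1], "'", call. = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) removed", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  if (!is.null(expr)) {
    bt <- expr$biotype
    for (i in seq_len(nrow(df))) {
      want <- pair_endpoint_biotypes(df$type[i])
      ends <- c(df$source[i], df$target[i])
      for (j in 1:2) {
        have <- bt[ends[j]]
        if (!is.na(have) && have != want[j])
          stop(sprintf("pair %s -> %s declared %s but '%s' has biotype %s",
                       df$source[i], df$target[i], df$type[i], ends[j],
                       have), call. = FALSE)
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("TargetPairSet", "data.frame")
  df
}

#' Read an expression matrix with sample metadata
#'
#' @param path expression TSV: first column gene id, optional `biotype`
#'   column, remaining columns one per sample (header = sample ids).
#' @param meta_path sample metadata TSV with columns `sample`, `patient`,
#'   `time_hours`.
#' @param biotype optional named character vector supplying biotypes when
#'   the expression file has no `biotype` column.
#' @return a validated [expression_matrix()].
#' @export
read_expression <- function(path, meta_path, biotype = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gid <- as.character(tab[[1]])
  tab <- tab[-1]
  if ("biotype" %in% names(tab)) {
    biotype <- stats::setNames(as.character(tab$biotype), gid)
    tab$biotype <- NULL
  }
  if (is.null(biotype))
    stop("no biotype column in ", path,
         " and no `biotype` argument supplied", call. = FALSE)
  for (cn in names(tab)) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v) && !anyNA(tab[[cn]]))
      stop("non-numeric cell in sample column '", cn, "'", call. = FALSE)
    tab[[cn]] <- v
  }
  values <- as.matrix(tab)
  rownames(values) <- gid
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(values, biotype, meta)
}

#' Write an expression matrix (and its sample metadata)
#' @param expr an `ExpressionMatrix`.
#' @param path expression TSV path (gene id + biotype + sample columns).
#' @param meta_path sample metadata TSV path.
#' @export
write_expression <- function(expr, path, meta_path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  out <- data.frame(gene_id = rownames(expr$values),
                    biotype = unname(expr$biotype),
                    expr$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a typed pair file
#' @param path TSV with columns `source`, `target`, `type`.
#' @param expr optional `ExpressionMatrix` for biotype validation.
#' @return a [target_pairs()] set.
#' @export
read_pairs <- function(path, expr = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "type") %in% names(tab)))
    stop("pair file must have columns source, target, type", call. = FALSE)
  target_pairs(tab$source, tab$target, tab$type, expr = expr)
}

#' Write a typed pair file
#' @param pairs a `TargetPairSet`.
#' @param path output TSV path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an annotation map for enrichment
#'
#' @param terms named list: term id -> character vector of annotated gene
#'   ids.
#' @param term_names named character vector: term id -> human-readable
#'   name.
#' @param universe character vector of background gene ids; every
#'   annotated gene must belong to it.
#' @return list of class `"AnnotationMap"`.
#' @export
annotation_map <- function(terms, term_names, universe) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  universe <- unique(as.character(universe))
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("`terms` must be uniquely named by term id", call. = FALSE)
  missing_nm <- setdiff(names(terms), names(term_names))
  if (length(missing_nm) > 0)
    stop("terms without a name: ",
         paste(missing_nm, collapse = ", "), call. = FALSE)
  stray <- setdiff(unique(unlist(terms)), universe)
  if (length(stray) > 0)
    stop("annotated genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  structure(list(terms = terms,
                 term_names = term_names[names(terms)],
                 universe = universe),
            class = "AnnotationMap")
}

#' Read a GMT-like annotation file
#'
#' Each line: term id, term name, then the annotated gene ids, all
#' tab-separated. The universe defaults to the union of all annotated
#' genes unless supplied.
#'
#' @param path GMT-like TSV path.
#' @param universe optional background gene set.
#' @return an [annotation_map()].
#' @export
read_annotation <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  nms <- stats::setNames(vapply(parts, `[`, "", 2), ids)
  terms <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(terms))
  annotation_map(terms, nms, universe)
}

#' Write a GMT-like annotation file
#' @param annot an `AnnotationMap`.
#' @param path output path.
#' @export
write_annotation <- function(annot, path) {
  lines <- vapply(names(annot$terms), function(id) {
    paste(c(id, annot$term_names[[id]], annot$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a ceRNA network
#'
#' `"SIF"` writes one `source<TAB>edge_type<TAB>target` line per edge, the
#' interaction token being the edge type, for direct Cytoscape import.
#' `"GraphML"` carries node biotype and edge type as attributes.
#' `"TSV"` writes the edge table; re-reading it with [read_pairs()]
#' reproduces the edge set exactly.
#'
#' @param net a `CeRNANetwork` (see [assemble_cerna()]).
#' @param path output path.
#' @param format one of `"SIF"`, `"GraphML"`, `"TSV"`.
#' @export
write_network <- function(net, path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "CeRNANetwork"))
  e <- net$edges
  if (format == "SIF") {
    writeLines(paste(e$source, e$type, e$target, sep = "\t"), path)
  } else if (format == "TSV") {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = e$source, to = e$target, type = e$type,
                     stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = net$nodes$id,
                            biotype = net$nodes$biotype,
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
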