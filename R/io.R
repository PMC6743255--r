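## Readers and writers for the pipeline's plain-text interchange formats:
## expression TSV, edge-list CSV with a node sidecar (so degree-zero entities
## survive serialization), GMT annotation sets, parent-child hierarchy TSV,
## and the tabular outputs. write-then-read is the identity on the in-memory
## structures.

#' Expression matrix TSV
#'
#' Rows are entities (first column the entity id), the header names the
#' samples; missing values are written as `NA` (empty fields read back as
#' missing too).
#'
#' @param x numeric entities-by-samples matrix with dimnames.
#' @param path file path.
#' @return `read_expression_tsv()` returns the matrix; writers return the
#'   path invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(entity = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("expression TSV needs an id column and data columns")
  if (anyDuplicated(df[[1L]]))
    stop("duplicate entity id at line ",
         which(duplicated(df[[1L]]))[1L] + 1L)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in the expression matrix")
  rownames(m) <- df[[1L]]
  m
}

#' Edge-list CSV with a node sidecar
#'
#' The graph travels as a two-column CSV `source,target` (each unordered pair
#' once); the full node set -- including degree-zero entities -- goes to a
#' sidecar file with one id per line, which governs the node set on reading.
#'
#' @param g a [reduced_graph] or igraph with named vertices.
#' @param path edge CSV path.
#' @param node_path node sidecar path; default `paste0(path, ".nodes")`.
#' @return `read_edge_list()` returns a [reduced_graph]; writers return the
#'   path invisibly.
#' @export
write_edge_list <- function(g, path, node_path = paste0(path, ".nodes")) {
  gr <- as_igraph(g)
  ends <- igraph::as_edgelist(gr)
  utils::write.table(data.frame(source = ends[, 1L], target = ends[, 2L]),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  writeLines(igraph::V(gr)$name, node_path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, node_path = paste0(path, ".nodes")) {
  ed <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(ed)))
    stop("edge list must have a 'source,target' header")
  nodes <- if (file.exists(node_path)) readLines(node_path) else
    unique(c(ed$source, ed$target))
  missing_nodes <- setdiff(unique(c(ed$source, ed$target)), nodes)
  if (length(missing_nodes))
    stop("edge endpoints absent from the node file: ",
         paste(utils::head(missing_nodes, 3), collapse = ", "))
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(ed))
    g <- igraph::add_edges(g, rbind(match(ed$source, nodes),
                                    match(ed$target, nodes)))
  reduced_graph(g, provenance = list(method = "file", path = path))
}

#' GMT annotation sets
#'
#' One term per line: id, description, then the annotated entity ids, all
#' tab-separated.
#'
#' @param ann named list term -> entity ids.
#' @param path file path.
#' @param descriptions optional named character descriptions per term.
#' @return `read_gmt()` returns the named list (descriptions in attribute
#'   `"descriptions"`); writers return the path invisibly.
#' @export
write_gmt <- function(ann, path, descriptions = NULL) {
  lines <- vapply(names(ann), function(t) {
    desc <- if (!is.null(descriptions) && t %in% names(descriptions))
      descriptions[[t]] else t
    paste(c(t, desc, ann[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1L], ": need id, description, entities")
  ids <- vapply(parts, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate GMT term id: ", dup[1L])
  ann <- lapply(parts, function(p) p[-(1:2)])
  names(ann) <- ids
  attr(ann, "descriptions") <- stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
  ann
}

#' Parent-child hierarchy TSV
#'
#' The two-column, headerless `parent<TAB>child` dialect of pathway relation
#' files.
#'
#' @param tree a [hierarchy_tree()] (the artificial root's edges are not
#'   written).
#' @param path file path.
#' @return `read_hierarchy_tsv()` returns a [hierarchy_tree()]; writers
#'   return the path invisibly.
#' @export
write_hierarchy_tsv <- function(tree, path) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  ed <- tree$edges[tree$edges$parent != tree$root, , drop = FALSE]
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hierarchy_tsv
#' @param root id for the artificial root added on reading.
#' @export
read_hierarchy_tsv <- function(path, root = "ROOT") {
  ed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ed) < 2) stop("hierarchy TSV needs two columns: parent<TAB>child")
  hierarchy_tree(data.frame(parent = as.character(ed[[1L]]),
                            child = as.character(ed[[2L]]),
                            stringsAsFactors = FALSE), root = root)
}

#' Edge score table CSV
#'
#' @param table an edge-score table from [score_all_spurious()] or
#'   [score_missing()].
#' @param path file path.
#' @return `read_edge_scores()` returns the data frame; writers return the
#'   path invisibly.
#' @export
write_edge_scores <- function(table, path) {
  utils::write.table(table, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_scores
#' @export
read_edge_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
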