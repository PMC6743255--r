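#' Construct an SBM state
#'
#' Bundles a simple undirected graph with a (possibly nested) block partition
#' and the derived microcanonical parameter caches: per-level edge-count
#' matrices (with doubled diagonal, so that `sum(e) == 2 * E` at every level),
#' block sizes, the degree sequence and block degree sums. These caches are
#' what the likelihoods, priors and the description length operate on.
#'
#' @param graph an [igraph::igraph] or [reduced_graph] object; must be simple
#'   and undirected. Degree-zero vertices are allowed.
#' @param levels a single integer vector (flat partition of the nodes) or a
#'   list of integer vectors: `levels[[1]]` assigns each node to a level-1
#'   block, `levels[[l]]` assigns each level-`(l-1)` block to a level-`l`
#'   block. For a hierarchical state the top level must consist of a single
#'   block.
#' @param degree_corrected logical; cache and use the degree sequence.
#' @param hierarchical logical; defaults to `TRUE` when more than one level is
#'   supplied. A flat state has exactly one level.
#' @return an object of class `sbm_state`.
#' @seealso [description_length()], [fit_sbm()]
#' @export
sbm_state <- function(graph, levels, degree_corrected = FALSE,
                      hierarchical = NULL) {
  g <- as_igraph(graph)
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    stop("graph must be simple (no multi-edges, no self-loops)")
  if (!is.list(levels)) levels <- list(as.integer(levels))
  levels <- lapply(levels, as.integer)
  levels <- normalize_levels(levels)
  if (is.null(hierarchical)) hierarchical <- length(levels) > 1L
  L <- length(levels)
  if (!hierarchical && L != 1L)
    stop("a non-hierarchical state has exactly one level")
  N <- igraph::vcount(g)
  if (length(levels[[1L]]) != N)
    stop("level-1 partition must assign every node")
  if (hierarchical && max(levels[[L]]) != 1L)
    stop("hierarchical boundary violated: the top level must have one block")

  st <- list(graph = g, levels = levels,
             degree_corrected = isTRUE(degree_corrected),
             hierarchical = isTRUE(hierarchical))
  st <- rebuild_caches(st)
  class(st) <- "sbm_state"
  st
}

## Relabel every level to consecutive block ids 1..B (order of first
## appearance preserved) and propagate the relabeling upward; drop trailing
## all-trivial duplication is left to callers.
normalize_levels <- function(levels) {
  for (l in seq_along(levels)) {
    b <- levels[[l]]
    if (anyNA(b) || any(b < 1L)) stop("block labels must be positive integers")
    u <- unique(b)
    levels[[l]] <- match(b, u)
    if (l < length(levels)) {
      up <- levels[[l + 1L]]
      if (length(up) < length(u)) stop("level ", l + 1L, " does not cover all blocks of level ", l)
      levels[[l + 1L]] <- up[u]  # keep only assignments of surviving blocks, reordered
    }
  }
  levels
}

## Edge-count matrix between blocks, diagonal doubled (e_rr = twice the number
## of within-block edges).
block_edge_matrix <- function(b, B, ends) {
  e <- matrix(0, B, B)
  if (nrow(ends) > 0) {
    bu <- b[ends[, 1L]]; bv <- b[ends[, 2L]]
    cnt <- tabulate(c((bu - 1L) * B + bv, (bv - 1L) * B + bu), B * B)
    e <- matrix(cnt, B, B)
  }
  e
}

aggregate_edge_matrix <- function(e, up, B_up) {
  M <- matrix(0, nrow(e), B_up)
  M[cbind(seq_along(up), up)] <- 1
  t(M) %*% e %*% M
}

rebuild_caches <- function(st) {
  g <- st$graph
  levels <- st$levels
  L <- length(levels)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::degree(g)

  B <- vapply(levels, max, integer(1))
  e_mats <- vector("list", L)
  n_units <- vector("list", L)
  e_mats[[1L]] <- block_edge_matrix(levels[[1L]], B[1L], ends)
  n_units[[1L]] <- tabulate(levels[[1L]], B[1L])
  if (L > 1L) for (l in 2:L) {
    e_mats[[l]] <- aggregate_edge_matrix(e_mats[[l - 1L]], levels[[l]], B[l])
    n_units[[l]] <- tabulate(levels[[l]], B[l])
  }
  st$N <- N; st$E <- E; st$k <- k
  st$B <- B
  st$e_mats <- e_mats
  st$n_units <- n_units
  st$er <- rowSums(e_mats[[1L]])
  st
}

#' @export
print.sbm_state <- function(x, ...) {
  cat(sprintf("<sbm_state> %d nodes, %d edges, %s%s, levels: %s\n",
              x$N, x$E,
              if (x$degree_corrected) "degree-corrected" else "classical",
              if (x$hierarchical) " hierarchical" else "",
              paste(x$B, collapse = " -> ")))
  invisible(x)
}

## Block membership of the original nodes at hierarchy level l.
level_membership <- function(state, l) {
  b <- state$levels[[1L]]
  if (l > 1L) for (m in 2:l) b <- state$levels[[m]][b]
  b
}

#' Serialize / restore an SBM state as JSON
#'
#' Only the per-level block assignments and the model flags are stored; all
#' parameter caches are recomputed on load from the graph, which must be
#' supplied separately (graphs travel as edge lists, see [write_edge_list()]).
#'
#' @param state an [sbm_state()] object.
#' @param path file path.
#' @export
write_sbm_state <- function(state, path) {
  obj <- list(levels = state$levels,
              degree_corrected = state$degree_corrected,
              hierarchical = state$hierarchical,
              entity_ids = igraph::V(state$graph)$name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sbm_state
#' @param graph the graph the stored partition refers to.
#' @export
read_sbm_state <- function(path, graph) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as_igraph(graph)
  ids <- igraph::V(g)$name
  if (!is.null(obj$entity_ids) && !is.null(ids) &&
      !identical(as.character(obj$entity_ids), as.character(ids)))
    stop("graph entity ids do not match the serialized state")
  levels <- obj$levels
  if (!is.list(levels)) levels <- list(levels)
  sbm_state(g, lapply(levels, as.integer),
            degree_corrected = isTRUE(obj$degree_corrected),
            hierarchical = isTRUE(obj$hierarchical))
}
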