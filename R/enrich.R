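## Block characterization: hypergeometric term overrepresentation with the
## study's size and significance filters, shuffle nulls, two tree distance
## measures on the annotation hierarchy, SBM-hierarchy block distances, and
## parent-term summarization.

#' Build an annotation term hierarchy
#'
#' Takes parent-child pairs among term ids and adds an artificial root
#' connecting all top-level terms, so distances are defined between any two
#' terms. Levels follow the convention: leaves at level 1,
#' `level(t) = 1 + longest downward path from t to a leaf`; the artificial
#' root therefore sits one level above the deepest term.
#'
#' @param edges data frame with columns `parent`, `child` (term ids), or an
#'   empty data frame.
#' @param terms optional ids of terms with no edges (e.g. a flat annotation);
#'   they become children of the root.
#' @param root id of the artificial root.
#' @return an object of class `hierarchy_tree`: list with `edges` (including
#'   the root edges), `terms`, `root`, `level` (named integer), `parents`
#'   (named list) and `graph` (undirected igraph for path distances).
#' @export
hierarchy_tree <- function(edges, terms = NULL, root = "ROOT") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    names(edges)[1:2] <- c("parent", "child")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
  } else {
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  }
  all_terms <- unique(c(edges$parent, edges$child, terms))
  if (root %in% all_terms) stop("root id collides with an existing term")
  top <- setdiff(all_terms, edges$child)
  if (!length(top))
    stop("hierarchy contains a cycle: no top-level term remains")
  edges <- rbind(data.frame(parent = root, child = top, stringsAsFactors = FALSE),
                 edges)
  all_terms <- c(root, all_terms)

  children <- split(edges$child, edges$parent)
  parents <- split(edges$parent, edges$child)

  ## levels by memoized longest-downward-path; also rejects cycles
  level <- stats::setNames(rep(NA_integer_, length(all_terms)), all_terms)
  visiting <- character(0)
  walk <- function(t) {
    if (!is.na(level[[t]])) return(level[[t]])
    if (t %in% visiting) stop("hierarchy contains a cycle at term ", t)
    visiting <<- c(visiting, t)
    ch <- children[[t]]
    lv <- if (is.null(ch) || !length(ch)) 1L
          else 1L + max(vapply(ch, walk, integer(1)))
    visiting <<- setdiff(visiting, t)
    level[[t]] <<- lv
    lv
  }
  for (t in all_terms) walk(t)

  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = FALSE,
                                     vertices = all_terms)
  structure(list(edges = edges, terms = all_terms, root = root,
                 level = level, parents = parents, children = children,
                 graph = g),
            class = "hierarchy_tree")
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  cat(sprintf("<hierarchy_tree> %d terms, root '%s' at level %d\n",
              length(x$terms) - 1L, x$root, x$level[[x$root]]))
  invisible(x)
}

#' Distances between annotation terms
#'
#' Measure (i), `term_distance_steps()`: length of the shortest path between
#' the two terms in the undirected hierarchy graph (root included). Measure
#' (ii), `term_distance_lca()`: the hierarchy level of the lowest common
#' ancestor (least common subsumer); higher levels mean more distant terms.
#'
#' @param tree a [hierarchy_tree()].
#' @param a,b term ids.
#' @return a single number.
#' @export
term_distance_steps <- function(tree, a, b) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  if (!a %in% tree$terms || !b %in% tree$terms)
    stop("term not in the hierarchy")
  as.numeric(igraph::distances(tree$graph, v = a, to = b))
}

#' @rdname term_distance_steps
#' @export
term_distance_lca <- function(tree, a, b) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  if (!a %in% tree$terms || !b %in% tree$terms)
    stop("term not in the hierarchy")
  anc <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier)) {
      ps <- unique(unlist(tree$parents[frontier]))
      ps <- setdiff(ps, out)
      out <- c(out, ps)
      frontier <- ps
    }
    out
  }
  common <- intersect(anc(a), anc(b))
  min(tree$level[common])
}

#' Hypergeometric overrepresentation of annotation terms in blocks
#'
#' For every block and every term whose annotated entities within the
#' universe number between `min_size` and `max_size`, the upper-tail
#' hypergeometric p-value of the block/term overlap is computed, adjusted by
#' Benjamini-Hochberg across the tested terms of the block; the q-value
#' column carries the BH-adjusted p. Rows are kept when the raw p-value is
#' below `alpha` and the q-value below `q_max`. Metabolite-style annotations
#' use `min_size = 2`.
#'
#' @param blocks named vector: entity id -> block label (the partition at one
#'   hierarchy level).
#' @param ann named list: term id -> entity ids.
#' @param universe entity ids forming the background (all entities of the
#'   network); defaults to `names(blocks)`.
#' @param min_size,max_size term size filter, applied to the term's entities
#'   within the universe.
#' @param alpha raw p-value cutoff.
#' @param q_max q-value cutoff.
#' @param level hierarchy level tag copied into the output.
#' @return data frame `(block, level, term, overlap, term_size, block_size,
#'   p, p_adjusted, q)`, one row per kept block/term pair.
#' @export
overrepresentation <- function(blocks, ann, universe = names(blocks),
                               min_size = 10, max_size = 500,
                               alpha = 0.05, q_max = 0.2, level = 1L) {
  if (length(universe) == 0) stop("empty universe")
  stopifnot(!is.null(names(blocks)))
  blocks <- blocks[names(blocks) %in% universe]
  term_sets <- lapply(ann, intersect, universe)
  sizes <- lengths(term_sets)
  tested <- names(term_sets)[sizes >= min_size & sizes <= max_size]
  out <- list()
  Nu <- length(universe)
  for (blk in sort(unique(blocks))) {
    members <- names(blocks)[blocks == blk]
    nb <- length(members)
    if (!length(tested)) next
    ov <- vapply(tested, function(t) length(intersect(term_sets[[t]], members)),
                 integer(1))
    K <- sizes[tested]
    p <- stats::phyper(ov - 1, K, Nu - K, nb, lower.tail = FALSE)
    p_adj <- stats::p.adjust(p, method = "BH")
    q <- p_adj  # BH-adjusted p as the practical q-value proxy
    keep <- p < alpha & q < q_max
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        block = blk, level = level, term = tested[keep],
        overlap = ov[keep], term_size = unname(K[keep]), block_size = nb,
        p = p[keep], p_adjusted = p_adj[keep], q = q[keep],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(out)) {
    return(data.frame(block = character(0), level = integer(0),
                      term = character(0), overlap = integer(0),
                      term_size = integer(0), block_size = integer(0),
                      p = numeric(0), p_adjusted = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Percentage of blocks with at least one overrepresented term
#'
#' @inheritParams overrepresentation
#' @param ... further arguments to [overrepresentation()].
#' @return a single percentage in `[0, 100]`.
#' @export
block_annotation_rate <- function(blocks, ann, universe = names(blocks), ...) {
  enr <- overrepresentation(blocks, ann, universe, ...)
  100 * length(unique(enr$block)) / length(unique(blocks))
}

#' Shuffle null for the block annotation rate
#'
#' Permutes the entity labels uniformly while keeping the block structure of
#' every level fixed, and recomputes the percentage of blocks with at least
#' one overrepresented term per shuffle and level.
#'
#' @param partition_levels list of named membership vectors (entity -> block),
#'   one per hierarchy level.
#' @param ann,universe,... as in [overrepresentation()].
#' @param n_shuffles number of shuffles (default 3).
#' @param seed integer seed.
#' @return numeric matrix `n_shuffles x levels` of percentages.
#' @export
shuffle_null <- function(partition_levels, ann, universe = NULL,
                         n_shuffles = 3, seed = 1L, ...) {
  if (!is.list(partition_levels)) partition_levels <- list(partition_levels)
  ids <- names(partition_levels[[1L]])
  if (is.null(universe)) universe <- ids
  set.seed(seed)
  out <- matrix(NA_real_, n_shuffles, length(partition_levels))
  for (sh in seq_len(n_shuffles)) {
    perm <- sample(ids)
    for (l in seq_along(partition_levels)) {
      shuffled <- stats::setNames(unname(partition_levels[[l]]), perm)
      out[sh, l] <- block_annotation_rate(shuffled, ann, universe, level = l, ...)
    }
  }
  dimnames(out) <- list(paste0("shuffle", seq_len(n_shuffles)),
                        paste0("level", seq_along(partition_levels)))
  out
}

#' Within- versus between-block term distances
#'
#' Only blocks with at least one overrepresented term enter. Per block pair,
#' the median distance over all cross-term combinations; per block (with at
#' least two distinct terms), the median over all unordered distinct term
#' pairs -- the trivial zero distances of a term to itself are omitted.
#' Welch's unequal-variance t-test compares the within and between lists.
#'
#' @param enr an [overrepresentation()] table (one level).
#' @param tree a [hierarchy_tree()].
#' @param measure `"steps"` (shortest path) or `"lca"` (level of the lowest
#'   common ancestor).
#' @return list with `within`, `between` (numeric vectors), `welch_p`, and
#'   `defined` (FALSE when fewer than 2 usable blocks or degenerate lists).
#' @export
block_distance_summary <- function(enr, tree, measure = c("steps", "lca")) {
  measure <- match.arg(measure)
  dist_fun <- if (measure == "steps") term_distance_steps else term_distance_lca
  terms_by_block <- split(enr$term, enr$block)
  blocks <- names(terms_by_block)
  if (length(blocks) < 2)
    return(list(within = numeric(0), between = numeric(0),
                welch_p = NA_real_, defined = FALSE))
  pair_dist <- function(ta, tb) {
    vapply(seq_along(ta), function(q) dist_fun(tree, ta[q], tb[q]), numeric(1))
  }
  within <- numeric(0)
  for (blk in blocks) {
    ts <- unique(terms_by_block[[blk]])
    if (length(ts) < 2) next
    cmb <- utils::combn(ts, 2)
    within <- c(within, stats::median(pair_dist(cmb[1L, ], cmb[2L, ])))
  }
  between <- numeric(0)
  cmbb <- utils::combn(blocks, 2)
  for (q in seq_len(ncol(cmbb))) {
    ta <- unique(terms_by_block[[cmbb[1L, q]]])
    tb <- unique(terms_by_block[[cmbb[2L, q]]])
    grid <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
    between <- c(between, stats::median(pair_dist(grid$a, grid$b)))
  }
  if (!length(within) || !length(between))
    return(list(within = within, between = between,
                welch_p = NA_real_, defined = FALSE))
  const_w <- length(within) == 1 || stats::sd(within) == 0
  const_b <- length(between) == 1 || stats::sd(between) == 0
  welch_p <- if (const_w && const_b) {
    if (isTRUE(all.equal(mean(within), mean(between)))) 1 else 0
  } else if (length(within) < 2 || length(between) < 2) {
    NA_real_
  } else {
    stats::t.test(within, between)$p.value
  }
  list(within = within, between = between, welch_p = welch_p,
       defined = is.finite(welch_p))
}

#' Distance between blocks in the SBM hierarchy
#'
#' Number of steps from one block to the other through their lowest common
#' higher-level block: `2 * (m - level)` where `m` is the first level at
#' which the two blocks share an ancestor; 0 for identical blocks.
#'
#' @param state a hierarchical [sbm_state()].
#' @param r,s block labels at `level`.
#' @param level hierarchy level the blocks live on (default 1).
#' @return a non-negative integer.
#' @export
sbm_block_distance <- function(state, r, s, level = 1L) {
  stopifnot(inherits(state, "sbm_state"))
  L <- length(state$levels)
  if (level > L) stop("level exceeds the hierarchy depth")
  Bl <- state$B[level]
  if (r < 1 || r > Bl || s < 1 || s > Bl) stop("no such block at this level")
  if (r == s) return(0L)
  if (!state$hierarchical) stop("state has no hierarchy above level 1")
  ru <- r; su <- s
  for (m in seq(level + 1L, L)) {
    ru <- state$levels[[m]][ru]; su <- state$levels[[m]][su]
    if (ru == su) return(2L * (m - level))
  }
  stop("blocks never merge below the top; hierarchy boundary violated")
}

#' Summarize overrepresented terms by their top-level parent
#'
#' Each overrepresented term is counted once per block it appears in and
#' mapped to its top-level parent (the child of the artificial root on the
#' term's ancestry; the lexicographically first one for terms with multiple
#' parents). The raw percentage is the parent's share of all overrepresented
#' rows at the level; the relative score divides it by the parent's share of
#' all terms in the hierarchy, flagging parents that appear more often than
#' their size suggests.
#'
#' @param enr an [overrepresentation()] table (any mix of levels).
#' @param tree a [hierarchy_tree()].
#' @return data frame `(parent, level, n, raw_pct, parent_share_pct,
#'   relative_score)`.
#' @export
parent_term_summary <- function(enr, tree) {
  if (!nrow(enr))
    return(data.frame(parent = character(0), level = integer(0),
                      n = integer(0), raw_pct = numeric(0),
                      parent_share_pct = numeric(0),
                      relative_score = numeric(0), stringsAsFactors = FALSE))
  top_terms <- sort(tree$children[[tree$root]])
  top_of <- function(t) {
    if (t %in% top_terms) return(t)
    frontier <- t
    seen <- character(0)
    repeat {
      ps <- sort(unique(unlist(tree$parents[frontier])))
      hit <- intersect(ps, top_terms)
      if (length(hit)) return(hit[1L])
      if (tree$root %in% ps) return(tree$root)  # orphan, counted under the root
      frontier <- setdiff(ps, seen)
      if (!length(frontier)) return(tree$root)
      seen <- c(seen, frontier)
    }
  }
  ## share of the annotation: sub-terms mapped to each top-level parent,
  ## relative to all sub-terms (the parents themselves are the categories,
  ## not members); parents without sub-terms count themselves
  sub_terms <- setdiff(tree$terms, c(tree$root, top_terms))
  share <- table(vapply(sub_terms, top_of, character(1)))
  childless <- setdiff(top_terms, names(share))
  if (length(childless))
    share <- c(share, stats::setNames(rep(1L, length(childless)), childless))
  share_pct <- 100 * as.numeric(share) / max(1L, length(sub_terms))
  names(share_pct) <- names(share)

  out <- list()
  for (lv in sort(unique(enr$level))) {
    rows <- enr[enr$level == lv, ]
    parent <- vapply(rows$term, top_of, character(1))
    cnt <- table(parent)
    raw_pct <- 100 * as.numeric(cnt) / nrow(rows)
    ps <- share_pct[names(cnt)]
    out[[length(out) + 1L]] <- data.frame(
      parent = names(cnt), level = lv, n = as.integer(cnt),
      raw_pct = raw_pct, parent_share_pct = unname(ps),
      relative_score = raw_pct / unname(ps),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
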