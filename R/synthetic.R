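## Generators for graphs with planted (possibly nested, possibly
## degree-heterogeneous) block structure, expression matrices with planted
## co-expression modules, and synthetic annotation hierarchies. These define
## the study conditions every downstream stage is exercised under.

#' Specification of a planted block structure
#'
#' @param block_sizes positive integers: number of nodes per level-1 block.
#' @param edge_count_matrix symmetric non-negative integer matrix `e`; the
#'   diagonal holds twice the within-block edge count (so every `e_rr` must be
#'   even and `sum(e)` is twice the total edge count).
#' @param degree_sequence optional integer degrees per node (nodes ordered
#'   block by block); within every block the degrees must sum to the block
#'   degree sum `e_r = rowSums(e)[r]`.
#' @param hierarchy optional list of coarser partitions of the blocks, one per
#'   extra level (the same shape as the upper levels of [sbm_state()]).
#' @param seed integer seed.
#' @return an object of class `planted_spec`.
#' @export
planted_spec <- function(block_sizes, edge_count_matrix, degree_sequence = NULL,
                         hierarchy = NULL, seed = 1L) {
  block_sizes <- as.integer(block_sizes)
  e <- as.matrix(edge_count_matrix)
  stopifnot(all(block_sizes > 0), nrow(e) == length(block_sizes),
            ncol(e) == length(block_sizes))
  if (!isTRUE(all.equal(e, t(e)))) stop("edge_count_matrix must be symmetric")
  if (any(e < 0) || any(e != round(e))) stop("edge counts must be non-negative integers")
  if (any(diag(e) %% 2 != 0)) stop("diagonal entries e_rr must be even (doubled within-block counts)")
  if (sum(e) %% 2 != 0) stop("total edge count E = sum(e)/2 must be an integer")
  if (!is.null(degree_sequence)) {
    k <- as.integer(degree_sequence)
    if (length(k) != sum(block_sizes)) stop("degree_sequence must cover every node")
    if (any(k < 0)) stop("degrees must be non-negative")
    b <- rep(seq_along(block_sizes), block_sizes)
    ksum <- as.vector(rowsum(k, b))
    if (!all(ksum == rowSums(e)))
      stop("per-block degree sums must equal the block degree sums e_r")
    degree_sequence <- k
  }
  structure(list(block_sizes = block_sizes, edge_count_matrix = e,
                 degree_sequence = degree_sequence, hierarchy = hierarchy,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Sample a graph with exactly the planted block structure
#'
#' Draws a simple undirected graph whose block-wise edge counts equal the
#' specification exactly, and, when a degree sequence is given, whose node
#' degrees equal it exactly (microcanonical sampling). Without a degree
#' sequence, edges are placed uniformly at random among the distinct node
#' pairs of each block pair. With one, half-edge stubs are matched per block
#' pair and multi-/self-edges are repaired by degree-preserving edge swaps
#' within the same block-pair class; if repair does not terminate within the
#' sweep bound, the requested combination is declared infeasible.
#'
#' @param spec a [planted_spec()].
#' @param max_repair_sweeps bound on repair sweeps before declaring the
#'   `(e, k)` combination infeasible.
#' @return a list with `graph` (a [reduced_graph]) and `membership` (the
#'   planted level-1 block of every node).
#' @export
sample_sbm_graph <- function(spec, max_repair_sweeps = 1e4) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  sizes <- spec$block_sizes
  e <- spec$edge_count_matrix
  Bn <- length(sizes)
  b <- rep(seq_len(Bn), sizes)
  offset <- c(0L, cumsum(sizes))
  N <- sum(sizes)

  ## feasibility of the counts alone
  for (r in seq_len(Bn)) {
    if (e[r, r] / 2 > choose(sizes[r], 2))
      stop(sprintf("infeasible: e_%d%d/2 = %d exceeds the %d possible within-block pairs",
                   r, r, e[r, r] / 2, choose(sizes[r], 2)))
    for (s in seq_len(Bn)) if (s > r && e[r, s] > sizes[r] * sizes[s])
      stop(sprintf("infeasible: e_%d%d = %d exceeds the %d possible between-block pairs",
                   r, s, e[r, s], sizes[r] * sizes[s]))
  }

  edges <- if (is.null(spec$degree_sequence)) {
    sample_edges_uniform(e, sizes, offset)
  } else {
    sample_edges_stub_matching(e, sizes, offset, spec$degree_sequence,
                               max_repair_sweeps)
  }
  g <- igraph::make_empty_graph(N, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(N))
  g <- igraph::add_edges(g, t(edges))
  out <- reduced_graph(g, provenance = list(method = "planted",
                                            seed = spec$seed))
  list(graph = out, membership = b)
}

## uniform placement: sample e_rs distinct pairs per block pair
sample_edges_uniform <- function(e, sizes, offset) {
  Bn <- length(sizes)
  out <- list()
  for (r in seq_len(Bn)) {
    m_rr <- e[r, r] / 2
    if (m_rr > 0) {
      pairs <- utils::combn(sizes[r], 2)
      pick <- sample.int(ncol(pairs), m_rr)
      out[[length(out) + 1L]] <- cbind(offset[r] + pairs[1L, pick],
                                       offset[r] + pairs[2L, pick])
    }
    for (s in seq_len(Bn)) if (s > r && e[r, s] > 0) {
      idx <- sample.int(sizes[r] * sizes[s], e[r, s]) - 1L
      out[[length(out) + 1L]] <- cbind(offset[r] + idx %% sizes[r] + 1L,
                                       offset[s] + idx %/% sizes[r] + 1L)
    }
  }
  do.call(rbind, c(out, list(matrix(integer(0), 0, 2))))
}

## stub matching with edge-swap repair, preserving (e, k) exactly
sample_edges_stub_matching <- function(e, sizes, offset, k, max_repair_sweeps) {
  Bn <- length(sizes)
  b <- rep(seq_len(Bn), sizes)
  stubs <- lapply(seq_len(Bn), function(r) {
    nodes <- which(b == r)
    s <- rep(nodes, k[nodes])
    if (length(s)) sample(s) else integer(0)
  })
  ptr <- rep(1L, Bn)
  take <- function(r, m) {
    out <- stubs[[r]][seq_len(m) + ptr[r] - 1L]
    ptr[r] <<- ptr[r] + m
    out
  }
  classes <- list(); edges <- list()
  for (r in seq_len(Bn)) {
    if (e[r, r] > 0) {
      s2 <- take(r, e[r, r])
      edges[[length(edges) + 1L]] <- matrix(s2, ncol = 2)
      classes[[length(classes) + 1L]] <- c(r, r)
    }
    for (s in seq_len(Bn)) if (s > r && e[r, s] > 0) {
      edges[[length(edges) + 1L]] <- cbind(take(r, e[r, s]), take(s, e[r, s]))
      classes[[length(classes) + 1L]] <- c(r, s)
    }
  }
  ## repair multi-/self-edges by swaps within each class; swapping endpoints
  ## of two same-class edges preserves both e and the degree sequence
  n_bad <- function(ed) {
    key <- pmin(ed[, 1L], ed[, 2L]) * 1e6 + pmax(ed[, 1L], ed[, 2L])
    sum(ed[, 1L] == ed[, 2L] | key %in% key[duplicated(key)])
  }
  for (ci in seq_along(edges)) {
    ed <- edges[[ci]]
    within <- classes[[ci]][1L] == classes[[ci]][2L]
    if (nrow(ed) < 2L) {
      if (n_bad(ed) > 0) stop("infeasible (e, k) combination: a single self-edge cannot be repaired")
      edges[[ci]] <- ed
      next
    }
    propose <- function(ed, i, j) {
      prop <- ed
      if (within && stats::runif(1) < 0.5) {
        prop[i, ] <- c(ed[i, 1L], ed[j, 1L])
        prop[j, ] <- c(ed[i, 2L], ed[j, 2L])
      } else {
        prop[i, 2L] <- ed[j, 2L]
        prop[j, 2L] <- ed[i, 2L]
      }
      prop
    }
    bad_key <- function(ed) {
      key <- pmin(ed[, 1L], ed[, 2L]) * 1e6 + pmax(ed[, 1L], ed[, 2L])
      which(ed[, 1L] == ed[, 2L] | key %in% key[duplicated(key)])
    }
    sweeps <- 0; stale <- 0
    repeat {
      bad <- bad_key(ed)
      if (!length(bad)) break
      sweeps <- sweeps + 1
      if (sweeps > max_repair_sweeps)
        stop("infeasible (e, k) combination: edge-swap repair did not terminate")
      cur <- n_bad(ed)
      i <- if (length(bad) == 1L) bad else sample(bad, 1L)
      moved <- FALSE
      for (try in seq_len(30L)) {
        j <- sample.int(nrow(ed), 1L)
        if (i == j) next
        prop <- propose(ed, i, j)
        nb <- n_bad(prop)
        if (nb < cur) { ed <- prop; moved <- TRUE; break }
        if (nb == cur && try == 30L) ed <- prop  # plateau move to escape cycles
      }
      stale <- if (moved) 0 else stale + 1
      if (stale >= 200L) {  # random restart of this class pairing
        stubs_flat <- c(ed[, 1L], ed[, 2L])
        if (within) {
          s2 <- sample(stubs_flat)
          ed <- matrix(s2, ncol = 2)
        } else {
          ed <- cbind(sample(ed[, 1L]), sample(ed[, 2L]))
        }
        stale <- 0
      }
    }
    edges[[ci]] <- ed
  }
  do.call(rbind, c(edges, list(matrix(integer(0), 0, 2))))
}

#' Specification of planted co-expression modules
#'
#' @param module_sizes integer entities per module.
#' @param n_samples number of samples (columns).
#' @param within_module_correlation target absolute Spearman correlation
#'   between entities of the same module, in `[0, 1]`; a single value or one
#'   per module (modules of real data differ in co-expression strength).
#' @param anticorrelated_fraction fraction of entities per module whose
#'   loading on the shared factor is sign-flipped.
#' @param na_rate expected fraction of missing cells.
#' @param na_mechanism `"random"` (missing completely at random) or
#'   `"log_zero_sentinel"` (cells marked missing the way log-transformed zero
#'   counts are, to be replaced by a sentinel by the missing-value policy).
#' @param seed integer seed.
#' @return an object of class `expression_spec`.
#' @export
expression_spec <- function(module_sizes, n_samples,
                            within_module_correlation = 0.7,
                            anticorrelated_fraction = 0,
                            na_rate = 0,
                            na_mechanism = c("random", "log_zero_sentinel"),
                            seed = 1L) {
  na_mechanism <- match.arg(na_mechanism)
  if (any(within_module_correlation < 0) || any(within_module_correlation > 1))
    stop("within_module_correlation must lie in [0, 1]")
  if (!length(within_module_correlation) %in% c(1L, length(module_sizes)))
    stop("within_module_correlation must be a single target or one per module")
  within_module_correlation <- rep_len(within_module_correlation,
                                       length(module_sizes))
  stopifnot(anticorrelated_fraction >= 0, anticorrelated_fraction <= 1,
            na_rate >= 0, na_rate <= 1, n_samples >= 2)
  structure(list(module_sizes = as.integer(module_sizes),
                 n_samples = as.integer(n_samples),
                 within_module_correlation = within_module_correlation,
                 anticorrelated_fraction = anticorrelated_fraction,
                 na_rate = na_rate, na_mechanism = na_mechanism,
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Sample an expression matrix with planted co-expression modules
#'
#' Entities of a module share a latent per-sample factor; each entity `i`
#' observes `a_i * f + sqrt(1 - a_i^2) * noise` with all components Gaussian,
#' so a pair of same-module entities has Pearson correlation `a^2`. The
#' loading magnitude is calibrated so that the implied large-sample Spearman
#' correlation, `(6 / pi) * asin(a^2 / 2)`, hits the requested target (the
#' Pearson-on-ranks approximation for bivariate normal data). A fraction of
#' loadings is sign-flipped to plant anticorrelation without changing the
#' absolute correlation the reduction consumes. Missing cells are injected
#' at `na_rate` per the chosen mechanism.
#'
#' @param spec an [expression_spec()].
#' @return a list with `matrix` (entities x samples, `NA` for missing,
#'   attribute `na_mechanism`) and `membership` (planted module per entity).
#' @export
sample_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(spec$seed)
  n <- sum(spec$module_sizes)
  m <- spec$n_samples
  member <- rep(seq_along(spec$module_sizes), spec$module_sizes)

  rho_s <- spec$within_module_correlation
  rho_p <- 2 * sin(pi * rho_s / 6)  # invert the Spearman/Pearson relation
  a_mod <- sqrt(rho_p)              # one loading magnitude per module

  x <- matrix(0, n, m)
  for (mod in seq_along(spec$module_sizes)) {
    rows <- which(member == mod)
    a <- a_mod[mod]
    f <- stats::rnorm(m)
    load <- rep(a, length(rows))
    n_flip <- round(spec$anticorrelated_fraction * length(rows))
    if (n_flip > 0) load[sample(length(rows), n_flip)] <- -a
    noise <- matrix(stats::rnorm(length(rows) * m), length(rows), m)
    x[rows, ] <- load %o% f + sqrt(max(0, 1 - a^2)) * noise
  }
  rownames(x) <- sprintf("ent%03d", seq_len(n))
  colnames(x) <- sprintf("s%03d", seq_len(m))

  if (spec$na_rate > 0) {
    miss <- if (spec$na_mechanism == "log_zero_sentinel") {
      ## zero-count dropouts hit the low end of the abundance scale: the
      ## na_rate fraction of lowest values is censored
      x <= stats::quantile(x, spec$na_rate)
    } else {
      matrix(stats::runif(n * m) < spec$na_rate, n, m)
    }
    x[miss] <- NA
  }
  attr(x, "na_mechanism") <- spec$na_mechanism
  list(matrix = x, membership = member)
}

#' Sample an annotation set aligned with planted modules
#'
#' Builds a rooted term hierarchy of the requested depth and leaf-term entity
#' sets that interpolate between the planted modules (`alignment = 1`: each
#' module's leaf term is exactly its entity set) and uniform random sets
#' (`alignment = 0`). Extra leaf terms beyond the number of modules get
#' random entity sets of module-like size.
#'
#' @param membership planted module label per entity (entity names taken from
#'   `names(membership)` if present, else `ent%03d`).
#' @param n_terms number of leaf terms (>= number of modules when
#'   `alignment == 1`).
#' @param hierarchy_depth depth of the term tree (>= 1); leaves sit
#'   `hierarchy_depth - 1` steps below the root.
#' @param alignment in `[0, 1]`; per entity, the probability of being
#'   annotated to its own module's term rather than a random one.
#' @param seed integer seed.
#' @return a list with `annotation` (named list term -> entity ids) and
#'   `hierarchy` (a [hierarchy_tree()]).
#' @export
sample_annotation <- function(membership, n_terms = NULL, hierarchy_depth = 2,
                              alignment = 1, seed = 1L) {
  stopifnot(hierarchy_depth >= 1, alignment >= 0, alignment <= 1)
  set.seed(seed)
  n_modules <- length(unique(membership))
  if (is.null(n_terms)) n_terms <- n_modules
  if (alignment == 1 && n_terms < n_modules)
    stop("alignment = 1 requires at least one term per module")
  ids <- names(membership)
  if (is.null(ids)) ids <- sprintf("ent%03d", seq_along(membership))

  terms <- sprintf("T%03d", seq_len(n_terms))
  ann <- stats::setNames(vector("list", n_terms), terms)
  ## consecutive grouping: terms of one module are neighbors, so they end up
  ## as siblings in the synthetic hierarchy
  mod_of_term <- if (n_terms >= n_modules)
    rep(seq_len(n_modules), each = ceiling(n_terms / n_modules))[seq_len(n_terms)]
  else c(seq_len(n_terms))
  mean_size <- max(2L, round(length(ids) / n_modules))
  for (t in seq_len(n_terms)) {
    mod <- mod_of_term[t]
    if (!is.na(mod)) {
      own <- ids[membership == mod]
      keep <- stats::runif(length(own)) < alignment
      pool <- setdiff(ids, own[keep])
      extra <- if (sum(!keep) > 0) sample(pool, sum(!keep)) else character(0)
      ann[[t]] <- sort(unique(c(own[keep], extra)))
      if (length(ann[[t]]) == 0) ann[[t]] <- sample(ids, mean_size)
    } else {
      ann[[t]] <- sort(sample(ids, mean_size))
    }
  }

  ## rooted tree of the stated depth: a chain of internal layers over the leaves
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  ## the artificial root added by hierarchy_tree() is the top of the stated
  ## depth, so only hierarchy_depth - 2 internal layers are built
  lower <- terms
  if (hierarchy_depth > 2) for (d in seq_len(hierarchy_depth - 2L)) {
    n_up <- max(1L, ceiling(length(lower) / 2))
    upper <- sprintf("I%d_%02d", d, seq_len(n_up))
    per <- ceiling(length(lower) / n_up)
    par <- upper[ceiling(seq_along(lower) / per)]
    edges <- rbind(edges, data.frame(parent = par, child = lower,
                                     stringsAsFactors = FALSE))
    lower <- upper
  }
  tree <- hierarchy_tree(edges, terms = terms)
  list(annotation = ann, hierarchy = tree)
}
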