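# Fixture builders and enumeration oracles shared across the suite.

named_graph <- function(g) {
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  g
}

two_cliques_graph <- function(size = 10) {
  g <- igraph::disjoint_union(igraph::make_full_graph(size),
                              igraph::make_full_graph(size))
  named_graph(igraph::add_edges(g, c(1, size + 1)))
}

single_edge_graph <- function() {
  named_graph(igraph::make_graph(c(1, 2), directed = FALSE))
}

# All multigraphs with E edges on N nodes (loops allowed), as multisets of
# pair indices; returns a list of adjacency matrices with A_ii = 2 * loops.
enumerate_multigraphs <- function(N, E) {
  pairs <- which(upper.tri(matrix(0, N, N), diag = TRUE), arr.ind = TRUE)
  P <- nrow(pairs)
  sel <- utils::combn(P + E - 1, E)  # multisets via stars and bars
  lapply(seq_len(ncol(sel)), function(ci) {
    idx <- sel[, ci] - seq_len(E) + 1L  # decode multiset
    A <- matrix(0L, N, N)
    for (pi in idx) {
      i <- pairs[pi, 1L]; j <- pairs[pi, 2L]
      if (i == j) A[i, i] <- A[i, i] + 2L
      else { A[i, j] <- A[i, j] + 1L; A[j, i] <- A[j, i] + 1L }
    }
    A
  })
}

# block edge-count matrix (doubled diagonal) of a multigraph adjacency
block_counts_from_adjacency <- function(A, b, B) {
  e <- matrix(0, B, B)
  N <- nrow(A)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) e[b[i], b[i]] <- e[b[i], b[i]] + A[i, i]
    else e[b[i], b[j]] <- e[b[i], b[j]] + A[i, j]
  }
  e
}

multigraph_degrees <- function(A) rowSums(A)

# naive direct evaluation of the classical likelihood from the displayed
# formula, in plain double arithmetic (all factorial arguments small enough
# to be exact)
naive_loglik_classical <- function(e, nr, A) {
  num <- prod(factorial(e[upper.tri(e)])) *
    prod(2^(diag(e) / 2) * factorial(diag(e) / 2))
  den <- prod(nr^rowSums(e)) *
    prod(factorial(A[upper.tri(A)])) *
    prod(2^(diag(A) / 2) * factorial(diag(A) / 2))
  log2(num / den)
}

naive_loglik_dc <- function(e, k, A) {
  num <- prod(factorial(e[upper.tri(e)])) *
    prod(2^(diag(e) / 2) * factorial(diag(e) / 2)) * prod(factorial(k))
  den <- prod(factorial(rowSums(e))) *
    prod(factorial(A[upper.tri(A)])) *
    prod(2^(diag(A) / 2) * factorial(diag(A) / 2))
  log2(num / den)
}

# all surjective labelings of N units onto 1..B
surjective_labelings <- function(N, B) {
  labs <- as.matrix(expand.grid(rep(list(seq_len(B)), N)))
  labs[apply(labs, 1, function(b) length(unique(b)) == B), , drop = FALSE]
}

# study conditions for the planted-recovery and selection experiments
planted_assortative_spec <- function(seed, n_blocks = 3, block_size = 20,
                                     d_within = 0.6, d_between = 0.12) {
  e_rr <- 2 * round(d_within * choose(block_size, 2))
  e_rs <- round(d_between * block_size^2)
  em <- matrix(e_rs, n_blocks, n_blocks); diag(em) <- e_rr
  planted_spec(rep(block_size, n_blocks), em, seed = seed)
}

planted_heterogeneous_spec <- function(seed) {
  em <- matrix(30, 3, 3); diag(em) <- 80
  k <- rep(c(rep(2L, 10), rep(12L, 10)), 3)
  planted_spec(rep(20L, 3), em, degree_sequence = k, seed = seed)
}

# a small synthetic study: four planted modules of heterogeneous
# co-expression strength, with a module-aligned annotation hierarchy
e2e_dataset <- function(seed) {
  sp <- expression_spec(rep(15, 4), 40,
                        within_module_correlation = c(0.4, 0.55, 0.7, 0.85),
                        anticorrelated_fraction = 0.2, na_rate = 0.05,
                        seed = seed)
  em <- sample_expression_matrix(sp)
  ann <- sample_annotation(stats::setNames(em$membership, rownames(em$matrix)),
                           n_terms = 8, hierarchy_depth = 3, alignment = 1,
                           seed = seed)
  list(expr = em, ann = ann)
}
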