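# Exact microcanonical probabilities: worked examples and enumeration
# oracles over exhaustive tiny ensembles.

test_that("restricted partition counts follow the recurrence", {
  expect_equal(2^log_q_partitions(0, 0), 1)
  expect_equal(2^log_q_partitions(5, 5), 7)   # the 7 integer partitions of 5
  expect_equal(2^log_q_partitions(4, 2), 3)   # {4},{3,1},{2,2}
  expect_equal(2^log_q_partitions(4, 10), 5)  # m > n caps at q(n, n)
  expect_equal(log_q_partitions(3, 0), -Inf)
  expect_error(log_q_partitions(-1, 2), "non-negative")
  # vectorized and consistent with scalar evaluation
  n <- c(0, 1, 5, 9, 12); m <- c(0, 1, 3, 9, 5)
  expect_equal(log_q_partitions(n, m),
               vapply(seq_along(n), function(i) log_q_partitions(n[i], m[i]),
                      numeric(1)))
})

test_that("hand-evaluated worked examples hold exactly", {
  g <- single_edge_graph()
  st <- sbm_state(g, c(1, 1))
  expect_equal(2^loglik_classical(st), 0.5)       # 2!!/2^2
  expect_equal(2^log_prior_edges(st), 0.25)       # B=1, E=1
  expect_equal(2^log_prior_partition(c(1, 1)), 0.5)
  expect_equal(description_length(st)$total, 4)   # -log2(0.5 * 0.25 * 0.5)

  std <- sbm_state(g, c(1, 1), degree_corrected = TRUE)
  expect_equal(2^loglik_degree_corrected(std), 1) # (2!! 1! 1!) / 2!
  expect_equal(2^log_prior_degrees(std), 0.5)     # (2!/2!) / q(2,2)

  # empty graph: likelihood and edge prior are empty products
  ge <- named_graph(igraph::make_empty_graph(4, directed = FALSE))
  ste <- sbm_state(ge, rep(1, 4))
  expect_equal(loglik_classical(ste), 0)
  expect_equal(log_prior_edges(ste), 0)           # 0^0 = 1 convention
  expect_equal(description_length(ste)$total,
               -log_prior_partition(rep(1, 4)))
  sted <- sbm_state(ge, rep(1, 4), degree_corrected = TRUE)
  expect_equal(log_prior_degrees(sted), 0)        # all-zero degrees

  # N=3 singleton partition: (1/6) * C(2,2)^-1 * (1/3)
  expect_equal(2^log_prior_partition(c(1, 2, 3)), 1 / 18)
  # B=2, E=3: n_e = 1, P = 2^-6
  expect_equal(2^sbmnet:::k_prior_edges(3, 2), 1 / 64)
  # empty blocks are normalized away before evaluation
  expect_equal(log_prior_partition(c(1, 3, 3)), log_prior_partition(c(1, 2, 2)))
})

test_that("partition prior sums to one over surjective labelings (N = 3, 4)", {
  for (N in 3:4) {
    tot <- 0
    for (B in seq_len(N)) {
      labs <- surjective_labelings(N, B)
      tot <- tot + sum(apply(labs, 1, function(b)
        2^sbmnet:::k_prior_partition(tabulate(b, B), N)))
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("classical likelihood sums to one over multigraphs with fixed (e, b)", {
  for (cfg in list(list(N = 3, E = 2, b = c(1, 1, 2)),
                   list(N = 4, E = 3, b = c(1, 1, 2, 2)),
                   list(N = 4, E = 2, b = rep(1, 4)))) {
    graphs <- enumerate_multigraphs(cfg$N, cfg$E)
    B <- max(cfg$b)
    nr <- tabulate(cfg$b, B)
    e_key <- vapply(graphs, function(A)
      paste(block_counts_from_adjacency(A, cfg$b, B), collapse = ","),
      character(1))
    for (key in unique(e_key)) {
      members <- graphs[e_key == key]
      e <- block_counts_from_adjacency(members[[1]], cfg$b, B)
      tot <- sum(vapply(members, function(A)
        2^sbmnet:::k_loglik_classical(e, nr, aij = A[upper.tri(A)],
                                      aii = diag(A)), numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("degree-corrected likelihood sums to one over multigraphs with fixed (k, e, b)", {
  graphs <- enumerate_multigraphs(3, 3)
  b <- c(1, 1, 2); B <- 2
  key <- vapply(graphs, function(A)
    paste(c(block_counts_from_adjacency(A, b, B), multigraph_degrees(A)),
          collapse = ","), character(1))
  for (kk in unique(key)) {
    members <- graphs[key == kk]
    e <- block_counts_from_adjacency(members[[1]], b, B)
    k <- multigraph_degrees(members[[1]])
    tot <- sum(vapply(members, function(A)
      2^sbmnet:::k_loglik_dc(e, k, aij = A[upper.tri(A)], aii = diag(A)),
      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("degree prior sums to one over degree sequences (e_r <= 4)", {
  for (cfg in list(list(nr = 3, er = 4), list(nr = 2, er = 3),
                   list(nr = 4, er = 2))) {
    seqs <- as.matrix(expand.grid(rep(list(0:cfg$er), cfg$nr)))
    seqs <- seqs[rowSums(seqs) == cfg$er, , drop = FALSE]
    tot <- sum(apply(seqs, 1, function(k)
      2^sbmnet:::k_prior_degrees(k, rep(1, cfg$nr), cfg$nr, cfg$er)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("random instances match naive direct evaluation of the formulas", {
  set.seed(42)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(8, 0.4)
    g <- named_graph(g)
    b <- sample(1:2, 8, replace = TRUE)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    st <- sbm_state(g, b)
    e <- st$e_mats[[1]]
    expect_equal(loglik_classical(st),
                 naive_loglik_classical(e, st$n_units[[1]], A * 0),
                 tolerance = 1e-12)
    std <- sbm_state(g, b, degree_corrected = TRUE)
    expect_equal(loglik_degree_corrected(std),
                 naive_loglik_dc(e, igraph::degree(g), A * 0),
                 tolerance = 1e-12)
  }
})

test_that("nested edge prior: hand example and enumeration oracle", {
  # two lower blocks of sizes (2, 1); coarse matrix e_12 = 1 -> P = 1/2
  expect_equal(2^sbmnet:::k_prior_edges_nested_level(matrix(c(0, 1, 1, 0), 2),
                                                     c(2, 1)), 0.5)
  # sum over all admissible finer matrices equals one for E <= 3
  n_up <- c(2, 1)  # two upper blocks containing 2 and 1 lower blocks
  for (E in 1:3) {
    for (e12 in 0:E) {
      within_pairs <- c(3, 1)  # cells available inside each upper block
      e11 <- E - e12  # put the rest within upper block 1
      # enumerate finer matrices: distribute e12 over 2x1 cells and
      # e11 edges over the 3 within-cells of block 1
      n_ways_between <- choose(2 + e12 - 1, e12)
      n_ways_within <- choose(3 + e11 - 1, e11)
      e_up <- matrix(c(2 * e11, e12, e12, 0), 2)
      p <- 2^sbmnet:::k_prior_edges_nested_level(e_up, n_up)
      expect_equal(p * n_ways_between * n_ways_within, 1, tolerance = 1e-12)
    }
  }
})

test_that("hierarchical DL reduces to the flat prior substitution on trivial stacks", {
  g <- two_cliques_graph(5)
  b1 <- rep(1:2, each = 5)
  flat <- description_length(sbm_state(g, b1))
  nested <- description_length(sbm_state(g, list(b1, c(1, 1))))
  # identical likelihood, different (documented) prior terms
  expect_equal(flat$terms[["graph_loglik"]], nested$terms[["graph_loglik"]])
  expect_equal(nested$total - flat$total,
               (nested$total - nested$terms[["graph_loglik"]]) -
                 (flat$total - flat$terms[["graph_loglik"]]))
  # one-level boundary stack: only the top edge prior and no partition cost
  ge <- single_edge_graph()
  h1 <- description_length(sbm_state(ge, list(c(1, 1)), hierarchical = TRUE))
  expect_equal(h1$total,
               -sbmnet:::k_loglik_classical(matrix(2, 1, 1), 2L) -
                 sbmnet:::k_prior_edges(1, 1))
})

test_that("description length bookkeeping and posterior odds", {
  set.seed(7)
  g <- named_graph(igraph::sample_gnp(12, 0.3))
  st <- sbm_state(g, list(sample(1:3, 12, TRUE), c(1, 2, 1), c(1, 1)),
                  degree_corrected = TRUE)
  dl <- description_length(st)
  expect_equal(dl$total, sum(dl$terms), tolerance = 1e-9)
  expect_equal(posterior_odds(10, 12), 4)
  expect_equal(posterior_odds(12, 10), 0.25)
  expect_equal(posterior_odds(dl, dl), 1)
})
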