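# Reduction: significance route, setting choice, scale-free index and the
# hard-threshold scan.

# builds a corr_network object directly from given matrices
fake_network <- function(rho, pvalue, n_obs = NULL) {
  ids <- rownames(rho)
  if (is.null(n_obs)) n_obs <- matrix(10L, nrow(rho), ncol(rho),
                                      dimnames = dimnames(rho))
  structure(list(entity_ids = ids, rho = rho, pvalue = pvalue, n_obs = n_obs),
            class = "corr_network")
}

triple_network <- function(p12, p13, p23) {
  ids <- c("a", "b", "c")
  rho <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(rho) <- NA
  p <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  p["a", "b"] <- p["b", "a"] <- p12
  p["a", "c"] <- p["c", "a"] <- p13
  p["b", "c"] <- p["c", "b"] <- p23
  fake_network(rho, p)
}

test_that("significance reduction applies the corrected thresholds over tested pairs", {
  net <- triple_network(0.01, 0.02, 0.04)
  # BH step-up: adjusted (0.03, 0.03, 0.04) -> all pass 0.05, none pass 0.01
  expect_equal(igraph::ecount(significance_reduce(net, "bh", 0.05)$graph), 3)
  expect_equal(igraph::ecount(significance_reduce(net, "bh", 0.01)$graph), 0)
  # Bonferroni: (0.03, 0.06, 0.12) -> one passes 0.05
  g <- significance_reduce(net, "bonferroni", 0.05)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(sort(igraph::V(g$graph)$name[igraph::as_edgelist(g$graph,
                                                                names = FALSE)]),
               c("a", "b"))
  # never-significant input keeps the node set and drops all edges
  net1 <- triple_network(1, 1, 1)
  g1 <- significance_reduce(net1, "bh", 0.05)
  expect_equal(igraph::ecount(g1$graph), 0)
  expect_equal(igraph::vcount(g1$graph), 3)
  # stringency monotonicity on a random instance
  set.seed(5)
  m <- sample_expression_matrix(expression_spec(c(10, 10), 30,
                                                within_module_correlation = 0.6,
                                                seed = 5))$matrix
  net2 <- spearman_network(m)
  e_b01 <- igraph::ecount(significance_reduce(net2, "bonferroni", 0.01)$graph)
  e_b05 <- igraph::ecount(significance_reduce(net2, "bonferroni", 0.05)$graph)
  e_h05 <- igraph::ecount(significance_reduce(net2, "bh", 0.05)$graph)
  expect_lte(e_b01, e_b05)
  expect_lte(e_b05, e_h05)
})

test_that("the significance route equals |rho| thresholding when data are complete", {
  set.seed(6)
  m <- sample_expression_matrix(expression_spec(c(15, 15), 40,
                                                within_module_correlation = 0.5,
                                                seed = 6))$matrix
  net <- spearman_network(m)
  g <- significance_reduce(net, "bh", 0.05)
  kept <- abs(net$rho[upper.tri(net$rho)])[igraph::as_adjacency_matrix(
    g$graph, sparse = FALSE)[upper.tri(net$rho)] == 1]
  dropped <- abs(net$rho[upper.tri(net$rho)])[igraph::as_adjacency_matrix(
    g$graph, sparse = FALSE)[upper.tri(net$rho)] == 0]
  expect_gt(min(kept), max(dropped))  # a single implied |rho| cut

  # with missing values the implied correlation threshold blurs
  m2 <- m; m2[sample(length(m2), length(m2) * 0.25)] <- NA
  net2 <- spearman_network(m2)
  g2 <- significance_reduce(net2, "bh", 0.05)
  adj2 <- igraph::as_adjacency_matrix(g2$graph, sparse = FALSE)
  kept2 <- abs(net2$rho[upper.tri(net2$rho)])[adj2[upper.tri(net2$rho)] == 1]
  dropped2 <- abs(net2$rho[upper.tri(net2$rho)])[adj2[upper.tri(net2$rho)] == 0]
  expect_lt(min(kept2), max(dropped2, na.rm = TRUE))
})

test_that("setting choice maximizes connectedness under the edge budget", {
  reports <- data.frame(correction = c("bonferroni", "bonferroni", "bh", "bh"),
                        alpha = c(0.01, 0.05, 0.01, 0.05),
                        edges = c(2e7, 9e6, 5e6, 1e6),
                        lcc_pct = c(99, 94, 90, 30))
  pick <- choose_significance_setting(reports)
  expect_equal(pick$edges, 9e6)  # best LCC among settings under the budget
  expect_true(attr(pick, "reports")$chosen[2])
  # single qualifying setting
  r2 <- reports; r2$edges <- c(2e7, 3e7, 5e6, 2e7)
  expect_equal(choose_significance_setting(r2)$edges, 5e6)
  # ties break toward the more stringent setting
  r3 <- reports; r3$edges <- rep(1e6, 4); r3$lcc_pct <- rep(90, 4)
  p3 <- choose_significance_setting(r3)
  expect_equal(p3$correction, "bonferroni")
  expect_equal(p3$alpha, 0.01)
  r4 <- reports; r4$edges <- rep(2e7, 4)
  expect_error(choose_significance_setting(r4), "stricter")
})

test_that("scale-free fit index follows the binned log-log regression contract", {
  # power-law frequencies with a negative exponent fit well
  set.seed(9)
  ks <- 1:100
  deg <- sample(ks, 1e4, replace = TRUE, prob = ks^-2)
  expect_gte(scale_free_fit_index(deg), 0.9)
  # increasing frequency: zero by the slope-sign rule
  inc <- rep(1:10, times = 1:10)
  expect_equal(scale_free_fit_index(inc), 0)
  # two distinct degrees: two points fit a line exactly
  expect_equal(scale_free_fit_index(rep(c(3, 30), c(50, 10))), 1)
  # degree-zero nodes are excluded before binning
  expect_equal(scale_free_fit_index(c(rep(0, 5), rep(c(3, 30), c(50, 10)))), 1)
  expect_error(scale_free_fit_index(rep(4, 10)), "distinct")
})

test_that("hard-threshold scan returns the first qualifying grid point", {
  set.seed(10)
  g0 <- igraph::sample_pa(500, m = 1, directed = FALSE)
  rho <- matrix(runif(500 * 500, 0, 0.42), 500)
  rho[as.matrix(igraph::as_edgelist(g0))] <- 0.8
  rho <- pmax(rho, t(rho)); diag(rho) <- NA
  dimnames(rho) <- list(paste0("e", 1:500), paste0("e", 1:500))
  net <- fake_network(rho, rho * 0 + 0.5)
  grid <- seq(0.3, 0.95, by = 0.05)
  res <- pick_hard_threshold(net, grid = grid, r2_min = 0.85)
  # oracle: scan the grid by hand with the same index
  first <- NA
  for (t in grid) {
    deg <- rowSums(!is.na(rho) & abs(rho) >= t)
    r2 <- tryCatch(scale_free_fit_index(deg), error = function(e) NA)
    if (!is.na(r2) && r2 > 0.85) { first <- t; break }
  }
  expect_equal(res$threshold, first)
  expect_equal(igraph::ecount(res$graph$graph),
               sum(abs(rho[upper.tri(rho)]) >= first, na.rm = TRUE))
  # a permissive requirement returns the first computable grid point
  expect_equal(pick_hard_threshold(net, grid = c(0.5, 0.6, 0.7),
                                   r2_min = 0)$threshold, 0.5)
  # single failing threshold reports the best scan result
  expect_error(pick_hard_threshold(net, grid = 0.7, r2_min = 0.9999), "best")
})

test_that("graph statistics report nodes, edges, isolates and the LCC", {
  gc <- named_graph(igraph::make_full_graph(162))
  s <- graph_stats(gc)
  expect_equal(s$edges, 13041)
  expect_equal(s$lcc_size, 162)
  expect_equal(s$nodes_degree_zero, 0)

  ge <- named_graph(igraph::make_empty_graph(5, directed = FALSE))
  se <- graph_stats(ge)
  expect_equal(se$edges, 0)
  expect_equal(se$nodes_degree_zero, 5)
  expect_equal(se$lcc_size, 1)

  gt <- igraph::disjoint_union(igraph::make_full_graph(3),
                               igraph::make_full_graph(3),
                               igraph::make_empty_graph(1, directed = FALSE))
  st <- graph_stats(named_graph(gt))
  expect_equal(st$edges, 6)
  expect_equal(st$nodes_degree_zero, 1)
  expect_equal(st$lcc_size, 3)
})
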