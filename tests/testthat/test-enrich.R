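# Overrepresentation, tree distances, shuffle nulls and summaries.

toy_tree <- function() {
  hierarchy_tree(data.frame(parent = c("A", "A", "B", "B"),
                            child = c("a1", "a2", "b1", "b2")))
}

test_that("hypergeometric p-values match exhaustive enumeration on small universes", {
  ids <- paste0("g", 1:20)
  blocks <- stats::setNames(rep(1:4, each = 5), ids)
  enr <- overrepresentation(blocks, list(T1 = ids[1:5]), universe = ids,
                            min_size = 2)
  expect_equal(enr$p[enr$block == 1], 1 / choose(20, 5))  # perfect overlap

  # enumeration oracle: P(overlap >= o) by counting block draws
  set.seed(15)
  ids2 <- paste0("h", 1:12)
  term <- ids2[1:5]
  blocks2 <- stats::setNames(rep(1:2, each = 6), ids2)
  enr2 <- overrepresentation(blocks2, list(TT = term), universe = ids2,
                             min_size = 2, alpha = 1.1, q_max = 1.1)
  draws <- utils::combn(12, 6)
  for (blk in 1:2) {
    o <- length(intersect(term, names(blocks2)[blocks2 == blk]))
    p_enum <- mean(apply(draws, 2, function(d)
      length(intersect(ids2[d], term)) >= o))
    expect_equal(enr2$p[enr2$block == blk], p_enum, tolerance = 1e-12)
  }

  # size filters and the stated cutoffs
  expect_equal(nrow(overrepresentation(blocks, list(T1 = ids[1:9]),
                                       universe = ids, min_size = 10)), 0)
  expect_equal(nrow(overrepresentation(blocks, list(T1 = paste0("x", 1:12)),
                                       universe = ids, min_size = 2)), 0)
  expect_error(overrepresentation(blocks, list(T1 = ids), universe = character(0)),
               "universe")
  expect_true(all(enr$p_adjusted >= enr$p))
})

test_that("tree distances implement both measures with the level convention", {
  tr <- toy_tree()
  expect_equal(tr$level[["a1"]], 1)  # leaves at level 1
  expect_equal(tr$level[["A"]], 2)
  expect_equal(tr$level[[tr$root]], 3)  # depth-2 annotation, root above

  expect_equal(term_distance_steps(tr, "a1", "a1"), 0)
  expect_equal(term_distance_steps(tr, "a1", "a2"), 2)  # siblings
  expect_equal(term_distance_steps(tr, "a1", "b1"), 4)  # through the root
  expect_equal(term_distance_lca(tr, "a1", "a2"), 2)    # their parent's level
  expect_equal(term_distance_lca(tr, "a1", "b2"), 3)    # the artificial root
  expect_equal(term_distance_lca(tr, "A", "a1"), 2)     # chain: LCA is the parent
  expect_error(term_distance_steps(tr, "a1", "zz"), "not in")

  # symmetry, non-negativity and the triangle inequality for measure (i)
  terms <- setdiff(tr$terms, tr$root)
  D <- outer(terms, terms,
             Vectorize(function(x, y) term_distance_steps(tr, x, y)))
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  for (i in seq_along(terms)) for (j in seq_along(terms))
    for (l in seq_along(terms))
      expect_lte(D[i, j], D[i, l] + D[l, j])
})

test_that("hierarchy construction rejects cycles and handles flat term lists", {
  expect_error(hierarchy_tree(data.frame(parent = c("x", "y"),
                                         child = c("y", "x"))), "cycle")
  flat <- hierarchy_tree(data.frame(parent = character(0),
                                    child = character(0)),
                         terms = c("t1", "t2"))
  expect_equal(term_distance_steps(flat, "t1", "t2"), 2)
})

test_that("within-block term distances separate from between-block ones", {
  tr <- toy_tree()
  # blocks annotated with siblings score lower within than across branches
  enr <- data.frame(block = c(1, 1, 2, 2, 3, 3), level = 1,
                    term = c("a1", "a2", "a1", "b1", "b1", "b2"))
  s <- block_distance_summary(enr, tr, measure = "steps")
  expect_equal(sort(s$within), c(2, 2, 4))
  expect_equal(sort(s$between), c(3, 3, 4))
  expect_true(s$defined)

  # two blocks sharing one term: between-distance zero
  enr0 <- data.frame(block = c(1, 2), level = 1, term = c("a1", "a1"))
  s0 <- block_distance_summary(enr0, tr)
  expect_equal(s0$between, 0)
  expect_equal(length(s0$within), 0)  # single-term blocks are skipped
  expect_false(s0$defined)

  # identical constant lists: Welch p = 1 by the t = 0 convention
  # (a flat hierarchy makes every distinct-term distance equal to 2)
  flat <- hierarchy_tree(data.frame(parent = character(0),
                                    child = character(0)),
                         terms = paste0("t", 1:4))
  enr1 <- data.frame(block = c(1, 1, 2, 2), level = 1,
                     term = c("t1", "t2", "t3", "t4"))
  s1 <- block_distance_summary(enr1, flat)
  expect_equal(s1$within, c(2, 2))
  expect_equal(s1$between, 2)
  expect_equal(s1$welch_p, 1)
})

test_that("SBM-hierarchy block distances count steps through the common ancestor", {
  g <- named_graph(igraph::make_full_graph(6))
  st <- sbm_state(g, list(c(1, 1, 2, 2, 3, 3), c(1, 1, 2), c(1, 1)))
  expect_equal(sbm_block_distance(st, 1, 1, 1), 0)
  expect_equal(sbm_block_distance(st, 1, 2, 1), 2)  # siblings at level 2
  expect_equal(sbm_block_distance(st, 1, 3, 1), 4)  # merge only at the top
  expect_equal(sbm_block_distance(st, 1, 2, 2), 2)
  expect_error(sbm_block_distance(st, 1, 9, 1), "no such block")
})

test_that("shuffle nulls keep structure fixed and are seeded", {
  set.seed(16)
  mem <- stats::setNames(rep(1:3, each = 10), sprintf("ent%03d", 1:30))
  ann <- sample_annotation(mem, alignment = 1, seed = 3)$annotation
  r_true <- block_annotation_rate(mem, ann, min_size = 2)
  nulls <- shuffle_null(list(level1 = mem), ann, n_shuffles = 3, seed = 5,
                        min_size = 2)
  expect_equal(dim(nulls), c(3, 1))
  expect_gt(r_true, max(nulls))  # aligned annotation beats every shuffle
  nulls2 <- shuffle_null(list(level1 = mem), ann, n_shuffles = 3, seed = 5,
                         min_size = 2)
  expect_identical(nulls, nulls2)
})

test_that("parent-term summary normalizes by the parent's annotation share", {
  edges <- data.frame(parent = c(rep("P1", 10), rep("P2", 40)),
                      child = paste0("t", 1:50))
  tr <- hierarchy_tree(edges)
  enr <- data.frame(block = c(1, 1, 2, 3), level = 1,
                    term = c("t1", "t2", "t11", "t12"))
  ps <- parent_term_summary(enr, tr)
  expect_equal(ps$relative_score[ps$parent == "P1"], (2 / 4) / (10 / 50))
  # a single parent covering every term scores exactly 1
  edges1 <- data.frame(parent = "P", child = paste0("t", 1:6))
  ps1 <- parent_term_summary(data.frame(block = 1:2, level = 1,
                                        term = c("t1", "t4")),
                             hierarchy_tree(edges1))
  expect_equal(ps1$relative_score, 1)
  expect_equal(nrow(parent_term_summary(
    data.frame(block = character(0), level = integer(0), term = character(0)),
    tr)), 0)
})
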