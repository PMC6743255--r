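## Microcanonical SBM probabilities and description length, all in bits
## (base-2 logarithms). Four variants: classical, degree-corrected (dc),
## hierarchical (h), degree-corrected hierarchical (dch).
##
## Conventions enforced throughout:
##   * e_rr (diagonal of the block edge-count matrix) is TWICE the number of
##     within-block edges, so rowSums(e) gives the block degree sums e_r and
##     sum(e) == 2E at every level.
##   * multigraph adjacency bookkeeping uses A_ii = twice the number of
##     self-loops, matching the half-edge count at the node.
##   * empty-graph limits: 0^0 = 1 in the edge prior, q(0, m) = 1.

.q_cache <- new.env(parent = emptyenv())

#' Number of restricted integer partitions, in log2
#'
#' `q(n, m)` counts the partitions of `n` into at most `m` parts, via the
#' recurrence `q(n, m) = q(n, m - 1) + q(n - m, m)` with `q(0, m) = 1` and
#' `q(n, 0) = 0` for `n > 0`. Used by the uniform hyperprior on degree
#' sequences. Values are computed in log space (no overflow) and cached.
#'
#' @param n,m non-negative integers (vectorized over `n` and `m`).
#' @return `log2(q(n, m))`, with `-Inf` where the count is zero.
#' @export
log_q_partitions <- function(n, m) {
  if (any(n < 0) || any(m < 0)) stop("arguments to q(n, m) must be non-negative")
  n <- as.integer(n); m <- as.integer(m)
  m <- pmin(m, pmax(n, 1L))  # q(n, m) = q(n, n) for m >= n; keep m >= 1 when n >= 1
  nmax <- max(n, 1L); mmax <- max(m, 1L)
  tab <- .q_cache$tab
  if (is.null(tab) || nrow(tab) < nmax + 1L || ncol(tab) < mmax + 1L) {
    ## grow geometrically so repeated small extensions do not trigger rebuilds
    NN <- max(nmax, if (is.null(tab)) 0L else 2L * (nrow(tab) - 1L), 128L)
    MM <- max(mmax, if (is.null(tab)) 0L else 2L * (ncol(tab) - 1L), 64L)
    tab <- matrix(-Inf, NN + 1L, MM + 1L)  # [n + 1, m + 1]
    tab[1L, ] <- 0  # q(0, m) = 1
    for (mm in seq_len(MM)) {
      for (nn in seq_len(NN)) {
        a <- tab[nn + 1L, mm]                                    # q(nn, mm - 1)
        b <- if (nn >= mm) tab[nn - mm + 1L, mm + 1L] else -Inf  # q(nn - mm, mm)
        tab[nn + 1L, mm + 1L] <-
          if (a == -Inf) b
          else if (b == -Inf) a
          else if (a > b) a + log2(1 + 2^(b - a))
          else b + log2(1 + 2^(a - b))
      }
    }
    .q_cache$tab <- tab
  }
  .q_cache$tab[cbind(n + 1L, m + 1L)]
}

## ---- count-level kernels (used by the state wrappers, the fit engine and
## ---- the enumeration oracles in the test suite) ----

## log2 P(G|e,b) for a multigraph with block matrix e, block sizes nr and
## adjacency multiplicities: off-diagonal counts aij (vector) and loop
## half-edge counts aii (vector, even). For simple graphs both default to
## empty and the denominator term is 1.
k_loglik_classical <- function(e, nr, aij = integer(0), aii = integer(0)) {
  er <- rowSums(e)
  ut <- e[upper.tri(e)]
  sum(lf2(ut)) + sum(ldf2(diag(e))) - sum(xlog2y(er, nr)) -
    sum(lf2(aij)) - sum(ldf2(aii))
}

## log2 P(G|k,e,b); the denominator carries e_r! (plain factorial), the form
## under which the microcanonical ensemble normalizes.
k_loglik_dc <- function(e, k, aij = integer(0), aii = integer(0)) {
  er <- rowSums(e)
  ut <- e[upper.tri(e)]
  sum(lf2(ut)) + sum(ldf2(diag(e))) + sum(lf2(k)) - sum(lf2(er)) -
    sum(lf2(aij)) - sum(ldf2(aii))
}

## log2 P(e) = log2 [ n_e^E / (n_e + 1)^(E + B(B+1)/2) ], n_e = 2E / (B(B+1))
k_prior_edges <- function(E, B) {
  ne <- 2 * E / (B * (B + 1))
  xlog2y(E, ne) - (E + B * (B + 1) / 2) * log2(ne + 1)
}

## log2 P(b) from the block sizes nr of the B non-empty blocks among N units
k_prior_partition <- function(nr, N) {
  B <- length(nr)
  sum(lf2(nr)) - lf2(N) - lchoose2(N - 1, B - 1) - log2(N)
}

## log2 P(k|e,b): k degrees, b level-1 block of each node
k_prior_degrees <- function(k, b, nr, er) {
  B <- length(nr)
  kidx <- match(k, unique(k))
  eta <- tabulate((kidx - 1L) * B + b, B * max(kidx))
  sum(lf2(eta[eta > 0L])) - sum(lf2(nr)) - sum(log_q_partitions(er, nr))
}

## log2 P(e_l | e_{l+1}, grouping): coarse matrix e_up between upper blocks
## whose sizes (in units of the finer level) are n_up.
k_prior_edges_nested_level <- function(e_up, n_up) {
  ut <- upper.tri(e_up)
  nn <- outer(n_up, n_up)
  -sum(lmultiset2(nn[ut], e_up[ut])) -
    sum(lmultiset2(n_up * (n_up + 1) / 2, diag(e_up) / 2))
}

## ---- state-level API ----

#' Microcanonical SBM likelihoods and priors
#'
#' Exact base-2 log probabilities of the microcanonical stochastic block
#' model, evaluated on an [sbm_state()]. `loglik_classical()` is
#' `log2 P(G|e,b)`; `loglik_degree_corrected()` is `log2 P(G|k,e,b)`;
#' `log_prior_edges()` is the flat prior `log2 P(e)`;
#' `log_prior_degrees()` is `log2 P(k|e,b)` under the uniform hyperprior on
#' degree frequencies; `log_prior_hierarchy()` is
#' `log2 [P({e_l}|{b_l}) P({b_l})]` for a nested state, with the boundary
#' conditions `B_L = 1` and `P(b_L) = 1`.
#'
#' @param state an [sbm_state()].
#' @return bits (base-2 log probability), a single number.
#' @name sbm-probabilities
NULL

#' @rdname sbm-probabilities
#' @export
loglik_classical <- function(state) {
  check_state(state)
  k_loglik_classical(state$e_mats[[1L]], state$n_units[[1L]])
}

#' @rdname sbm-probabilities
#' @export
loglik_degree_corrected <- function(state) {
  check_state(state)
  if (!isTRUE(all.equal(unname(state$k), unname(igraph::degree(state$graph)))))
    stop("cached degree sequence inconsistent with the graph")
  k_loglik_dc(state$e_mats[[1L]], state$k)
}

#' @rdname sbm-probabilities
#' @export
log_prior_edges <- function(state) {
  k_prior_edges(state$E, state$B[1L])
}

#' Prior probability of a single-level partition
#'
#' `log2 P(b)` for the three-stage prior: number of non-empty blocks uniform
#' on `1..N`, block sizes uniform among compositions, assignment uniform given
#' the sizes. Empty labels are normalized away before evaluation.
#'
#' @param b integer vector assigning each of the `N` units to a block.
#' @param N number of units; defaults to `length(b)`.
#' @return bits, a single number.
#' @export
log_prior_partition <- function(b, N = length(b)) {
  b <- match(b, unique(b))
  nr <- tabulate(b)
  k_prior_partition(nr, N)
}

#' @rdname sbm-probabilities
#' @export
log_prior_degrees <- function(state) {
  if (!state$degree_corrected) stop("state is not degree-corrected")
  k_prior_degrees(state$k, state$levels[[1L]], state$n_units[[1L]], state$er)
}

#' @rdname sbm-probabilities
#' @export
log_prior_hierarchy <- function(state) {
  if (!state$hierarchical) stop("state is not hierarchical")
  sum(hier_edge_prior_terms(state)) + sum(hier_partition_prior_terms(state))
}

## per-level log2 P(e_l|e_{l+1}, b_{l+1}) for l = 1..L-1, plus the top-level
## edge prior (flat prior at B = 1, i.e. n_e = E) as the final element
hier_edge_prior_terms <- function(state) {
  L <- length(state$levels)
  terms <- numeric(L)
  if (L > 1L) for (l in seq_len(L - 1L)) {
    terms[l] <- k_prior_edges_nested_level(state$e_mats[[l + 1L]],
                                           state$n_units[[l + 1L]])
  }
  terms[L] <- k_prior_edges(state$E, 1L)
  terms
}

## per-level log2 P(b_l); the boundary level contributes P(b_L) = 1
hier_partition_prior_terms <- function(state) {
  L <- length(state$levels)
  terms <- numeric(L)
  if (L > 1L) for (l in seq_len(L - 1L)) {
    N_l <- if (l == 1L) state$N else state$B[l - 1L]
    terms[l] <- k_prior_partition(state$n_units[[l]], N_l)
  }
  terms
}

check_state <- function(state) {
  if (!inherits(state, "sbm_state")) stop("expected an sbm_state")
  e1 <- state$e_mats[[1L]]
  if (abs(sum(e1) - 2 * state$E) > 1e-9)
    stop("internal consistency error: block edge counts do not sum to 2E")
  invisible(state)
}

#' Description length of a graph under an SBM state
#'
#' Assembles the description length `DL = -log2 P(G|lambda, b) -
#' log2 P(lambda, b)` in bits for the variant encoded by the state's flags:
#' the classical variant sums the graph likelihood with the flat edge prior
#' and the partition prior; degree correction swaps the likelihood and adds
#' the degree-sequence prior; hierarchical variants replace the flat edge
#' prior with the nested chain of edge priors and sum partition priors over
#' levels. Lower DL means a better (more parsimonious) fit.
#'
#' @param state an [sbm_state()].
#' @return an object of class `dl_breakdown`: a list with `terms` (named
#'   per-component bits) and `total` (their sum).
#' @export
description_length <- function(state) {
  check_state(state)
  terms <- c(graph_loglik = -if (state$degree_corrected)
               loglik_degree_corrected(state) else loglik_classical(state))
  if (state$degree_corrected)
    terms["degree_prior"] <- -log_prior_degrees(state)
  if (state$hierarchical) {
    ep <- -hier_edge_prior_terms(state)
    pp <- -hier_partition_prior_terms(state)
    names(ep) <- paste0("edge_prior_l", seq_along(ep))
    names(pp) <- paste0("partition_prior_l", seq_along(pp))
    terms <- c(terms, ep, pp)
  } else {
    terms["edge_prior"] <- -log_prior_edges(state)
    terms["partition_prior"] <- -log_prior_partition(state$levels[[1L]], state$N)
  }
  structure(list(terms = terms, total = sum(terms)), class = "dl_breakdown")
}

#' @export
print.dl_breakdown <- function(x, ...) {
  cat(sprintf("Description length: %.4f bits\n", x$total))
  for (nm in names(x$terms)) cat(sprintf("  %-22s %12.4f\n", nm, x$terms[[nm]]))
  invisible(x)
}

#' Posterior odds ratio between two fits
#'
#' `Lambda = 2^-(DL1 - DL2)` under equal prior model probabilities; values
#' above 1 favor the first model.
#'
#' @param dl1,dl2 description lengths in bits (numbers or `dl_breakdown`s).
#' @return the odds ratio, a single positive number.
#' @export
posterior_odds <- function(dl1, dl2) {
  if (inherits(dl1, "dl_breakdown")) dl1 <- dl1$total
  if (inherits(dl2, "dl_breakdown")) dl2 <- dl2$total
  stopifnot(is.finite(dl1), is.finite(dl2))
  2^(-(dl1 - dl2))
}
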