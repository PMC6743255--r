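## Description-length minimization: agglomerative multi-level search with
## multiple random restarts. Flat variants run on an incremental move engine
## (single-unit moves with neighbor-biased candidate sets, plus block-merge
## moves); hierarchical variants refine the level stack bottom-up with
## full-DL sweeps until no level improves.

#' Fit configuration
#'
#' @param variant one of `"classical"`, `"dc"` (degree-corrected), `"h"`
#'   (hierarchical), `"dch"` (degree-corrected hierarchical).
#' @param n_inits number of random restarts (desk default 10; the production
#'   setting used for the real networks is 500).
#' @param max_sweeps cap on move sweeps per stage.
#' @param mode `"greedy"` (accept only DL-decreasing moves) or `"metropolis"`
#'   (accept a proposed move with probability `min(1, 2^-dDL)`).
#' @param seed master seed; every init derives its own seed from it.
#' @param audit_rate fraction of accepted moves whose incremental dDL is
#'   checked against a full description-length recomputation; the maximum
#'   discrepancy is reported in the result.
#' @param max_levels hierarchy depth cap.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(variant = c("classical", "dc", "h", "dch"),
                       n_inits = 10, max_sweeps = 100,
                       mode = c("greedy", "metropolis"),
                       seed = 1L, audit_rate = 0, max_levels = 10) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  stopifnot(n_inits >= 1)
  structure(list(variant = variant, n_inits = as.integer(n_inits),
                 max_sweeps = as.integer(max_sweeps), mode = mode,
                 seed = as.integer(seed), audit_rate = audit_rate,
                 max_levels = as.integer(max_levels)),
            class = "fit_config")
}

#' Draw a random partition from the partition prior
#'
#' Samples the number of blocks `B` uniformly on `1..N`, then block sizes
#' uniformly among the compositions of `N` into `B` positive parts, then a
#' uniform assignment with those sizes -- the prior the description length
#' uses for a single level.
#'
#' @param graph igraph or [reduced_graph] (only the node count is used), or a
#'   single integer node count.
#' @param seed optional seed.
#' @return integer block labels of length `N`.
#' @export
random_initial_partition <- function(graph, seed = NULL) {
  N <- if (is.numeric(graph)) as.integer(graph) else igraph::vcount(as_igraph(graph))
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  B <- sample.int(N, 1L)
  sizes <- if (B == 1L) N else diff(c(0L, sort(sample.int(N - 1L, B - 1L)), N))
  sample(rep(seq_len(B), sizes))
}

## ---- internal flat move engine ----

new_fit_state <- function(adj, k, N, E, b, dc) {
  fs <- new.env(parent = emptyenv())
  fs$adj <- adj; fs$k <- k; fs$N <- N; fs$E <- E; fs$dc <- dc
  b <- match(b, unique(b))
  B <- max(b)
  fs$b <- b; fs$Ball <- B
  ends <- cbind(unlist(lapply(seq_len(N), function(i) rep(i, length(adj[[i]])))),
                unlist(adj))
  ends <- ends[ends[, 1L] < ends[, 2L], , drop = FALSE]
  fs$e <- block_edge_matrix(b, B, ends)
  fs$nr <- tabulate(b, B)
  fs$er <- rowSums(fs$e)
  fs$Bne <- sum(fs$nr > 0)
  if (dc) {
    fs$deg_vals <- sort(unique(k))
    fs$kidx <- match(k, fs$deg_vals)
    eta <- matrix(0L, B, length(fs$deg_vals))
    for (i in seq_len(N)) eta[b[i], fs$kidx[i]] <- eta[b[i], fs$kidx[i]] + 1L
    fs$eta <- eta
  }
  fs$dl <- fit_dl(fs)
  fs$audit_max <- 0
  fs
}

## full DL of the flat model from the fit-state caches
fit_dl <- function(fs) {
  e <- fs$e; nr <- fs$nr; er <- fs$er
  lik <- sum(lf2(e[upper.tri(e)])) + sum(ldf2(diag(e)))
  if (fs$dc) {
    lik <- lik + sum(lf2(fs$k)) - sum(lf2(er))
    pk <- sum(lf2(fs$eta)) - sum(lf2(nr)) - sum(log_q_partitions(er, pmax(nr, 0L)))
  } else {
    lik <- lik - sum(xlog2y(er, nr))
    pk <- 0
  }
  pe <- k_prior_edges(fs$E, fs$Bne)
  pb <- sum(lf2(nr)) - lf2(fs$N) - lchoose2(fs$N - 1, fs$Bne - 1) - log2(fs$N)
  -(lik + pk + pe + pb)
}

## first empty slot, or a freshly grown one
free_slot <- function(fs) {
  empty <- which(fs$nr == 0)
  if (length(empty)) return(empty[1L])
  B <- fs$Ball + 1L
  fs$e <- rbind(cbind(fs$e, 0), 0)
  fs$nr <- c(fs$nr, 0L); fs$er <- c(fs$er, 0)
  if (fs$dc) fs$eta <- rbind(fs$eta, 0L)
  fs$Ball <- B
  B
}

## dDL (bits) of moving node i to block t; t must be an allocated slot
move_delta <- function(fs, i, t) {
  r <- fs$b[i]
  if (t == r) return(0)
  ki <- fs$k[i]
  e <- fs$e; nr <- fs$nr; er <- fs$er
  cvec <- tabulate(fs$b[fs$adj[[i]]], fs$Ball)
  s_other <- which(cvec > 0)
  s_other <- s_other[s_other != r & s_other != t]

  d_lik <- 0
  if (length(s_other)) {
    cs <- cvec[s_other]
    d_lik <- d_lik + sum(lf2(e[r, s_other] - cs) - lf2(e[r, s_other]) +
                         lf2(e[t, s_other] + cs) - lf2(e[t, s_other]))
  }
  cr <- cvec[r]; ct <- cvec[t]
  d_lik <- d_lik + lf2(e[r, t] - ct + cr) - lf2(e[r, t]) +
    ldf2(e[r, r] - 2 * cr) - ldf2(e[r, r]) +
    ldf2(e[t, t] + 2 * ct) - ldf2(e[t, t])

  er_r2 <- er[r] - ki; er_t2 <- er[t] + ki
  nr_r2 <- nr[r] - 1L; nr_t2 <- nr[t] + 1L
  if (fs$dc) {
    d_lik <- d_lik - lf2(er_r2) + lf2(er[r]) - lf2(er_t2) + lf2(er[t])
  } else {
    d_lik <- d_lik - xlog2y(er_r2, nr_r2) + xlog2y(er[r], nr[r]) -
      xlog2y(er_t2, nr_t2) + xlog2y(er[t], nr[t])
  }

  Bne2 <- fs$Bne - (nr_r2 == 0L) + (nr[t] == 0L)
  d_pb <- lf2(nr_r2) - lf2(nr[r]) + lf2(nr_t2) - lf2(nr[t])
  d_pe <- 0
  if (Bne2 != fs$Bne) {
    d_pb <- d_pb - lchoose2(fs$N - 1, Bne2 - 1) + lchoose2(fs$N - 1, fs$Bne - 1)
    d_pe <- k_prior_edges(fs$E, Bne2) - k_prior_edges(fs$E, fs$Bne)
  }

  d_pk <- 0
  if (fs$dc) {
    kx <- fs$kidx[i]
    d_pk <- -log2(fs$eta[r, kx]) + log2(fs$eta[t, kx] + 1) -
      lf2(nr_r2) + lf2(nr[r]) - lf2(nr_t2) + lf2(nr[t]) -
      log_q_partitions(er_r2, nr_r2) + log_q_partitions(er[r], nr[r]) -
      log_q_partitions(er_t2, nr_t2) + log_q_partitions(er[t], nr[t])
  }
  -(d_lik + d_pb + d_pe + d_pk)
}

apply_move <- function(fs, i, t) {
  r <- fs$b[i]
  if (t == r) return(invisible())
  ki <- fs$k[i]
  cvec <- tabulate(fs$b[fs$adj[[i]]], fs$Ball)
  cr <- cvec[r]; ct <- cvec[t]
  sel <- which(cvec > 0); sel <- sel[sel != r & sel != t]
  if (length(sel)) {
    fs$e[r, sel] <- fs$e[r, sel] - cvec[sel]; fs$e[sel, r] <- fs$e[r, sel]
    fs$e[t, sel] <- fs$e[t, sel] + cvec[sel]; fs$e[sel, t] <- fs$e[t, sel]
  }
  fs$e[r, t] <- fs$e[r, t] - ct + cr; fs$e[t, r] <- fs$e[r, t]
  fs$e[r, r] <- fs$e[r, r] - 2 * cr
  fs$e[t, t] <- fs$e[t, t] + 2 * ct
  fs$er[r] <- fs$er[r] - ki; fs$er[t] <- fs$er[t] + ki
  was_empty_t <- fs$nr[t] == 0L
  fs$nr[r] <- fs$nr[r] - 1L; fs$nr[t] <- fs$nr[t] + 1L
  fs$Bne <- fs$Bne - (fs$nr[r] == 0L) + was_empty_t
  if (fs$dc) {
    kx <- fs$kidx[i]
    fs$eta[r, kx] <- fs$eta[r, kx] - 1L
    fs$eta[t, kx] <- fs$eta[t, kx] + 1L
  }
  fs$b[i] <- t
  invisible()
}

## vectorized dDL of merging block r into every other block (Inf where invalid)
merge_delta_row <- function(fs, r) {
  e <- fs$e; nr <- fs$nr; er <- fs$er
  B <- fs$Ball
  out <- rep(Inf, B)
  targets <- which(nr > 0)
  targets <- targets[targets != r]
  if (!length(targets)) return(out)

  erow <- e[r, ]
  Fmat <- lf2(sweep(e, 2, erow, `+`)) - lf2(e) -
    matrix(lf2(erow), B, B, byrow = TRUE)
  A <- rowSums(Fmat) - Fmat[, r] - diag(Fmat)
  d_diag <- ldf2(diag(e) + e[r, r] + 2 * erow) - ldf2(diag(e)) -
    ldf2(e[r, r]) - lf2(erow)
  d_lik <- A + d_diag

  er2 <- er + er[r]; nr2 <- nr + nr[r]
  if (fs$dc) {
    d_ernr <- -lf2(er2) + lf2(er) + lf2(er[r])
  } else {
    d_ernr <- -xlog2y(er2, nr2) + xlog2y(er, nr) + xlog2y(er[r], nr[r])
  }
  d_pb <- lf2(nr2) - lf2(nr) - lf2(nr[r]) -
    lchoose2(fs$N - 1, fs$Bne - 2) + lchoose2(fs$N - 1, fs$Bne - 1)
  d_pe <- k_prior_edges(fs$E, fs$Bne - 1L) - k_prior_edges(fs$E, fs$Bne)

  d_pk <- 0
  if (fs$dc) {
    eta <- fs$eta
    G <- lf2(sweep(eta, 2, eta[r, ], `+`)) - lf2(eta)
    d_pk <- rowSums(G) - sum(lf2(eta[r, ])) -
      lf2(nr2) + lf2(nr) + lf2(nr[r]) -
      log_q_partitions(er2, nr2) + log_q_partitions(er, nr) +
      log_q_partitions(er[r], nr[r])
  }
  res <- -(d_lik + d_ernr + d_pb + d_pe + if (fs$dc) d_pk else 0)
  out[targets] <- res[targets]
  out
}

apply_merge <- function(fs, r, t) {
  e <- fs$e
  fs$e[t, ] <- e[t, ] + e[r, ]
  fs$e[, t] <- fs$e[t, ]
  fs$e[t, t] <- e[t, t] + e[r, r] + 2 * e[r, t]
  fs$e[r, ] <- 0; fs$e[, r] <- 0
  fs$er[t] <- fs$er[t] + fs$er[r]; fs$er[r] <- 0
  fs$nr[t] <- fs$nr[t] + fs$nr[r]; fs$nr[r] <- 0L
  fs$Bne <- fs$Bne - 1L
  if (fs$dc) {
    fs$eta[t, ] <- fs$eta[t, ] + fs$eta[r, ]
    fs$eta[r, ] <- 0L
  }
  fs$b[fs$b == r] <- t
  invisible()
}

audit_check <- function(fs) {
  full <- fit_dl(fs)
  fs$audit_max <- max(fs$audit_max, abs(full - fs$dl))
  invisible()
}

## one fit of the flat model from a given initial partition
fit_flat <- function(adj, k, N, E, b0, dc, mode = "greedy",
                     max_sweeps = 100, audit_rate = 0) {
  fs <- new_fit_state(adj, k, N, E, b0, dc)
  tol <- 1e-10
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    ## (a) single-unit moves
    for (i in sample.int(N)) {
      nbr_blocks <- unique(fs$b[fs$adj[[i]]])
      cand <- setdiff(nbr_blocks, fs$b[i])
      nonempty <- which(fs$nr > 0)
      if (length(nonempty) > 1L)
        cand <- unique(c(cand, sample(nonempty, 1L)))
      if (fs$nr[fs$b[i]] > 1L) cand <- c(cand, free_slot(fs))
      if (!length(cand)) next
      if (mode == "greedy") {
        deltas <- vapply(cand, function(t) move_delta(fs, i, t), numeric(1))
        j <- which.min(deltas)
        if (deltas[j] < -tol) {
          fs$dl <- fs$dl + deltas[j]
          apply_move(fs, i, cand[j])
          improved <- TRUE
          if (audit_rate > 0 && stats::runif(1) < audit_rate) audit_check(fs)
        }
      } else {
        t <- if (length(nbr_blocks) && stats::runif(1) < 0.9)
          fs$b[fs$adj[[i]][sample.int(length(fs$adj[[i]]), 1L)]]
        else cand[sample.int(length(cand), 1L)]
        if (t == fs$b[i]) next
        d <- move_delta(fs, i, t)
        if (stats::runif(1) < 2^(-d)) {
          fs$dl <- fs$dl + d
          apply_move(fs, i, t)
          improved <- improved || d < -tol
          if (audit_rate > 0 && stats::runif(1) < audit_rate) audit_check(fs)
        }
      }
    }
    ## (b) agglomerative block merges
    repeat {
      if (fs$Bne < 2L) break
      nonempty <- which(fs$nr > 0)
      D <- vapply(nonempty, function(r) min(merge_delta_row(fs, r)),
                  numeric(1))
      j <- which.min(D)
      if (D[j] >= -tol) break
      r <- nonempty[j]
      t <- which.min(merge_delta_row(fs, r))
      fs$dl <- fs$dl + D[j]
      apply_merge(fs, r, t)
      improved <- TRUE
      if (audit_rate > 0 && stats::runif(1) < audit_rate) audit_check(fs)
    }
    if (!improved) break
  }
  list(b = match(fs$b, unique(fs$b)), dl = fs$dl, audit_max = fs$audit_max)
}

## ---- hierarchical refinement (full-DL sweeps on the level stack) ----

## DL of a level stack, from precomputed edge ends and degrees
eval_levels_dl <- function(ends, k, N, E, levels, dc) {
  levels <- normalize_levels(levels)
  L <- length(levels)
  B <- vapply(levels, max, integer(1))
  e_mats <- vector("list", L); n_units <- vector("list", L)
  e_mats[[1L]] <- block_edge_matrix(levels[[1L]], B[1L], ends)
  n_units[[1L]] <- tabulate(levels[[1L]], B[1L])
  if (L > 1L) for (l in 2:L) {
    e_mats[[l]] <- aggregate_edge_matrix(e_mats[[l - 1L]], levels[[l]], B[l])
    n_units[[l]] <- tabulate(levels[[l]], B[l])
  }
  e1 <- e_mats[[1L]]; er <- rowSums(e1)
  lik <- if (dc) k_loglik_dc(e1, k) else k_loglik_classical(e1, n_units[[1L]])
  pk <- if (dc) k_prior_degrees(k, levels[[1L]], n_units[[1L]], er) else 0
  pe <- k_prior_edges(E, 1L)
  if (L > 1L) for (l in seq_len(L - 1L))
    pe <- pe + k_prior_edges_nested_level(e_mats[[l + 1L]], n_units[[l + 1L]])
  pb <- 0
  if (L > 1L) for (l in seq_len(L - 1L)) {
    N_l <- if (l == 1L) N else B[l - 1L]
    pb <- pb + k_prior_partition(n_units[[l]], N_l)
  }
  -(lik + pk + pe + pb)
}

## greedy sweep of level l under the full nested DL; returns updated stack
hier_level_sweep <- function(ends, k, N, E, levels, l, dc, dl) {
  n_units <- length(levels[[l]])
  improved <- FALSE
  for (u in sample.int(n_units)) {
    cur <- levels[[l]][u]
    Bl <- max(levels[[l]])
    cand <- setdiff(seq_len(Bl + 1L), cur)  # every block plus a new one
    best <- dl; best_t <- cur
    for (t in cand) {
      trial <- levels
      trial[[l]][u] <- t
      if (t == Bl + 1L && l < length(trial))
        trial[[l + 1L]] <- c(trial[[l + 1L]], trial[[l + 1L]][cur])
      d <- eval_levels_dl(ends, k, N, E, trial, dc)
      if (d < best - 1e-10) { best <- d; best_t <- t; best_levels <- trial }
    }
    if (best_t != cur) {
      levels <- normalize_levels(best_levels)
      dl <- best
      improved <- TRUE
    }
  }
  list(levels = levels, dl = dl, improved = improved)
}

## hierarchy refinement on top of a flat level-1 partition
fit_hier <- function(ends, k, N, E, b1, dc, max_levels = 10, max_rounds = 10) {
  levels <- list(b1)
  if (max(b1) > 1L) levels <- c(levels, list(rep(1L, max(b1))))
  levels <- normalize_levels(levels)
  dl <- eval_levels_dl(ends, k, N, E, levels, dc)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    l <- 1L
    while (l <= length(levels)) {
      res <- hier_level_sweep(ends, k, N, E, levels, l, dc, dl)
      levels <- res$levels; dl <- res$dl
      improved <- improved || res$improved
      ## keep the boundary: a split top level gets a fresh unit level on top
      L <- length(levels)
      if (max(levels[[L]]) > 1L && L < max_levels) {
        levels <- c(levels, list(rep(1L, max(levels[[L]]))))
        dl <- eval_levels_dl(ends, k, N, E, levels, dc)
      }
      l <- l + 1L
    }
    ## drop redundant all-trivial top levels (keep one boundary level)
    while (length(levels) > 1L && max(levels[[length(levels)]]) == 1L &&
           length(levels[[length(levels)]]) == 1L) {
      levels <- levels[-length(levels)]
    }
    if (max(levels[[length(levels)]]) > 1L)
      levels <- c(levels, list(rep(1L, max(levels[[length(levels)]]))))
    dl <- eval_levels_dl(ends, k, N, E, levels, dc)
    if (!improved) break
  }
  list(levels = levels, dl = dl)
}

## ---- public fitting API ----

variant_flags <- function(variant) {
  list(dc = variant %in% c("dc", "dch"),
       hier = variant %in% c("h", "dch"))
}

#' Fit a stochastic block model by description-length minimization
#'
#' Runs `n_inits` restarts from partitions drawn from the partition prior.
#' Each restart alternates single-unit moves (candidate blocks biased toward
#' the blocks of the unit's neighbors, with a uniform fallback and a fresh
#' block) with agglomerative block merges, accepting per the configured mode,
#' until a full pass yields no improvement. For hierarchical variants the
#' flat fit seeds a level stack that is then swept level by level under the
#' full nested description length, deepening while that lowers it.
#'
#' @param graph a [reduced_graph] or igraph; must be simple.
#' @param cfg a [fit_config()].
#' @return an object of class `sbm_fit`: list with `state` (the best
#'   [sbm_state()]), `dl` (its description length in bits), `dl_trace`
#'   (per-init minimum), `variant`, and `audit_max` (largest deviation
#'   between incremental and recomputed dDL over audited moves, when
#'   auditing was enabled).
#' @export
fit_sbm <- function(graph, cfg = fit_config()) {
  g <- as_igraph(graph)
  N <- igraph::vcount(g)
  if (N == 0) stop("cannot fit a graph with no nodes")
  flags <- variant_flags(cfg$variant)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  k <- igraph::degree(g)
  E <- igraph::ecount(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (flags$dc) invisible(log_q_partitions(2L * E, max(N, 1L)))  # warm the cache

  seeds <- derive_seeds(cfg$seed, cfg$n_inits)
  best <- NULL; trace <- numeric(cfg$n_inits); audit_max <- 0
  for (init in seq_len(cfg$n_inits)) {
    set.seed(seeds[init])
    b0 <- random_initial_partition(N)
    flat <- fit_flat(adj, k, N, E, b0, flags$dc, mode = cfg$mode,
                     max_sweeps = cfg$max_sweeps, audit_rate = cfg$audit_rate)
    audit_max <- max(audit_max, flat$audit_max)
    if (flags$hier) {
      res <- fit_hier(ends, k, N, E, flat$b, flags$dc,
                      max_levels = cfg$max_levels)
      levels <- res$levels; dl <- res$dl
    } else {
      levels <- list(flat$b); dl <- flat$dl
    }
    trace[init] <- dl
    if (is.null(best) || dl < best$dl) best <- list(levels = levels, dl = dl)
  }
  state <- sbm_state(g, best$levels, degree_corrected = flags$dc,
                     hierarchical = flags$hier)
  dl_check <- description_length(state)$total
  structure(list(state = state, dl = dl_check, dl_trace = trace,
                 variant = cfg$variant, audit_max = audit_max,
                 config = cfg),
            class = "sbm_fit")
}

#' @export
print.sbm_fit <- function(x, ...) {
  cat(sprintf("<sbm_fit> variant %s: DL = %.2f bits over %d inits; levels %s\n",
              x$variant, x$dl, length(x$dl_trace),
              paste(x$state$B, collapse = " -> ")))
  invisible(x)
}

#' Select among SBM variants by posterior odds
#'
#' Fits each requested variant and ranks them by minimal description length;
#' the posterior odds ratio `2^-(DL_i - DL_best)` is reported against the
#' best variant (which gets `Lambda = 1`).
#'
#' @param graph a [reduced_graph] or igraph.
#' @param variants character vector of variants to fit.
#' @param n_inits,seed,mode,audit_rate passed to [fit_config()].
#' @return a data frame `(variant, dl, lambda, best)` sorted by DL, with the
#'   fits in attribute `"fits"`.
#' @export
select_model <- function(graph, variants = c("classical", "dc", "h", "dch"),
                         n_inits = 10, seed = 1L, mode = "greedy",
                         audit_rate = 0) {
  stopifnot(length(variants) >= 1)
  fits <- lapply(seq_along(variants), function(vi) {
    fit_sbm(graph, fit_config(variant = variants[vi], n_inits = n_inits,
                              mode = mode, seed = seed + vi - 1L,
                              audit_rate = audit_rate))
  })
  dls <- vapply(fits, `[[`, numeric(1), "dl")
  out <- data.frame(variant = variants, dl = dls,
                    lambda = 2^(-(dls - min(dls))),
                    best = dls == min(dls))
  out <- out[order(out$dl), ]
  rownames(out) <- NULL
  attr(out, "fits") <- stats::setNames(fits, variants)
  out
}
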