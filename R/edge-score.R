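## Edge confidence scores: description-length differences at the fixed best
## partition for single-edge perturbations. Positive score = the perturbation
## (adding a putatively missing edge / removing a putatively spurious one)
## improves the fit. Scores are relative confidence values, not
## probabilities.

## DL(G + dG) - DL(G) for a single-edge perturbation, computed from the
## affected terms only (likelihood entries of the touched block pair, block
## degree sums, the two node degrees and their frequency classes, the edge
## prior at E +/- 1, and the nested multiset terms along the endpoint blocks'
## common ancestry). Partition priors do not change: b* is held fixed.
dl_perturb_delta <- function(state, u, v, delta) {
  b1 <- state$levels[[1L]]
  r <- b1[u]; s <- b1[v]
  e1 <- state$e_mats[[1L]]
  er <- state$er; nr <- state$n_units[[1L]]
  k <- state$k
  same <- r == s

  d_pair <- if (same) ldf2(e1[r, r] + 2 * delta) - ldf2(e1[r, r])
            else lf2(e1[r, s] + delta) - lf2(e1[r, s])
  er2 <- er
  if (same) er2[r] <- er2[r] + 2 * delta
  else { er2[r] <- er2[r] + delta; er2[s] <- er2[s] + delta }
  blocks <- unique(c(r, s))

  if (state$degree_corrected) {
    d_lik <- d_pair +
      lf2(k[u] + delta) - lf2(k[u]) + lf2(k[v] + delta) - lf2(k[v]) +
      sum(-lf2(er2[blocks]) + lf2(er[blocks]))
    k2 <- k; k2[u] <- k2[u] + delta; k2[v] <- k2[v] + delta
    d_pk <- 0
    for (blk in blocks) {
      idx <- which(b1 == blk)
      d_pk <- d_pk + sum(lf2(table(k2[idx]))) - sum(lf2(table(k[idx]))) -
        log_q_partitions(er2[blk], nr[blk]) + log_q_partitions(er[blk], nr[blk])
    }
  } else {
    d_lik <- d_pair + sum(-xlog2y(er2[blocks], nr[blocks]) +
                            xlog2y(er[blocks], nr[blocks]))
    d_pk <- 0
  }

  E <- state$E
  if (state$hierarchical) {
    d_pe <- k_prior_edges(E + delta, 1L) - k_prior_edges(E, 1L)
    L <- length(state$levels)
    ru <- r; su <- s
    if (L > 1L) for (l in seq_len(L - 1L)) {
      ru <- state$levels[[l + 1L]][ru]; su <- state$levels[[l + 1L]][su]
      eu <- state$e_mats[[l + 1L]]; nu <- state$n_units[[l + 1L]]
      d_pe <- d_pe + if (ru == su) {
        -lmultiset2(nu[ru] * (nu[ru] + 1) / 2, (eu[ru, ru] + 2 * delta) / 2) +
          lmultiset2(nu[ru] * (nu[ru] + 1) / 2, eu[ru, ru] / 2)
      } else {
        -lmultiset2(nu[ru] * nu[su], eu[ru, su] + delta) +
          lmultiset2(nu[ru] * nu[su], eu[ru, su])
      }
    }
  } else {
    B <- state$B[1L]
    d_pe <- k_prior_edges(E + delta, B) - k_prior_edges(E, B)
  }
  -(d_lik + d_pk + d_pe)
}

#' Confidence score of a single-edge perturbation
#'
#' `DL(G at b*) - DL(G + dG at b*)` in bits, for `dG` the addition of an
#' absent edge (`mode = "add"`, a putatively missing edge) or the removal of
#' an existing edge (`mode = "remove"`, a putatively spurious one), with the
#' fitted partition held fixed for both graphs. Only the affected blocks'
#' terms are touched. For degree-corrected states the perturbed description
#' uses the updated degree sequence and degree prior.
#'
#' @param state a fitted [sbm_state()].
#' @param u,v node names or indices, `u != v`.
#' @param mode `"add"` or `"remove"`.
#' @return the score in bits (a single number; positive means the
#'   perturbation improves the fit).
#' @export
score_edge <- function(state, u, v, mode = c("add", "remove")) {
  mode <- match.arg(mode)
  g <- state$graph
  if (is.character(u)) u <- match(u, igraph::V(g)$name)
  if (is.character(v)) v <- match(v, igraph::V(g)$name)
  stopifnot(!is.na(u), !is.na(v))
  if (u == v) stop("self-pairs are not scored")
  present <- igraph::are_adjacent(g, u, v)
  if (mode == "add" && present) stop("edge already present; use mode = 'remove'")
  if (mode == "remove" && !present) stop("edge absent; use mode = 'add'")
  delta <- if (mode == "add") 1L else -1L
  unname(-dl_perturb_delta(state, u, v, delta))
}

#' Score every existing edge as putatively spurious
#'
#' @param state a fitted [sbm_state()].
#' @param rho optional matrix of correlations (entity names as dimnames) from
#'   which `|rho|` per edge is looked up for validation.
#' @return an edge-score table: data frame `(u, v, kind, score_bits,
#'   abs_rho)` with one row per existing edge, `kind = "spurious"`.
#' @export
score_all_spurious <- function(state, rho = NULL) {
  g <- state$graph
  ends <- igraph::as_edgelist(g, names = FALSE)
  nm <- igraph::V(g)$name
  score <- if (nrow(ends)) vapply(seq_len(nrow(ends)), function(i)
    score_edge(state, ends[i, 1L], ends[i, 2L], "remove"), numeric(1)) else numeric(0)
  make_score_table(nm[ends[, 1L]], nm[ends[, 2L]], "spurious", score, rho)
}

#' Score putatively missing edges
#'
#' Scores absent pairs between degree-positive nodes (`kind = "missing"`) up
#' to `budget` pairs, ranked by `|rho|` when requested (the strategy used
#' when scoring all absent pairs is infeasible). Degree-zero nodes are
#' indistinguishable to the SBM within a block: each (zero-class, target)
#' combination is scored once through a representative node
#' (`kind = "missing_disc"`).
#'
#' @param state a fitted [sbm_state()].
#' @param budget maximum number of `missing` rows (> 0).
#' @param ranking `"by_abs_rho"` (requires `rho`) or `"all"` (first `budget`
#'   pairs in node order).
#' @param rho correlation matrix for ranking/validation.
#' @return an edge-score table (see [score_all_spurious()]).
#' @export
score_missing <- function(state, budget = NULL, ranking = c("by_abs_rho", "all"),
                          rho = NULL) {
  ranking <- match.arg(ranking)
  g <- state$graph
  if (is.null(budget)) budget <- max(1L, igraph::ecount(g))
  if (budget <= 0) stop("budget must be positive")
  if (ranking == "by_abs_rho" && is.null(rho)) stop("ranking by |rho| needs rho")
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  pos <- which(deg > 0)

  ## absent pairs among degree-positive nodes
  tab <- NULL
  if (length(pos) >= 2) {
    adjm <- igraph::as_adjacency_matrix(g, sparse = FALSE)[pos, pos, drop = FALSE]
    ut <- which(upper.tri(adjm) & adjm == 0)
    i <- pos[(ut - 1L) %% length(pos) + 1L]
    j <- pos[(ut - 1L) %/% length(pos) + 1L]
    if (length(i)) {
      if (ranking == "by_abs_rho") {
        w <- abs(rho[cbind(nm[i], nm[j])])
        ord <- order(-w)
      } else ord <- seq_along(i)
      keep <- ord[seq_len(min(budget, length(ord)))]
      i <- i[keep]; j <- j[keep]
      score <- vapply(seq_along(i), function(q)
        score_edge(state, i[q], j[q], "add"), numeric(1))
      tab <- make_score_table(nm[i], nm[j], "missing", score, rho)
    }
  }

  ## one representative per (degree-zero class, degree-positive target)
  zero <- which(deg == 0)
  if (length(zero) && length(pos)) {
    b1 <- state$levels[[1L]]
    reps <- zero[!duplicated(b1[zero])]
    rows <- expand.grid(w = reps, v = pos)
    score <- vapply(seq_len(nrow(rows)), function(q)
      score_edge(state, rows$w[q], rows$v[q], "add"), numeric(1))
    tab <- rbind(tab, make_score_table(nm[rows$w], nm[rows$v], "missing_disc",
                                       score, rho))
  }
  if (is.null(tab)) tab <- make_score_table(character(0), character(0),
                                            character(0), numeric(0), rho)
  tab
}

make_score_table <- function(u, v, kind, score, rho) {
  abs_rho <- if (!is.null(rho) && length(u)) abs(rho[cbind(u, v)]) else
    rep(NA_real_, length(u))
  data.frame(u = u, v = v, kind = rep_len(kind, length(u)),
             score_bits = score, abs_rho = abs_rho,
             stringsAsFactors = FALSE)
}

#' Validate edge scores against the edge correlations
#'
#' For each score kind, the Spearman correlation between the confidence score
#' and `|rho|`, and the fraction of scores above the natural threshold 0
#' (reported, not applied). Kinds with fewer than 3 rows or constant values
#' are flagged undefined.
#'
#' @param table an edge-score table with `abs_rho` filled in.
#' @return data frame `(kind, n, cor_score_absrho, frac_positive, defined)`.
#' @export
validate_scores <- function(table) {
  kinds <- unique(table$kind)
  out <- lapply(kinds, function(kd) {
    d <- table[table$kind == kd & !is.na(table$abs_rho), ]
    defined <- nrow(d) >= 3 && stats::sd(d$score_bits) > 0 && stats::sd(d$abs_rho) > 0
    data.frame(kind = kd, n = nrow(d),
               cor_score_absrho = if (defined)
                 stats::cor(d$score_bits, d$abs_rho, method = "spearman") else NA_real_,
               frac_positive = if (nrow(d)) mean(d$score_bits > 0) else NA_real_,
               defined = defined)
  })
  do.call(rbind, out)
}
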