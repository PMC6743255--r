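## Network reduction: significance of correlation with multiple-testing
## correction, or the lowest correlation threshold achieving a scale-free
## degree distribution. Output graphs are binary and keep every entity as a
## node (degree zero allowed).

#' Construct a reduced graph
#'
#' A simple undirected binary graph retaining all entities as nodes, plus a
#' provenance record of the reduction that produced it.
#'
#' @param graph an igraph object (vertex names are the entity ids).
#' @param provenance list describing the reduction method and setting.
#' @return an object of class `reduced_graph`.
#' @export
reduced_graph <- function(graph, provenance = list()) {
  g <- as_igraph(graph)
  g <- igraph::simplify(g)
  structure(list(graph = g, provenance = provenance), class = "reduced_graph")
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat(sprintf("<reduced_graph> %d nodes, %d edges (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(names(x$provenance), unlist(x$provenance),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

graph_from_pairs <- function(ids, i, j, provenance) {
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(i)) g <- igraph::add_edges(g, rbind(i, j))
  reduced_graph(g, provenance)
}

#' Reduce a correlation network by significance of correlation
#'
#' Keeps an edge iff its multiplicity-corrected p-value is below `alpha`. The
#' correction (Bonferroni or Benjamini-Hochberg step-up) is applied over all
#' tested pairs, i.e. the pairs with a defined correlation; undefined pairs
#' are excluded. The output is binarized.
#'
#' @param net a [spearman_network()] result.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha significance threshold (the study grid is 0.01 and 0.05).
#' @return a [reduced_graph].
#' @export
significance_reduce <- function(net, correction = c("bonferroni", "bh"),
                                alpha = 0.05) {
  correction <- match.arg(correction)
  stopifnot(inherits(net, "corr_network"))
  ut <- upper.tri(net$rho)
  idx <- which(ut & !is.na(net$pvalue))
  p_adj <- stats::p.adjust(net$pvalue[idx],
                           method = if (correction == "bh") "BH" else "bonferroni")
  keep <- idx[p_adj < alpha]
  n <- length(net$entity_ids)
  i <- (keep - 1L) %% n + 1L
  j <- (keep - 1L) %/% n + 1L
  graph_from_pairs(net$entity_ids, i, j,
                   list(method = "significance", correction = correction,
                        alpha = alpha))
}

#' Summarize a reduced graph
#'
#' Node, edge, degree-zero and largest-connected-component counts, the
#' characteristics used to compare candidate reductions.
#'
#' @param g a [reduced_graph] or igraph.
#' @return one-row data frame with `nodes`, `edges`, `nodes_degree_zero`,
#'   `lcc_size`, `lcc_pct`.
#' @export
graph_stats <- function(g) {
  gr <- as_igraph(g)
  comp <- igraph::components(gr)
  data.frame(nodes = igraph::vcount(gr),
             edges = igraph::ecount(gr),
             nodes_degree_zero = sum(igraph::degree(gr) == 0),
             lcc_size = if (comp$no > 0) max(comp$csize) else 0L,
             lcc_pct = if (igraph::vcount(gr) > 0)
               100 * max(comp$csize) / igraph::vcount(gr) else NA_real_)
}

#' Choose among candidate significance settings
#'
#' Among the candidate reductions with fewer than `max_edges` edges, returns
#' the one with the highest percentage of nodes in the largest connected
#' component; ties break toward the more stringent setting (Bonferroni over
#' Benjamini-Hochberg, alpha 0.01 over 0.05).
#'
#' @param reports data frame with columns `correction`, `alpha`, `edges`,
#'   `lcc_pct` (one row per candidate setting, e.g. rows of [graph_stats()]
#'   augmented with the setting).
#' @param max_edges upper bound on an acceptable edge count (default `1e7`).
#' @return the chosen row of `reports`, with a logical `chosen` column added
#'   to the full data frame in attribute `"reports"`.
#' @export
choose_significance_setting <- function(reports, max_edges = 1e7) {
  stopifnot(all(c("correction", "alpha", "edges", "lcc_pct") %in% names(reports)))
  ok <- reports$edges < max_edges
  if (!any(ok))
    stop("no candidate setting below ", max_edges,
         " edges; use a stricter alpha or correction")
  stringency <- ifelse(tolower(reports$correction) == "bonferroni", 0L, 1L) * 2L +
    ifelse(reports$alpha <= 0.01, 0L, 1L)
  ord <- order(!ok, -reports$lcc_pct, stringency)
  pick <- ord[1L]
  reports$chosen <- seq_len(nrow(reports)) == pick
  structure(reports[pick, , drop = FALSE], reports = reports)
}

#' Scale-free fit index of a degree sequence
#'
#' Degree-zero nodes are excluded; the positive degrees are binned into
#' `n_bins` equal-width bins, and `log10` of the bin frequency is regressed on
#' `log10` of the mean bin degree over the non-empty bins. Returns the
#' regression R-squared, set to 0 when the fitted slope is positive (a
#' power law must have a negative exponent).
#'
#' @param degrees non-negative integer degrees.
#' @param n_bins number of equal-width bins (default 10).
#' @return R-squared in `[0, 1]`.
#' @export
scale_free_fit_index <- function(degrees, n_bins = 10) {
  d <- degrees[degrees > 0]
  if (length(unique(d)) < 2)
    stop("need at least 2 distinct positive degrees for the log-log regression")
  breaks <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(d, bin, length)
  mean_deg <- tapply(d, bin, mean)
  keep <- !is.na(freq) & freq > 0
  lx <- log10(mean_deg[keep]); ly <- log10(freq[keep])
  if (length(lx) < 2) return(1)  # a single occupied bin: nothing to misfit
  fit <- stats::lm(ly ~ lx)
  if (stats::coef(fit)[2L] > 0) return(0)
  summary(fit)$r.squared
}

#' Pick the lowest hard threshold giving a scale-free reduced network
#'
#' Scans the ascending threshold grid; at each threshold `t` the binary graph
#' keeping pairs with `|rho| >= t` is formed and its scale-free fit index
#' computed. The first threshold whose index exceeds `r2_min` is returned
#' with its graph. An optional refinement stage re-scans at `refine_step`
#' resolution between the previous grid point and the first passing one
#' (the two-stage coarse/fine procedure).
#'
#' @param net a [spearman_network()] result.
#' @param grid ascending thresholds in (0, 1) (default `seq(0.3, 0.95, 0.05)`).
#' @param r2_min required scale-free fit index (default 0.85).
#' @param refine_step optional step for the refinement stage (e.g. 0.001);
#'   `NULL` for a single-stage scan.
#' @param n_bins passed to [scale_free_fit_index()].
#' @return list with `threshold`, `r2`, `graph` (a [reduced_graph]) and
#'   `scan` (data frame of every threshold tried with its index).
#' @export
pick_hard_threshold <- function(net, grid = seq(0.3, 0.95, by = 0.05),
                                r2_min = 0.85, refine_step = NULL, n_bins = 10) {
  stopifnot(inherits(net, "corr_network"), length(grid) > 0,
            all(grid > 0), all(grid < 1), !is.unsorted(grid))
  absrho <- abs(net$rho)
  scan <- data.frame(threshold = numeric(0), r2 = numeric(0))
  try_threshold <- function(t) {
    adj <- !is.na(absrho) & absrho >= t
    deg <- rowSums(adj)
    r2 <- tryCatch(scale_free_fit_index(deg, n_bins = n_bins), error = function(e) NA_real_)
    scan <<- rbind(scan, data.frame(threshold = t, r2 = r2))
    r2
  }
  hit <- NA_real_
  for (ti in seq_along(grid)) {
    r2 <- try_threshold(grid[ti])
    if (!is.na(r2) && r2 > r2_min) { hit <- grid[ti]; break }
  }
  if (!is.na(hit) && !is.null(refine_step) && ti > 1L) {
    fine <- seq(grid[ti - 1L], hit, by = refine_step)
    for (t in fine) {
      r2 <- try_threshold(t)
      if (!is.na(r2) && r2 > r2_min) { hit <- t; break }
    }
  }
  if (is.na(hit)) {
    if (all(is.na(scan$r2)))
      stop("no threshold yields a computable fit index; best (t, R^2) undefined")
    best <- scan[which.max(scan$r2), ]
    stop(sprintf("no threshold reaches R^2 > %.3f; best was t = %.3f (R^2 = %.3f)",
                 r2_min, best$threshold, best$r2))
  }
  r2_hit <- scan$r2[scan$threshold == hit][1L]
  keep <- which(upper.tri(absrho) & !is.na(absrho) & absrho >= hit)
  n <- length(net$entity_ids)
  g <- graph_from_pairs(net$entity_ids,
                        (keep - 1L) %% n + 1L, (keep - 1L) %/% n + 1L,
                        list(method = "scalefree", threshold = hit, r2 = r2_hit))
  list(threshold = hit, r2 = r2_hit, graph = g, scan = scan)
}
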