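## End-to-end pipeline: correlation network -> reduction -> SBM fits and
## model selection -> edge scores -> block enrichment, with every stage's
## seed derived from one master seed and a machine-readable manifest.

#' Pipeline configuration
#'
#' @param matrix path to an expression TSV or an in-memory entities-by-samples
#'   matrix.
#' @param annotation optional GMT path or named list term -> entity ids.
#' @param hierarchy optional hierarchy TSV path or [hierarchy_tree()].
#' @param out_dir output directory (created if absent).
#' @param na_policy missing-value policy, see [handle_missing()].
#' @param na_fraction_max tolerated per-entity missing fraction.
#' @param reduction `"significance"` or `"scalefree"`.
#' @param corrections,alphas candidate settings for the significance route.
#' @param max_edges acceptable edge-count bound when choosing a setting.
#' @param sf_grid,sf_r2_min threshold grid and fit requirement for the
#'   scale-free route.
#' @param variants SBM variants to fit and select among.
#' @param n_inits restarts per variant.
#' @param edge_score_budget missing-edge scoring budget (default: as many as
#'   there are existing edges).
#' @param enrich_min_size,enrich_max_size term-size filter for the
#'   overrepresentation analysis.
#' @param n_shuffles shuffle-null repetitions.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, annotation = NULL, hierarchy = NULL,
                            out_dir = tempfile("sbmnet_run_"),
                            na_policy = c("none", "sentinel_log_zero", "drop_high_na"),
                            na_fraction_max = 0.2,
                            reduction = c("significance", "scalefree"),
                            corrections = c("bonferroni", "bh"),
                            alphas = c(0.01, 0.05),
                            max_edges = 1e7,
                            sf_grid = seq(0.3, 0.95, by = 0.05),
                            sf_r2_min = 0.85,
                            variants = "dch",
                            n_inits = 5,
                            edge_score_budget = NULL,
                            enrich_min_size = 2, enrich_max_size = 500,
                            n_shuffles = 3,
                            seed = 1L) {
  structure(list(matrix = matrix, annotation = annotation, hierarchy = hierarchy,
                 out_dir = out_dir, na_policy = match.arg(na_policy),
                 na_fraction_max = na_fraction_max,
                 reduction = match.arg(reduction),
                 corrections = corrections, alphas = alphas,
                 max_edges = max_edges, sf_grid = sf_grid,
                 sf_r2_min = sf_r2_min, variants = variants,
                 n_inits = n_inits, edge_score_budget = edge_score_budget,
                 enrich_min_size = enrich_min_size,
                 enrich_max_size = enrich_max_size,
                 n_shuffles = n_shuffles, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes correlation-network construction, reduction, SBM fitting and
#' model selection, edge-confidence scoring, and (when an annotation is
#' supplied) per-level block overrepresentation with shuffle nulls and
#' hierarchy distance summaries. All tables are written to the output
#' directory together with a manifest recording seeds and settings; reruns
#' with the same configuration reproduce the outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with the stage results: `network_stats`,
#'   `reduction`, `selection`, `best_fit`, `edge_scores`, `score_validation`,
#'   `enrichment`, `annotation_rates`, `shuffle_rates`, `distance_summary`,
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 4L)  # fit, shuffles, spare, spare

  x <- if (is.character(cfg$matrix)) read_expression_tsv(cfg$matrix) else cfg$matrix
  hm <- handle_missing(x, policy = cfg$na_policy,
                       na_fraction_max = cfg$na_fraction_max)
  x <- hm$matrix
  net <- spearman_network(x)

  n <- nrow(x)
  before <- data.frame(setting = "before_reduction", correction = NA, alpha = NA,
                       nodes = n, edges = n * (n - 1) / 2,
                       nodes_degree_zero = 0L, lcc_size = n, lcc_pct = 100)

  if (cfg$reduction == "significance") {
    cand <- expand.grid(correction = cfg$corrections, alpha = cfg$alphas,
                        stringsAsFactors = FALSE)
    graphs <- vector("list", nrow(cand))
    reports <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      graphs[[i]] <<- significance_reduce(net, cand$correction[i], cand$alpha[i])
      cbind(cand[i, , drop = FALSE], graph_stats(graphs[[i]]))
    }))
    chosen <- choose_significance_setting(reports, max_edges = cfg$max_edges)
    g <- graphs[[which(attr(chosen, "reports")$chosen)]]
    reduction <- list(reports = attr(chosen, "reports"), chosen = chosen)
  } else {
    sf <- pick_hard_threshold(net, grid = cfg$sf_grid, r2_min = cfg$sf_r2_min)
    g <- sf$graph
    reduction <- list(scan = sf$scan,
                      chosen = data.frame(threshold = sf$threshold, r2 = sf$r2))
  }
  utils::write.table(rbind(before,
                           cbind(setting = "reduced", correction = NA, alpha = NA,
                                 graph_stats(g))),
                     file.path(cfg$out_dir, "network_characteristics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(g, file.path(cfg$out_dir, "reduced_graph.csv"))

  selection <- select_model(g, variants = cfg$variants, n_inits = cfg$n_inits,
                            seed = seeds[1L])
  fits <- attr(selection, "fits")
  best_fit <- fits[[selection$variant[1L]]]
  utils::write.table(selection, file.path(cfg$out_dir, "model_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dl_trace <- do.call(rbind, lapply(names(fits), function(v)
    data.frame(variant = v, init = seq_along(fits[[v]]$dl_trace),
               dl = fits[[v]]$dl_trace)))
  utils::write.table(dl_trace, file.path(cfg$out_dir, "dl_per_init.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sbm_state(best_fit$state, file.path(cfg$out_dir, "best_state.json"))

  state <- best_fit$state
  budget <- if (is.null(cfg$edge_score_budget)) max(1L, state$E) else cfg$edge_score_budget
  scores <- rbind(score_all_spurious(state, rho = net$rho),
                  score_missing(state, budget = budget,
                                ranking = "by_abs_rho", rho = net$rho))
  validation <- validate_scores(scores)
  write_edge_scores(scores, file.path(cfg$out_dir, "edge_scores.csv"))
  utils::write.table(validation, file.path(cfg$out_dir, "score_validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enrichment <- annotation_rates <- shuffle_rates <- distance_summary <- NULL
  ann <- cfg$annotation
  if (!is.null(ann)) {
    if (is.character(ann)) ann <- read_gmt(ann)
    tree <- cfg$hierarchy
    if (is.character(tree)) tree <- read_hierarchy_tsv(tree)
    ids <- igraph::V(state$graph)$name
    n_levels <- max(1L, length(state$levels) - as.integer(state$hierarchical))
    part_levels <- lapply(seq_len(n_levels), function(l)
      stats::setNames(level_membership(state, l), ids))
    enrichment <- do.call(rbind, lapply(seq_len(n_levels), function(l)
      overrepresentation(part_levels[[l]], ann, universe = ids,
                         min_size = cfg$enrich_min_size,
                         max_size = cfg$enrich_max_size, level = l)))
    annotation_rates <- vapply(seq_len(n_levels), function(l)
      block_annotation_rate(part_levels[[l]], ann, universe = ids,
                            min_size = cfg$enrich_min_size,
                            max_size = cfg$enrich_max_size, level = l),
      numeric(1))
    shuffle_rates <- shuffle_null(part_levels, ann, universe = ids,
                                  n_shuffles = cfg$n_shuffles,
                                  seed = seeds[2L],
                                  min_size = cfg$enrich_min_size,
                                  max_size = cfg$enrich_max_size)
    utils::write.table(enrichment, file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(level = seq_len(n_levels), rate_pct = annotation_rates,
                 t(shuffle_rates)),
      file.path(cfg$out_dir, "annotation_rates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tree) && !is.null(enrichment) && nrow(enrichment)) {
      distance_summary <- block_distance_summary(
        enrichment[enrichment$level == 1L, ], tree, measure = "steps")
    }
  }

  manifest <- list(package_version = as.character(utils::packageVersion("sbmnet")),
                   seed = cfg$seed, stage_seeds = seeds,
                   reduction = cfg$reduction, variants = cfg$variants,
                   n_inits = cfg$n_inits, na_policy = cfg$na_policy,
                   best_variant = selection$variant[1L],
                   best_dl_bits = selection$dl[1L])
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(network_stats = before, reduction = reduction,
                 selection = selection, best_fit = best_fit,
                 edge_scores = scores, score_validation = validation,
                 enrichment = enrichment, annotation_rates = annotation_rates,
                 shuffle_rates = shuffle_rates,
                 distance_summary = distance_summary,
                 out_dir = cfg$out_dir))
}
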