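## Missing-value policies and the Spearman correlation network with per-pair
## p-values over pairwise-complete observations.

#' Apply a missing-value policy to an expression matrix
#'
#' Three policies: `sentinel_log_zero` replaces every missing cell by a
#' sentinel value (the convention for log-transformed zero counts);
#' `drop_high_na` removes entities whose missing count strictly exceeds
#' `floor(na_fraction_max * n_samples)`; `none` passes the matrix through.
#'
#' @param x numeric entities-by-samples matrix, `NA` marking missing cells.
#' @param policy one of `"sentinel_log_zero"`, `"drop_high_na"`, `"none"`.
#' @param na_fraction_max tolerated missing fraction per entity (default 0.2,
#'   i.e. with 36 samples an entity with 8 or more missing values is dropped
#'   while 7 are tolerated).
#' @param sentinel replacement value for `sentinel_log_zero` (default -10).
#' @return a list with `matrix` (the processed matrix), `removed` (dropped
#'   entity ids) and `n_removed`.
#' @export
handle_missing <- function(x, policy = c("sentinel_log_zero", "drop_high_na", "none"),
                           na_fraction_max = 0.2, sentinel = -10) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(x), na_fraction_max >= 0, na_fraction_max <= 1)
  removed <- character(0)
  if (policy == "sentinel_log_zero") {
    x[is.na(x)] <- sentinel
  } else if (policy == "drop_high_na") {
    limit <- floor(na_fraction_max * ncol(x))
    n_na <- rowSums(is.na(x))
    drop <- n_na > limit
    removed <- rownames(x)[drop]
    if (is.null(removed)) removed <- as.character(which(drop))
    x <- x[!drop, , drop = FALSE]
    if (nrow(x) == 0) stop("missing-value filter removed all entities")
  }
  list(matrix = x, removed = removed, n_removed = length(removed))
}

#' Spearman correlation network over pairwise-complete observations
#'
#' For every unordered entity pair, the Spearman rank correlation (midranks
#' for ties) is computed over the samples observed in both entities, with a
#' two-sided p-value from the t approximation `t = rho * sqrt((n - 2) /
#' (1 - rho^2))` on `n - 2` degrees of freedom. Pairs with fewer than 3
#' shared observations, and pairs where an entity is constant over the shared
#' window, get an undefined correlation (`NA`) and are never significant.
#' Perfect correlations get `p = 0` exactly.
#'
#' @param x numeric entities-by-samples matrix with `NA` for missing values.
#' @param entity_cap guard on the number of entities for which the full
#'   correlation matrix may be materialized (default 20000); above it use
#'   [write_spearman_edges()], which streams over row blocks.
#' @return an object of class `corr_network`: list with `entity_ids`, and the
#'   symmetric matrices `rho`, `pvalue` and `n_obs`. The diagonal is `NA`
#'   (self-pairs are excluded from every downstream edge set).
#' @export
spearman_network <- function(x, entity_cap = 20000) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (nrow(x) > entity_cap)
    stop("more than ", entity_cap, " entities: raise entity_cap or stream ",
         "pairs with write_spearman_edges()")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  obs <- !is.na(x)
  n_obs <- tcrossprod(obs * 1)
  rho <- suppressWarnings(
    stats::cor(t(x), method = "spearman", use = "pairwise.complete.obs"))
  rho[n_obs < 3] <- NA
  pvalue <- spearman_pvalue(rho, n_obs)
  diag(rho) <- NA; diag(pvalue) <- NA
  dimnames(rho) <- dimnames(pvalue) <- dimnames(n_obs) <- list(ids, ids)
  structure(list(entity_ids = ids, rho = rho, pvalue = pvalue, n_obs = n_obs),
            class = "corr_network")
}

spearman_pvalue <- function(rho, n_obs) {
  p <- matrix(NA_real_, nrow(rho), ncol(rho))
  ok <- !is.na(rho) & n_obs >= 3
  r <- rho[ok]; n <- n_obs[ok]
  denom <- 1 - r^2
  pv <- numeric(length(r))
  perfect <- denom <= 0
  pv[perfect] <- 0
  tt <- r[!perfect] * sqrt((n[!perfect] - 2) / denom[!perfect])
  pv[!perfect] <- 2 * stats::pt(abs(tt), n[!perfect] - 2, lower.tail = FALSE)
  p[ok] <- pmin(pv, 1)
  p
}

#' @export
print.corr_network <- function(x, ...) {
  n <- length(x$entity_ids)
  cat(sprintf("<corr_network> %d entities, %d pairs (%d undefined)\n",
              n, n * (n - 1) / 2,
              sum(is.na(x$rho[upper.tri(x$rho)]))))
  invisible(x)
}

#' Stream Spearman edges of a large matrix to CSV
#'
#' Computes the same per-pair statistics as [spearman_network()] in row-block
#' chunks, writing rows `source,target,rho,pvalue,n_obs` (each unordered pair
#' once) without materializing the full correlation matrix. Intended for
#' inputs above the in-memory entity cap.
#'
#' @inheritParams spearman_network
#' @param path output CSV path.
#' @param chunk_size rows per block.
#' @return the path, invisibly.
#' @export
write_spearman_edges <- function(x, path, chunk_size = 1000) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  xr <- t(x)  # samples x entities, the orientation cor() wants
  obs <- !is.na(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("source,target,rho,pvalue,n_obs", con)
  starts <- seq(1L, nrow(x) - 1L, by = chunk_size)
  for (st in starts) {
    rows <- st:min(st + chunk_size - 1L, nrow(x) - 1L)
    cols <- (st + 1L):nrow(x)
    n_obs <- tcrossprod(obs[rows, , drop = FALSE] * 1, obs[cols, , drop = FALSE] * 1)
    rho <- suppressWarnings(
      stats::cor(xr[, rows, drop = FALSE], xr[, cols, drop = FALSE],
                 method = "spearman", use = "pairwise.complete.obs"))
    rho[n_obs < 3] <- NA
    p <- spearman_pvalue(rho, n_obs)
    keep <- which(outer(rows, cols, `<`))
    i <- rows[(keep - 1L) %% length(rows) + 1L]
    j <- cols[(keep - 1L) %/% length(rows) + 1L]
    df <- data.frame(source = ids[i], target = ids[j],
                     rho = rho[keep], pvalue = p[keep], n_obs = n_obs[keep])
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
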