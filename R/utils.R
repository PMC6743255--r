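## Internal numeric helpers. All model arithmetic is carried out in base-2
## logarithms ("bits") so that description lengths can be assembled by addition
## without factorial overflow.

LOG2E <- 1 / log(2)

## log2(x!)
lf2 <- function(x) lgamma(x + 1) * LOG2E

## log2(x!!) for even x >= 0, with (2m)!! = 2^m * m!
ldf2 <- function(x) {
  if (any(x %% 2 != 0)) stop("double factorial is only used for even arguments here")
  m <- x / 2
  m + lf2(m)
}

## log2 of binomial coefficient
lchoose2 <- function(n, k) lchoose(n, k) * LOG2E

## log2 of the number of multisets of size m from n elements, C(n+m-1, m).
## multiset(n, 0) = 1 for any n >= 0; multiset(0, m>0) = 0 (log = -Inf).
lmultiset2 <- function(n, m) {
  out <- numeric(length(m))
  n <- rep_len(n, length(m))
  zero <- m == 0
  bad <- !zero & n == 0
  ok <- !zero & !bad
  out[bad] <- -Inf
  out[ok] <- lchoose2(n[ok] + m[ok] - 1, m[ok])
  out
}

## log2(2^a + 2^b), numerically stable
logadd2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log2(1 + 2^(pmin(a, b) - m)))
}

## x * log2(y) with the 0 * log(0) = 0 convention
xlog2y <- function(x, y) {
  out <- x * log2(y)
  out[x == 0] <- 0
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units; 1 means
#' identical partitions up to relabeling, values near 0 are expected for
#' unrelated partitions.
#'
#' @param a,b integer or factor vectors of equal length assigning each unit to
#'   a group.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

## Derive per-stage seeds (< 2^31) from one master seed, reproducibly.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master)
  sample.int(2147483646L, n)
}

## Normalize a graph argument: accept igraph or reduced_graph.
as_igraph <- function(g) {
  if (inherits(g, "reduced_graph")) return(g$graph)
  if (inherits(g, "igraph")) return(g)
  stop("expected an igraph or reduced_graph object")
}
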