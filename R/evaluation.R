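# Partition quality and comparison statistics.

#' Calinski-Harabasz pseudo-F for a partition
#'
#' `F = (R2 / (K - 1)) / ((1 - R2) / (n - K))` — the between/within
#' variance ratio, penalizing larger K. Unlike R2 (which any extra group,
#' especially a singleton, inflates), pseudo-F allows comparison of
#' partitions of the same data with different numbers of groups.
#'
#' @param r2 fit statistic in `[0, 1)` (see [fit_stats()]).
#' @param K number of groups, `2 <= K < n`.
#' @param n number of observations.
#' @return The pseudo-F value.
#' @export
pseudo_f <- function(r2, K, n) {
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (K < 2 || K >= n) stop("need 2 <= K < n")
  (r2 / (K - 1)) / ((1 - r2) / (n - K))
}

#' Agreement between two group solutions of the same facilities
#'
#' Restricts both partitions to their common facilities, matches groups of
#' one solution to groups of the other by maximum-weight bipartite
#' matching on shared-member counts, and reports the percentage of common
#' facilities that fall in matched group pairs, plus the number of matched
#' pairs with exactly identical membership. Used e.g. to compare solutions
#' fitted on independent time periods.
#'
#' @param sol_a,sol_b named group-label vectors (or `hg_solution` objects).
#' @return A list of class `hg_agreement`: `n_common`, `percent`,
#'   `exact_matches`, and `matching` (data.frame of matched group pairs
#'   with shared counts).
#' @export
solution_agreement <- function(sol_a, sol_b) {
  a <- if (inherits(sol_a, "hg_solution")) sol_a$assignments else sol_a
  b <- if (inherits(sol_b, "hg_solution")) sol_b$assignments else sol_b
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("no common facilities between solutions")
  a <- a[common]; b <- b[common]
  ga <- sort(unique(a)); gb <- sort(unique(b))
  w <- table(factor(a, ga), factor(b, gb))
  match_ab <- bipartite_match(unclass(w))
  shared <- integer(0); pairs_a <- character(0); pairs_b <- character(0)
  exact <- 0L
  for (i in seq_along(ga)) {
    j <- match_ab[i]
    if (is.na(j)) next
    pairs_a <- c(pairs_a, as.character(ga[i]))
    pairs_b <- c(pairs_b, as.character(gb[j]))
    shared <- c(shared, w[i, j])
    if (w[i, j] == sum(w[i, ]) && w[i, j] == sum(w[, j])) exact <- exact + 1L
  }
  structure(
    list(n_common = length(common),
         percent = 100 * sum(shared) / length(common),
         exact_matches = exact,
         matching = data.frame(group_a = pairs_a, group_b = pairs_b,
                               shared = shared)),
    class = "hg_agreement")
}

# maximum-weight bipartite matching on a non-negative weight matrix;
# returns, for each row, the matched column index or NA
bipartite_match <- function(w) {
  if (nrow(w) == 1 || ncol(w) == 1) {
    # degenerate: match the single group to its largest counterpart
    if (nrow(w) == 1) return(which.max(w[1, ]))
    out <- rep(NA_integer_, nrow(w))
    out[which.max(w[, 1])] <- 1L
    return(out)
  }
  dimnames(w) <- NULL  # vertex ids stay positional
  g <- igraph::graph_from_biadjacency_matrix(w, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  idx <- as.integer(m$matching[seq_len(nrow(w))]) - nrow(w)
  idx[!is.na(idx) & idx < 1] <- NA_integer_
  idx
}

#' @export
print.hg_agreement <- function(x, ...) {
  cat(sprintf("Solution agreement: %.2f%% of %d common facilities; %d exactly matched group(s)\n",
              x$percent, x$n_common, x$exact_matches))
  invisible(x)
}

#' Adjusted Rand index between a solution and reference labels
#'
#' Chance-corrected partition agreement: 1 for identical partitions,
#' about 0 for independent ones. Used to score recovery of planted
#' community structure in synthetic regions.
#'
#' @param labels_a,labels_b two label vectors of equal length (an
#'   `hg_solution` may be supplied; its assignments are used).
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
recovery_score <- function(labels_a, labels_b) {
  a <- if (inherits(labels_a, "hg_solution")) labels_a$assignments else labels_a
  b <- if (inherits(labels_b, "hg_solution")) labels_b$assignments else labels_b
  if (!is.null(names(a)) && !is.null(names(b)) &&
      setequal(names(a), names(b)))
    b <- b[names(a)]
  if (length(a) != length(b))
    stop("label vectors differ in length")
  mclust::adjustedRandIndex(a, b)
}

#' Size of the K-group assignment space
#'
#' Estimates the number of distinct ways to sort N observations into K
#' groups, `K^N / K!`, in log space (so it is exact to floating precision
#' even when the count is astronomically large).
#'
#' @param K number of groups.
#' @param N number of observations (`N >= K`).
#' @return A list with `log10` (log10 of the count), `mantissa` (leading
#'   digit, one significant figure) and `exponent` (the power of ten).
#' @export
partition_count_estimate <- function(K, N) {
  if (K < 1 || N < K) stop("need 1 <= K <= N")
  l10 <- N * log10(K) - lgamma(K + 1) / log(10)
  expo <- floor(l10)
  mant <- signif(10^(l10 - expo), 1)
  if (mant >= 10) { mant <- mant / 10; expo <- expo + 1 }
  list(log10 = l10, mantissa = mant, exponent = expo)
}
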