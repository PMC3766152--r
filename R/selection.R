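# Choosing the number of groups: incremental F statistic over the sweep,
# candidate solutions at its strict local maxima, and a three-step
# decision-rule heuristic.

#' Decision rules for selecting the number of groups
#'
#' The default rules encode two planning qualifications: no individual
#' group may contain more than 20 underlying facilities, and the number of
#' single-facility groups is minimized. Ties after both rules are broken
#' by taking the largest K. The rules are plain data so applications with
#' different planning constraints can adjust them.
#'
#' @param max_group_size maximum facilities allowed in one group
#'   (default 20).
#' @param minimize_single keep only candidates with the fewest
#'   single-facility groups (default TRUE).
#' @return A list of class `selection_rules`.
#' @export
selection_rules <- function(max_group_size = 20L, minimize_single = TRUE) {
  max_group_size <- as.integer(max_group_size)
  if (is.na(max_group_size) || max_group_size < 1L)
    stop("max_group_size must be a positive integer")
  structure(list(max_group_size = max_group_size,
                 minimize_single = isTRUE(minimize_single),
                 tie_rule = "maximum K"),
            class = "selection_rules")
}

#' Incremental F statistic over a consecutive-K solution grid
#'
#' For each K on the grid,
#' `incF(K) = (R2(K) - R2(K-1)) / ((1 - R2(K)) / (n - (K - 1)))`,
#' the fit gained by allowing one more group relative to the residual
#' unexplained variance per remaining degree of freedom. The K = 1
#' reference (R2 = 0) must be present so incF is defined at K = 2.
#'
#' @param r2_series numeric vector of R2 values named by K, on a
#'   consecutive integer grid starting at 1 with `r2[1] = 0`.
#' @param n number of facilities (observations); must exceed the largest K.
#' @return Named numeric vector of incF values for K >= 2. Positions where
#'   R2 = 1 (perfect fit) are `NA`: incF is undefined there and such K are
#'   excluded from the candidate search.
#' @export
incremental_f <- function(r2_series, n) {
  ks <- as.integer(names(r2_series))
  if (anyNA(ks)) stop("r2_series must be named by integer K")
  o <- order(ks)
  ks <- ks[o]; r2 <- as.numeric(r2_series[o])
  if (ks[1] != 1L || any(diff(ks) != 1L))
    stop("r2_series must cover a consecutive K grid starting at K = 1")
  if (r2[1] != 0) stop("the K = 1 reference must have r2 = 0")
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  if (n <= max(ks)) stop("n must exceed the largest K on the grid")
  i <- seq(2, length(ks))
  incf <- (r2[i] - r2[i - 1]) / ((1 - r2[i]) / (n - (ks[i] - 1)))
  incf[r2[i] == 1] <- NA_real_
  setNames(incf, ks[i])
}

#' Candidate solutions at strict local maxima of incF
#'
#' A grid point K is a candidate when `incF(K) > incF(K-1)` and
#' `incF(K) > incF(K+1)` (strictly; plateaus are not candidates).
#' Endpoints of the grid lack a two-sided neighborhood and are never
#' candidates. Each candidate row is annotated with the number of
#' single-facility groups (`SH`) and the largest group size (`Max`), both
#' counted in *underlying* facilities via `member_count`: a merged
#' tandem-reporting observation contributes all its members to its group's
#' size and is never counted as a single-facility group.
#'
#' @param incf_series named incF vector from [incremental_f()] on a
#'   consecutive K grid (NA entries are excluded from the search).
#' @param solutions list of `hg_solution` objects named by K (e.g.
#'   `cluster_sweep()$solutions`), covering every candidate K.
#' @param facilities optional [facility_table()] supplying `member_count`
#'   (default: every observation is a single facility).
#' @return A `data.frame` of class `hg_candidates` with columns
#'   `clusters`, `incF`, `SH`, `Max`, ordered by increasing K.
#' @export
find_candidates <- function(incf_series, solutions, facilities = NULL) {
  ks <- as.integer(names(incf_series))
  o <- order(ks)
  ks <- ks[o]; incf <- as.numeric(incf_series[o])
  if (length(ks) < 3) stop("need at least 3 grid points to find local maxima")
  if (any(diff(ks) != 1L)) stop("incF series must be on a consecutive K grid")
  is_max <- rep(FALSE, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    if (anyNA(incf[(i - 1):(i + 1)])) next
    is_max[i] <- incf[i] > incf[i - 1] && incf[i] > incf[i + 1]
  }
  cand_k <- ks[is_max]
  rows <- lapply(cand_k, function(K) {
    sol <- solutions[[as.character(K)]]
    if (is.null(sol)) stop("no solution provided for candidate K = ", K)
    sz <- group_sizes(sol$assignments, facilities)
    data.frame(clusters = K, incF = incf[ks == K],
               SH = sum(sz$members == 1L), Max = max(sz$members))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clusters = integer(), incF = numeric(),
               SH = integer(), Max = integer())
  class(out) <- c("hg_candidates", "data.frame")
  out
}

# per-group observation and underlying-facility counts
group_sizes <- function(assignments, facilities = NULL) {
  mc <- rep(1L, length(assignments))
  if (!is.null(facilities)) {
    idx <- match(names(assignments), facilities$facility_id)
    if (anyNA(idx)) stop("assignments contain facilities missing from the registry")
    mc <- facilities$member_count[idx]
  }
  members <- vapply(split(mc, assignments), sum, 0L)
  obs <- vapply(split(mc, assignments), length, 0L)
  list(members = members, observations = obs)
}

#' Select the final number of groups by the three-step heuristic
#'
#' Step 1 removes candidates in which any group holds more than
#' `rules$max_group_size` underlying facilities. Step 2 keeps the
#' candidates with the minimum number of single-facility groups. Step 3
#' returns the largest K among the survivors. Every elimination is
#' recorded in an audit table.
#'
#' @param candidates an `hg_candidates` table from [find_candidates()] (or
#'   any data frame with columns `clusters`, `incF`, `SH`, `Max`).
#' @param rules a [selection_rules()] object.
#' @return A list with `K` (the selected number of groups), `survivors`
#'   (the K values alive after each step) and `audit` (a data.frame of
#'   eliminated candidates with the step and reason).
#' @export
select_k <- function(candidates, rules = selection_rules()) {
  stopifnot(is.data.frame(candidates),
            all(c("clusters", "incF", "SH", "Max") %in% names(candidates)))
  if (nrow(candidates) == 0) stop("no candidate solutions to select from")
  cand <- candidates[order(candidates$clusters), ]
  audit <- data.frame(clusters = integer(), step = integer(),
                      reason = character())

  keep1 <- cand$Max <= rules$max_group_size
  if (any(!keep1))
    audit <- rbind(audit, data.frame(
      clusters = cand$clusters[!keep1], step = 1L,
      reason = sprintf("largest group has %d > %d facilities",
                       cand$Max[!keep1], rules$max_group_size)))
  s1 <- cand[keep1, ]
  if (nrow(s1) == 0)
    stop("no candidate satisfies max_group_size = ", rules$max_group_size,
         "; consider relaxing the selection rules")

  if (rules$minimize_single) {
    min_sh <- min(s1$SH)
    keep2 <- s1$SH == min_sh
    if (any(!keep2))
      audit <- rbind(audit, data.frame(
        clusters = s1$clusters[!keep2], step = 2L,
        reason = sprintf("%d single-facility groups > minimum %d",
                         s1$SH[!keep2], min_sh)))
    s2 <- s1[keep2, ]
  } else s2 <- s1

  K <- max(s2$clusters)
  if (nrow(s2) > 1)
    audit <- rbind(audit, data.frame(
      clusters = setdiff(s2$clusters, K), step = 3L,
      reason = sprintf("smaller than maximum surviving K = %d", K)))

  list(K = K,
       survivors = list(step1 = s1$clusters, step2 = s2$clusters),
       audit = audit[order(audit$clusters), ])
}

#' Write a candidate table in the standard display format
#'
#' Columns `clusters,incF,SH,Max`, incF rounded to 2 decimals; a JSON
#' sidecar retains full precision.
#'
#' @param candidates an `hg_candidates` table.
#' @param path output CSV path.
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates
  out$incF <- sprintf("%.2f", out$incF)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(candidates), sub("\\.[^.]*$", ".json", path),
                       digits = NA)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path CSV path with columns `clusters,incF,SH,Max`.
#' @return An `hg_candidates` data frame.
#' @export
read_candidates <- function(path) {
  out <- read.csv(path)
  need <- c("clusters", "incF", "SH", "Max")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop("missing candidate column(s): ", paste(missing_cols, collapse = ", "))
  out <- out[need]
  class(out) <- c("hg_candidates", "data.frame")
  out
}
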