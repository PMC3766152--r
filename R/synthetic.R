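# Synthetic patient-flow regions with planted community structure, so the
# whole pipeline is testable without confidential hospitalization data.
#
# The generator emulates the *statistical shape* of real origin-
# destination patient-day data: facilities and areal units clustered
# around community centers, log-normal facility sizes, and integer
# patient-day flows drawn from a gravity (Huff-type) allocation
#   p(facility i | unit j)  ~  S_i^alpha * exp(-beta * d_ij) * gamma^[same community] ,
# with S_i the facility's attractiveness (bed count). It makes no attempt
# to mimic any particular geography, road network or temporal trend.

#' Generate a synthetic patient-flow region
#'
#' Places `n_communities` community centers evenly on a ring
#' (`community_spacing` apart), scatters facilities and areal units around
#' each center, draws facility bed counts from a log-normal distribution,
#' and samples each unit's patient days from a multinomial over facilities
#' with gravity-model probabilities. Distances are Euclidean on the
#' generated plane, in the same units (km) as `beta` is per-km.
#'
#' Defaults describe a region with pronounced community structure:
#' communities 60 km apart with 8 km within-community scatter and a
#' distance-decay rate of 0.15/km, so cross-community flows are rare but
#' not impossible — the regime the grouping methodology is designed for.
#'
#' @param n_communities number of planted communities (default 5).
#' @param facilities_per_community facilities per community; a single
#'   count or a `c(min, max)` range sampled per community (default 3).
#' @param units_per_community areal units per community; count or range
#'   (default 6).
#' @param bed_meanlog,bed_sdlog log-normal bed-size parameters (defaults
#'   `log(150)` and 0.7, i.e. a median 150-bed facility with occasional
#'   much larger ones).
#' @param alpha gravity size exponent (default 1: attraction proportional
#'   to beds).
#' @param beta distance-decay rate per km (default 0.15).
#' @param gamma within-community affinity multiplier, `>= 1` (default 3).
#' @param days_per_unit mean total patient days per areal unit (Poisson;
#'   default 2000).
#' @param community_spacing distance in km between adjacent community
#'   centers (default 60; must be positive).
#' @param scatter_sd standard deviation in km of facility/unit scatter
#'   around their community center (default 8).
#' @param seed RNG seed (required; the same seed reproduces the region
#'   exactly).
#' @return A list of class `hg_region`: `od` ([utilization_od()]),
#'   `dist` ([distance_matrix()]), `facilities` ([facility_table()] with
#'   bed counts), `labels` (named planted community of each facility),
#'   `facility_coords` and `unit_coords` (two-column matrices).
#' @export
generate_region <- function(n_communities = 5L,
                            facilities_per_community = 3L,
                            units_per_community = 6L,
                            bed_meanlog = log(150), bed_sdlog = 0.7,
                            alpha = 1, beta = 0.15, gamma = 3,
                            days_per_unit = 2000,
                            community_spacing = 60,
                            scatter_sd = 8,
                            seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (n_communities < 1 || any(facilities_per_community < 1) ||
      any(units_per_community < 1))
    stop("counts must be >= 1")
  if (beta < 0 || alpha < 0) stop("alpha and beta must be >= 0")
  if (gamma < 1) stop("gamma must be >= 1")
  if (community_spacing <= 0 && n_communities > 1)
    stop("community centers coincide: community_spacing must be positive")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  draw_count <- function(spec, n) {
    if (length(spec) == 1) rep(as.integer(spec), n)
    else sample(seq(spec[1], spec[2]), n, replace = TRUE)
  }
  nf <- draw_count(facilities_per_community, n_communities)
  nu <- draw_count(units_per_community, n_communities)
  n <- sum(nf); z <- sum(nu)
  if (n < 2) stop("need at least 2 facilities in total")

  # centers on a ring whose chord between neighbors equals the spacing
  ang <- seq(0, 2 * pi, length.out = n_communities + 1)[seq_len(n_communities)]
  radius <- if (n_communities > 1) community_spacing / (2 * sin(pi / n_communities)) else 0
  cx <- radius * cos(ang); cy <- radius * sin(ang)

  fac_com <- rep(seq_len(n_communities), nf)
  unit_com <- rep(seq_len(n_communities), nu)
  fac_ids <- sprintf("H%03d", seq_len(n))
  unit_ids <- sprintf("U%03d", seq_len(z))
  fxy <- cbind(cx[fac_com] + rnorm(n, 0, scatter_sd),
               cy[fac_com] + rnorm(n, 0, scatter_sd))
  uxy <- cbind(cx[unit_com] + rnorm(z, 0, scatter_sd),
               cy[unit_com] + rnorm(z, 0, scatter_sd))
  rownames(fxy) <- fac_ids; rownames(uxy) <- unit_ids

  beds <- round(rlnorm(n, bed_meanlog, bed_sdlog))
  beds[beds < 10] <- 10

  d_fu <- sqrt(outer(fxy[, 1], uxy[, 1], "-")^2 +
               outer(fxy[, 2], uxy[, 2], "-")^2)
  counts <- matrix(0, n, z, dimnames = list(fac_ids, unit_ids))
  for (j in seq_len(z)) {
    p <- beds^alpha * exp(-beta * d_fu[, j]) *
      ifelse(fac_com == unit_com[j], gamma, 1)
    counts[, j] <- rmultinom(1, rpois(1, days_per_unit), p)
  }

  d_ff <- sqrt(outer(fxy[, 1], fxy[, 1], "-")^2 +
               outer(fxy[, 2], fxy[, 2], "-")^2)
  dimnames(d_ff) <- list(fac_ids, fac_ids)

  structure(
    list(od = utilization_od(counts),
         dist = distance_matrix(d_ff, tol = 1e-6),
         facilities = facility_table(fac_ids, beds = beds),
         labels = setNames(fac_com, fac_ids),
         facility_coords = fxy,
         unit_coords = uxy),
    class = "hg_region")
}

#' @export
print.hg_region <- function(x, ...) {
  cat(sprintf("Synthetic region: %d facilities, %d areal units, %d planted communities, %s patient days\n",
              length(x$od$facilities), length(x$od$units),
              length(unique(x$labels)), format(sum(x$od$counts), big.mark = ",")))
  invisible(x)
}

#' Write a synthetic region to the standard input-file formats
#'
#' Emits `od.csv` (long OD table), `distances.csv` (square matrix),
#' `registry.csv` (facility table with empty tandem labels) and
#' `labels.csv` (planted ground truth) into a directory.
#'
#' @param region an `hg_region` from [generate_region()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "hg_region"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("od.csv", "distances.csv", "registry.csv", "labels.csv"))
  write_od_long(region$od, paths[1])
  write_distance_matrix(region$dist, paths[2])
  reg <- region$facilities
  reg$tandem_group <- ""
  reg$member_count <- NULL
  write.csv(reg, paths[3], row.names = FALSE, quote = FALSE)
  write.csv(data.frame(facility_id = names(region$labels),
                       community = unname(region$labels)),
            paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Published statewide candidate table (Michigan acute-care hospitals)
#'
#' The candidate-solution summary from the statewide Michigan analysis of
#' 2008-2010 inpatient data (158 clustered observations): for each of the
#' 52 candidate K values flagged by the incremental-F local-maxima rule,
#' the incF value, the number of single-hospital groups (`SH`) and the
#' largest group size (`Max`). Bundled as a worked reference for the
#' selection heuristic: with the default rules the heuristic removes all
#' candidates below 29 groups (size rule), keeps the SH = 1 candidates
#' \{29, 31, 33\} and selects K = 33.
#'
#' @return An `hg_candidates` data frame with 52 rows.
#' @export
michigan_candidates <- function() {
  out <- data.frame(
    clusters = c(3L, 5L, 7L, 11L, 14L, 18L, 21L, 23L, 27L, 29L, 31L, 33L,
                 36L, 38L, 42L, 46L, 49L, 51L, 53L, 55L, 58L, 60L, 63L,
                 69L, 73L, 75L, 77L, 81L, 83L, 86L, 89L, 93L, 97L, 99L,
                 101L, 103L, 107L, 109L, 112L, 115L, 120L, 124L, 126L,
                 129L, 132L, 135L, 141L, 144L, 146L, 149L, 152L, 154L),
    incF = c(94.81, 81.11, 33.59, 14.88, 7.93, 6.59, 9.38, 6.52, 6.02,
             3.56, 3.52, 4.11, 4.35, 4.39, 4.05, 4.12, 3.92, 3.71, 3.61,
             3.53, 4.02, 3.97, 4.02, 4.25, 4.61, 4.43, 4.13, 4.38, 4.17,
             4.29, 3.77, 3.83, 4.14, 4.37, 4.72, 5.22, 4.94, 3.77, 3.79,
             3.84, 3.41, 3.08, 2.52, 2.44, 2.39, 2.10, 1.91, 1.91, 1.87,
             1.99, 1.88, 1.92),
    SH = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 5L, 7L,
           9L, 11L, 13L, 15L, 16L, 20L, 22L, 27L, 36L, 40L, 43L, 44L,
           48L, 49L, 53L, 58L, 64L, 70L, 73L, 77L, 79L, 83L, 86L, 90L,
           93L, 99L, 103L, 107L, 111L, 114L, 118L, 125L, 129L, 133L,
           136L, 141L, 145L),
    Max = c(91L, 60L, 61L, 51L, 48L, 45L, 36L, 36L, 24L, 17L, 17L, 17L,
            17L, 17L, 17L, 16L, 16L, 12L, 12L, 12L, 12L, 12L, 12L, 12L,
            12L, 12L, 9L, 8L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L,
            7L, 7L, 7L, 5L, 5L, 5L, 5L, 5L, 5L, 4L, 4L, 3L, 3L, 3L))
  class(out) <- c("hg_candidates", "data.frame")
  out
}
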