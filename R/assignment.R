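# Geographic assignment of a new or proposed facility to an existing
# group solution. The new facility has no utilization history, so it is
# placed by location alone: its rescaled distance vector is compared with
# the distance block of each group center and the nearest center wins.

#' Build the rescaled distance vector for a new facility
#'
#' Divides the raw travel distances from the new facility to every
#' existing facility by the *original* rescaling maximum `d_max` (stored
#' on the feature matrix), and arranges the entries in the original
#' facility order. Entries may exceed 1 when the new facility is farther
#' from some facility than any historical pair was.
#'
#' @param raw_distances numeric vector of non-negative distances, named by
#'   facility id (reordered to `facility_order`) or unnamed and already in
#'   order.
#' @param d_max the rescaling maximum from the fitted feature matrix.
#' @param facility_order character vector: the original facility ordering.
#' @return Numeric vector of rescaled distances in the original order.
#' @export
build_new_vector <- function(raw_distances, d_max, facility_order) {
  if (d_max <= 0) stop("d_max must be positive")
  if (length(raw_distances) != length(facility_order))
    stop(sprintf("expected %d distances, got %d",
                 length(facility_order), length(raw_distances)))
  if (!is.null(names(raw_distances))) {
    absent <- setdiff(facility_order, names(raw_distances))
    if (length(absent))
      stop("distances missing for: ", paste(absent, collapse = ", "))
    raw_distances <- raw_distances[facility_order]
  }
  if (any(raw_distances < 0)) stop("distances must be non-negative")
  h <- unname(raw_distances) / d_max
  if (any(h > 1))
    message(sprintf("%d rescaled distance(s) exceed 1 (beyond the historical maximum)",
                    sum(h > 1)))
  setNames(h, facility_order)
}

#' Assign a new facility to the nearest existing group
#'
#' Subsets each group center to its distance-block columns and computes
#' the Euclidean distance `d = sqrt(sum((c_i - h_i)^2))` from the new
#' facility's rescaled distance vector to each center. The facility is
#' assigned to the group with the minimum d; ties go to the lowest group
#' index (and are reported). Only the distance block participates — the
#' utilization block of the centers is ignored by construction.
#'
#' @param solution an `hg_solution` whose centers carry the full feature
#'   columns.
#' @param new_vector rescaled distance vector from [build_new_vector()].
#' @param block per-column block labels of the feature matrix
#'   (`"utilization"`/`"distance"`), as stored by [build_features()].
#' @param distance_weight scalar weight applied to the distance block when
#'   the features were built (default 1).
#' @return A list with `group` (the assigned index) and `d` (the distance
#'   from the new facility to every group center).
#' @export
assign_new_facility <- function(solution, new_vector, block,
                                distance_weight = 1) {
  stopifnot(inherits(solution, "hg_solution"))
  if (missing(block) || is.null(block)) stop("block labels are required")
  if (length(block) != ncol(solution$centers))
    stop("block labels do not match the center columns")
  dcols <- which(block == "distance")
  if (length(dcols) != length(new_vector))
    stop(sprintf("new-facility vector has %d entries but the distance block has %d columns",
                 length(new_vector), length(dcols)))
  centers <- solution$centers[, dcols, drop = FALSE]
  h <- unname(new_vector) * distance_weight
  d <- sqrt(rowSums(sweep(centers, 2, h)^2))
  grp <- which(d == min(d))
  if (length(grp) > 1)
    message("tie in assignment distance; lowest group index chosen: ",
            paste(grp, collapse = ", "))
  list(group = grp[1], d = unname(d))
}
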