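# Clustering feature space: CI profiles joined with rescaled distances.

#' Rescale a distance matrix to the unit interval
#'
#' Divides every entry by the maximum pairwise distance, so the distance
#' block of the feature matrix lives on the same 0-1 scale as the CI
#' block. The maximum (`d_max`, in the original distance units) is retained
#' because a new facility's distance vector must later be rescaled by the
#' *original* maximum, not one recomputed with the new facility included.
#'
#' @param dist a [distance_matrix()] object (or square numeric matrix).
#' @return A list with `rescaled` (matrix in `[0, 1]`) and `d_max`.
#' @export
rescale_distances <- function(dist) {
  d <- if (inherits(dist, "distance_matrix")) dist$d else as.matrix(dist)
  if (nrow(d) < 2) stop("need at least two facilities to rescale distances")
  d_max <- max(d[row(d) != col(d)])
  if (d_max <= 0) stop("all inter-facility distances are zero")
  list(rescaled = d / d_max, d_max = d_max)
}

#' Join CI and rescaled-distance blocks into the clustering feature matrix
#'
#' Produces the n x m data matrix that is actually clustered: m = z + p
#' attributes per facility, the z CI columns first, then the p rescaled
#' distance columns (p equals n except when merged observations retain
#' distances to the original facility locations). Both blocks lie in
#' `[0, 1]`, which keeps their ranges comparable without further
#' standardization.
#'
#' @param ci CI matrix from [compute_ci()].
#' @param rescaled rescaled distance matrix (same facility row order).
#' @param d_max the rescaling maximum from [rescale_distances()].
#' @param distance_weight optional scalar multiplier on the distance block
#'   (default 1, i.e. the blocks are weighted implicitly by their column
#'   counts z and p). Exposed for sensitivity analysis.
#' @return Numeric matrix of class `hg_features` with attributes `block`
#'   (per-column `"utilization"`/`"distance"` labels), `d_max` and
#'   `distance_weight`.
#' @export
build_features <- function(ci, rescaled, d_max, distance_weight = 1) {
  ci <- as.matrix(ci)
  rescaled <- as.matrix(rescaled)
  if (!identical(rownames(ci), rownames(rescaled)))
    stop("facility ordering differs between CI and distance blocks")
  if (d_max <= 0) stop("d_max must be positive")
  if (distance_weight <= 0) stop("distance_weight must be positive")
  dcols <- rescaled * distance_weight
  colnames(dcols) <- paste0("dist:", colnames(rescaled))
  x <- cbind(ci, dcols)
  structure(x,
            block = rep(c("utilization", "distance"),
                        c(ncol(ci), ncol(rescaled))),
            d_max = d_max,
            distance_weight = distance_weight,
            class = c("hg_features", class(x)))
}

#' Write a feature matrix with an auditable two-row header
#'
#' The first header row labels each column's block (`utilization` or
#' `distance`), the second carries the column id.
#'
#' @param features an `hg_features` matrix from [build_features()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_features <- function(features, path, sep = ",") {
  stopifnot(inherits(features, "hg_features"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("block", attr(features, "block")), collapse = sep), con)
  writeLines(paste(c("facility_id", colnames(features)), collapse = sep), con)
  body <- apply(features, 1, function(r) paste(r, collapse = sep))
  writeLines(paste(rownames(features), body, sep = sep), con)
}
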