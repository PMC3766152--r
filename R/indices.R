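# Patient-origin utilization indices.

#' Commitment Index matrix
#'
#' The Commitment Index `CI[i, j] = Pd[i, j] / Pd[i]` is the share of
#' facility i's total patient days contributed by areal unit j. Each
#' facility's row sums to one, so CI profiles characterize the geographic
#' footprint of a facility's patient base in a way that is directly
#' comparable across facilities of very different sizes: scaling a
#' facility's utilization row leaves its CI profile unchanged.
#'
#' @param od a [utilization_od()] object with every facility active
#'   (apply [drop_inactive()] first).
#' @return Numeric matrix of CI values, same dimnames as the utilization
#'   matrix; rows sum to 1.
#' @export
compute_ci <- function(od) {
  stopifnot(inherits(od, "utilization_od"))
  tot <- rowSums(od$counts)
  if (any(tot == 0))
    stop("facilities with zero patient days present; apply drop_inactive() first: ",
         paste(od$facilities[tot == 0], collapse = ", "))
  od$counts / tot
}

#' Relevance Index matrix
#'
#' The Relevance Index `RI[i, j] = Pd[i, j] / Pd[j]` is the share of areal
#' unit j's total patient days supplied by facility i — the unit's
#' dependence on the facility. Columns sum to one when the utilization
#' table is exhaustive for the unit. Unlike CI, RI is strongly driven by
#' facility size. RI is provided for diagnostics and comparison; the
#' clustering pipeline itself uses CI only.
#'
#' @param od a [utilization_od()] object.
#' @return Numeric matrix of RI values; columns for areal units with no
#'   patient days are all zero by convention.
#' @export
compute_ri <- function(od) {
  stopifnot(inherits(od, "utilization_od"))
  tot <- colSums(od$counts)
  tot[tot == 0] <- 1  # zero-usage units become all-zero columns
  sweep(od$counts, 2, tot, "/")
}

#' Write an index matrix as delimited text
#'
#' Facility rows, areal-unit columns, fixed decimal precision.
#'
#' @param m a CI or RI matrix (facilities x units).
#' @param path output path.
#' @param digits decimal places (default 6).
#' @param sep field separator.
#' @export
write_index_matrix <- function(m, path, digits = 6, sep = ",") {
  out <- data.frame(facility_id = rownames(m),
                    format(round(m, digits), nsmall = digits, trim = TRUE),
                    check.names = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
}
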