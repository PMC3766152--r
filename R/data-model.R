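# Domain containers and input normalization.
#
# All orderings are deterministic (lexicographic on ids) so that repeated
# runs on the same files are byte-identical downstream.

#' Construct a facility-by-areal-unit utilization matrix
#'
#' Holds non-negative patient-day totals with facilities on rows and areal
#' units (e.g. zip codes) on columns. Row sums give the total patient days
#' at each facility (`Pd_i`), column sums the total patient days used by
#' residents of each areal unit (`Pd_j`).
#'
#' @param counts numeric matrix of non-negative patient-day totals with
#'   facility ids as row names and areal-unit ids as column names.
#' @return An object of class `utilization_od`: a list with elements
#'   `counts` (the matrix), `facilities` and `units` (ordered id vectors).
#' @export
utilization_od <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must carry facility row names and areal-unit column names")
  if (anyNA(counts) || !is.numeric(counts))
    stop("'counts' must be numeric with no missing values")
  if (any(counts < 0))
    stop("patient-day counts must be non-negative")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate facility ids in 'counts'")
  structure(
    list(counts = counts,
         facilities = rownames(counts),
         units = colnames(counts)),
    class = "utilization_od")
}

#' @export
print.utilization_od <- function(x, ...) {
  cat(sprintf("Utilization OD matrix: %d facilities x %d areal units, %s patient days\n",
              length(x$facilities), length(x$units),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.utilization_od <- function(x) dim(x$counts)

#' Construct an inter-facility distance matrix
#'
#' @param d square numeric matrix of non-negative travel distances with
#'   identical facility ids as row and column names, zero diagonal, and
#'   symmetric within `tol`.
#' @param tol relative tolerance for symmetry (default `1e-9`); asymmetry
#'   below `tol` is removed by averaging `d` with its transpose.
#' @return An object of class `distance_matrix`: a list with elements `d`
#'   and `facilities`.
#' @export
distance_matrix <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must carry facility ids")
  if (!identical(rownames(d), colnames(d)))
    stop("distance matrix row and column ids differ")
  if (anyNA(d) || any(d < 0)) stop("distances must be non-negative and complete")
  rel <- max(abs(d - t(d))) / max(max(d), .Machine$double.eps)
  if (rel > tol)
    stop(sprintf("distance matrix is asymmetric (relative asymmetry %.3g)", rel))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(d = d, facilities = rownames(d)), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d facilities, max distance %.3g\n",
              length(x$facilities), max(x$d)))
  invisible(x)
}

#' @export
dim.distance_matrix <- function(x) dim(x$d)

#' Construct a facility registry table
#'
#' `member_count` records how many underlying facilities an observation
#' represents: 1 for an ordinary facility, more for a merged tandem-reporting
#' group. The selection heuristic uses it to count "single-facility" groups
#' and group sizes in underlying facilities.
#'
#' @param facility_id character vector of unique ids.
#' @param name display names (defaults to the ids).
#' @param member_count positive integer count of underlying facilities.
#' @param beds optional non-negative bed counts (NA allowed).
#' @return A `data.frame` with class `facility_table`.
#' @export
facility_table <- function(facility_id, name = facility_id,
                           member_count = 1L, beds = NA_real_) {
  facility_id <- as.character(facility_id)
  if (anyDuplicated(facility_id)) stop("facility ids must be unique")
  member_count <- as.integer(rep_len(member_count, length(facility_id)))
  if (any(member_count < 1L)) stop("member_count must be >= 1")
  beds <- rep_len(beds, length(facility_id))
  if (any(!is.na(beds) & beds < 0)) stop("beds must be non-negative")
  out <- data.frame(facility_id = facility_id,
                    name = as.character(rep_len(name, length(facility_id))),
                    member_count = member_count,
                    beds = beds,
                    stringsAsFactors = FALSE)
  class(out) <- c("facility_table", "data.frame")
  out
}

#' Read a long-format origin-destination patient-day file
#'
#' Reads a delimited text file with one row per (facility, areal unit) pair
#' and densifies it into a [utilization_od()] matrix. Duplicate pairs are
#' summed; unobserved pairs become zeros; facilities and units are ordered
#' lexicographically so results are reproducible.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @param columns length-3 character vector naming the facility-id, unit-id
#'   and patient-day columns in the file, in that order.
#' @return A [utilization_od()] object.
#' @export
read_od_long <- function(path, sep = ",",
                         columns = c("facility_id", "unit_id", "patient_days")) {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop(sprintf("no data rows in '%s'", path))
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  fac <- raw[[columns[1]]]
  unit <- raw[[columns[2]]]
  pd <- suppressWarnings(as.numeric(raw[[columns[3]]]))
  bad <- which(is.na(pd) | pd < 0)
  if (length(bad))
    stop(sprintf("negative or non-numeric patient_days at data row %d (value '%s')",
                 bad[1], raw[[columns[3]]][bad[1]]))
  od_table(fac, unit, pd)
}

# densify long triples into a lexicographically ordered matrix
od_table <- function(fac, unit, pd) {
  flev <- sort(unique(fac))
  ulev <- sort(unique(unit))
  m <- matrix(0, length(flev), length(ulev), dimnames = list(flev, ulev))
  idx <- cbind(match(fac, flev), match(unit, ulev))
  for (r in seq_along(pd)) m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + pd[r]
  utilization_od(m)
}

#' Write a utilization matrix as a long-format delimited file
#'
#' Zero cells are omitted; reading the file back with [read_od_long()]
#' reproduces the matrix exactly.
#'
#' @param od a [utilization_od()] object.
#' @param path output path.
#' @param sep field separator.
#' @export
write_od_long <- function(od, path, sep = ",") {
  stopifnot(inherits(od, "utilization_od"))
  nz <- which(od$counts != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  out <- data.frame(facility_id = od$facilities[nz[, 1]],
                    unit_id = od$units[nz[, 2]],
                    patient_days = od$counts[nz])
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a square inter-facility distance matrix
#'
#' The first row and first column must carry the facility ids. Asymmetry up
#' to `1e-6` relative is symmetrized by averaging; larger asymmetry is an
#' error. A nonzero diagonal is reset to zero with a warning.
#'
#' @param path path to a delimited square matrix file.
#' @param sep field separator.
#' @return A [distance_matrix()] object.
#' @export
read_distance_matrix <- function(path, sep = ",") {
  d <- as.matrix(read.csv(path, sep = sep, row.names = 1, check.names = FALSE))
  if (nrow(d) != ncol(d))
    stop(sprintf("distance matrix in '%s' is not square (%d x %d)",
                 path, nrow(d), ncol(d)))
  if (!identical(rownames(d), colnames(d)))
    stop("distance matrix header ids do not match row ids")
  rel <- max(abs(d - t(d))) / max(max(d), .Machine$double.eps)
  if (rel > 1e-6)
    stop(sprintf("distance matrix is asymmetric (relative asymmetry %.3g > 1e-6)", rel))
  if (any(diag(d) != 0)) {
    warning("nonzero diagonal entries reset to 0")
    diag(d) <- 0
  }
  distance_matrix(d, tol = 1e-6)
}

#' Write a distance matrix file readable by [read_distance_matrix()]
#'
#' @param dist a [distance_matrix()] object.
#' @param path output path.
#' @param sep field separator.
#' @export
write_distance_matrix <- function(dist, path, sep = ",") {
  stopifnot(inherits(dist, "distance_matrix"))
  out <- data.frame(facility_id = dist$facilities, dist$d,
                    check.names = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a facility registry file
#'
#' Expected columns: `facility_id,name,beds,tandem_group`, where
#' `tandem_group` is a shared label for facilities that report their
#' utilization jointly (empty otherwise).
#'
#' @param path path to a delimited registry file.
#' @param sep field separator.
#' @return A list with `table` (a [facility_table()]) and `tandem_groups`
#'   (a named list of facility-id vectors, one per tandem label).
#' @export
read_facility_registry <- function(path, sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("facility_id", "name", "beds", "tandem_group")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing registry column(s): ", paste(missing_cols, collapse = ", "))
  tg <- as.character(raw$tandem_group)
  tg[is.na(tg)] <- ""
  groups <- split(as.character(raw$facility_id), tg)
  groups <- groups[names(groups) != ""]
  groups <- groups[vapply(groups, length, 1L) > 1L]
  list(table = facility_table(raw$facility_id, raw$name,
                              beds = suppressWarnings(as.numeric(raw$beds))),
       tandem_groups = groups)
}

#' Merge tandem-reporting facilities into single observations
#'
#' Facilities that report utilization jointly are collapsed into one
#' observation per group: utilization rows are summed, distance rows and
#' columns are averaged over the members (the members sit at distinct
#' locations, so their distance vectors differ slightly), and the merged
#' observation's self-distance is set to zero. The returned facility table
#' records `member_count` so downstream group-size and single-facility
#' accounting can count underlying facilities, not observations.
#'
#' @param od a [utilization_od()] object.
#' @param dist a [distance_matrix()] over the same facilities.
#' @param groups named list of facility-id vectors to merge; each group's
#'   name becomes the merged observation's id (unnamed groups get the first
#'   member's id).
#' @return A list with merged `od`, `dist` and a `facilities`
#'   [facility_table()].
#' @export
merge_tandem_facilities <- function(od, dist, groups) {
  stopifnot(inherits(od, "utilization_od"), inherits(dist, "distance_matrix"))
  if (!identical(od$facilities, dist$facilities))
    stop("utilization and distance facility orderings differ")
  groups <- as.list(groups)
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("tandem groups overlap: ", paste(unique(members[duplicated(members)]),
                                          collapse = ", "))
  absent <- setdiff(members, od$facilities)
  if (length(absent))
    stop("tandem members not present: ", paste(absent, collapse = ", "))
  if (is.null(names(groups))) names(groups) <- rep("", length(groups))
  names(groups) <- ifelse(names(groups) == "",
                          vapply(groups, `[`, "", 1L), names(groups))

  keep <- setdiff(od$facilities, members)
  new_ids <- sort(c(keep, names(groups)))
  m_counts <- matrix(0, length(new_ids), length(od$units),
                     dimnames = list(new_ids, od$units))
  m_d <- matrix(0, length(new_ids), length(new_ids),
                dimnames = list(new_ids, new_ids))
  member_count <- setNames(rep(1L, length(new_ids)), new_ids)

  # distance columns averaged member-wise first, then rows
  col_of <- function(id) {
    if (id %in% keep) dist$d[, id] else rowMeans(dist$d[, groups[[id]], drop = FALSE])
  }
  cols <- vapply(new_ids, col_of, numeric(length(od$facilities)))
  for (id in new_ids) {
    if (id %in% keep) {
      m_counts[id, ] <- od$counts[id, ]
      m_d[id, ] <- cols[id, ]
    } else {
      g <- groups[[id]]
      m_counts[id, ] <- colSums(od$counts[g, , drop = FALSE])
      m_d[id, ] <- colMeans(cols[g, , drop = FALSE])
      member_count[id] <- length(g)
    }
  }
  m_d <- (m_d + t(m_d)) / 2
  diag(m_d) <- 0
  list(od = utilization_od(m_counts),
       dist = distance_matrix(m_d, tol = 1),
       facilities = facility_table(new_ids, member_count = member_count))
}

#' Remove facilities with no reported patient days
#'
#' Facilities whose utilization row sums to zero cannot produce Commitment
#' Index profiles and are removed before clustering, with a warning naming
#' each. Areal-unit columns that sum to zero are retained: they contribute
#' constant zero CI columns and do not affect clustering.
#'
#' @param od a [utilization_od()] object.
#' @return A list with the filtered `od` and `dropped` (character vector of
#'   removed facility ids, possibly empty).
#' @export
drop_inactive <- function(od) {
  stopifnot(inherits(od, "utilization_od"))
  tot <- rowSums(od$counts)
  dropped <- od$facilities[tot == 0]
  if (length(dropped) == length(od$facilities))
    stop("all facilities have zero patient days")
  for (id in dropped)
    warning(sprintf("facility '%s' has no patient days and was removed", id))
  if (length(dropped))
    od <- utilization_od(od$counts[tot > 0, , drop = FALSE])
  list(od = od, dropped = dropped)
}

# subset a distance matrix to (and order by) the given facility ids
subset_distance <- function(dist, ids) {
  absent <- setdiff(ids, dist$facilities)
  if (length(absent))
    stop("facilities missing from distance matrix: ",
         paste(absent, collapse = ", "))
  distance_matrix(dist$d[ids, ids, drop = FALSE], tol = 1)
}
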