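# The user-facing model interface: fit the whole grouping pipeline in one
# call and interact with the result through standard S3 methods.

#' Fit a hospital-group solution from utilization and distance data
#'
#' Runs the full grouping pipeline: optional tandem-facility merging,
#' removal of facilities with no patient days, Commitment Index profiles,
#' max-rescaled distances, the feature join, a deterministic Ward-seeded
#' K-means sweep over the K grid, the incremental-F candidate search, and
#' the three-step decision-rule selection of the final K. The whole fit is
#' deterministic: the same inputs always produce the same solution.
#'
#' @param od a [utilization_od()] object.
#' @param distances a [distance_matrix()] over the same facilities.
#' @param tandem_groups optional named list of facility-id vectors to
#'   merge as jointly reporting observations (see
#'   [merge_tandem_facilities()]).
#' @param facilities optional [facility_table()]; created automatically
#'   (and updated by merging) when omitted.
#' @param rules a [selection_rules()] object.
#' @param k_range optional `c(k_min, k_max)` override of the swept K grid
#'   (default 2 to n - 1).
#' @param distance_weight optional scalar weight on the distance block
#'   (default 1).
#' @return An object of class `hospital_groups` with components
#'   `solution` (the selected `hg_solution`), `K`, `candidates`,
#'   `selection` (survivors + audit), `sweep` (all per-K solutions),
#'   `incF`, `features`, `facilities`, `dropped`, `d_max` and `call`.
#'   Methods: [print()], [summary()], [plot()], [predict()], [fitted()].
#' @examples
#' region <- generate_region(seed = 42)
#' fit <- hospital_groups(region$od, region$dist)
#' fit
#' table(fitted(fit), region$labels)
#' @export
hospital_groups <- function(od, distances, tandem_groups = NULL,
                            facilities = NULL, rules = selection_rules(),
                            k_range = NULL, distance_weight = 1) {
  stopifnot(inherits(od, "utilization_od"),
            inherits(distances, "distance_matrix"))
  cl <- match.call()
  mismatch <- c(setdiff(od$facilities, distances$facilities),
                setdiff(distances$facilities, od$facilities))
  if (length(mismatch))
    stop("utilization and distance facility sets differ: ",
         paste(unique(mismatch), collapse = ", "))
  distances <- subset_distance(distances, od$facilities)

  if (is.null(facilities)) facilities <- facility_table(od$facilities)
  if (length(tandem_groups)) {
    merged <- merge_tandem_facilities(od, distances, tandem_groups)
    od <- merged$od; distances <- merged$dist; facilities <- merged$facilities
  }

  act <- withCallingHandlers(drop_inactive(od),
                             warning = function(w) {
                               message(conditionMessage(w))
                               invokeRestart("muffleWarning")
                             })
  od <- act$od
  if (length(act$dropped)) {
    distances <- subset_distance(distances, od$facilities)
    facilities <- facilities[facilities$facility_id %in% od$facilities, ]
  }

  ci <- compute_ci(od)
  rs <- rescale_distances(distances)
  feats <- build_features(ci, rs$rescaled, rs$d_max,
                          distance_weight = distance_weight)

  n <- nrow(feats)
  if (is.null(k_range)) k_range <- c(2L, n - 1L)
  sw <- cluster_sweep(feats, k_range[1], k_range[2])
  incf <- incremental_f(sw$r2, n)
  cands <- find_candidates(incf, sw$solutions, facilities)
  sel <- select_k(cands, rules)
  structure(
    list(solution = sw$solutions[[as.character(sel$K)]],
         K = sel$K,
         candidates = cands,
         selection = sel,
         sweep = sw,
         incF = incf,
         features = feats,
         facilities = facilities,
         dropped = act$dropped,
         d_max = rs$d_max,
         rules = rules,
         call = cl),
    class = "hospital_groups")
}

#' @export
print.hospital_groups <- function(x, ...) {
  n <- nrow(x$features)
  z <- sum(attr(x$features, "block") == "utilization")
  cat("Hospital-group solution (Ward-seeded K-means)\n")
  cat(sprintf("  %d facilities x %d areal units (feature matrix %d x %d)\n",
              n, z, n, ncol(x$features)))
  if (length(x$dropped))
    cat(sprintf("  dropped (no patient days): %s\n",
                paste(x$dropped, collapse = ", ")))
  cat(sprintf("  candidates: %d local maxima of incF over K = %d..%d\n",
              nrow(x$candidates), x$sweep$k_range[1], x$sweep$k_range[2]))
  cat(sprintf("  selected K = %d (R2 = %.4f, pseudo-F = %.2f)\n",
              x$K, x$solution$r2, pseudo_f(x$solution$r2, x$K, n)))
  invisible(x)
}

#' @export
summary.hospital_groups <- function(object, ...) {
  n <- nrow(object$features)
  sz <- group_sizes(object$solution$assignments, object$facilities)
  structure(
    list(K = object$K, n = n,
         r2 = object$solution$r2,
         rss = object$solution$rss,
         tss = object$solution$tss,
         pseudo_f = pseudo_f(object$solution$r2, object$K, n),
         group_members = sz$members,
         single_groups = sum(sz$members == 1L),
         candidates = object$candidates,
         survivors = object$selection$survivors,
         audit = object$selection$audit,
         dropped = object$dropped),
    class = "summary.hospital_groups")
}

#' @export
print.summary.hospital_groups <- function(x, ...) {
  cat(sprintf("Selected K = %d groups over %d facilities\n", x$K, x$n))
  cat(sprintf("  R2 = %.4f, pseudo-F = %.2f, single-facility groups = %d, largest group = %d\n",
              x$r2, x$pseudo_f, x$single_groups, max(x$group_members)))
  cat("\nCandidate solutions (local maxima of incF):\n")
  disp <- x$candidates
  disp$incF <- round(disp$incF, 2)
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf("\nSurvivors of the size rule: %s\n",
              paste(x$survivors$step1, collapse = ", ")))
  cat(sprintf("Survivors of the single-group rule: %s\n",
              paste(x$survivors$step2, collapse = ", ")))
  invisible(x)
}

#' @export
fitted.hospital_groups <- function(object, ...) object$solution$assignments

#' @export
coef.hospital_groups <- function(object, ...) object$solution$centers

#' Assign new facilities to a fitted hospital-group solution
#'
#' Places each new facility into the existing group whose center's
#' distance block is nearest (Euclidean) to the facility's rescaled
#' distance vector — geographic assignment only, since a proposed
#' facility has no utilization history.
#'
#' @param object a fitted `hospital_groups` object.
#' @param newdist numeric vector of raw travel distances from the new
#'   facility to every clustered facility (named by facility id or in the
#'   fitted order), or a matrix/data.frame with one row per new facility.
#' @param ... unused.
#' @return For a single vector, a list with `group` and `d` (distances to
#'   every group center); for a matrix, a named integer vector of groups.
#' @export
predict.hospital_groups <- function(object, newdist, ...) {
  block <- attr(object$features, "block")
  w <- attr(object$features, "distance_weight")
  order_ids <- rownames(object$features)
  one <- function(v) {
    h <- build_new_vector(v, object$d_max, order_ids)
    assign_new_facility(object$solution, h, block, distance_weight = w)
  }
  if (is.matrix(newdist) || is.data.frame(newdist)) {
    m <- as.matrix(newdist)
    out <- vapply(seq_len(nrow(m)), function(i) one(m[i, ])$group, 0L)
    names(out) <- rownames(m)
    out
  } else one(newdist)
}

#' Plot the incremental-F profile of a fitted solution
#'
#' incF against K, with candidate solutions (strict local maxima) marked
#' and the selected K highlighted.
#'
#' @param x a fitted `hospital_groups` object.
#' @param ... further arguments passed to [plot()].
#' @export
plot.hospital_groups <- function(x, ...) {
  ks <- as.integer(names(x$incF))
  plot(ks, x$incF, type = "l", xlab = "Number of groups (K)",
       ylab = "Incremental F", ...)
  points(x$candidates$clusters, x$candidates$incF, pch = 19, col = "red")
  abline(v = x$K, lty = 2)
  legend("topright", bty = "n",
         legend = c("candidate (local max)", sprintf("selected K = %d", x$K)),
         pch = c(19, NA), lty = c(NA, 2), col = c("red", "black"))
  invisible(x)
}
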