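# Fixtures are built in code; no data files.

# small OD object from a bare matrix
toy_od <- function(counts, facilities = NULL, units = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- facilities %||% sprintf("F%02d", seq_len(nrow(counts)))
  colnames(counts) <- units %||% sprintf("U%02d", seq_len(ncol(counts)))
  utilization_od(counts)
}

toy_dist <- function(d, facilities = NULL) {
  d <- as.matrix(d)
  ids <- facilities %||% sprintf("F%02d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  distance_matrix(d)
}

random_od <- function(n, z, seed, lambda = 40) {
  set.seed(seed)
  m <- matrix(rpois(n * z, lambda), n, z)
  toy_od(m)
}

# well-separated point clouds as a plain feature matrix
clouds <- function(sizes, centers, sd = 0.05, seed = 1) {
  set.seed(seed)
  p <- length(centers[[1]])
  x <- do.call(rbind, lapply(seq_along(sizes), function(k) {
    sweep(matrix(rnorm(sizes[k] * p, 0, sd), sizes[k], p),
          2, centers[[k]], "+")
  }))
  rownames(x) <- sprintf("F%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  x
}

cloud_labels <- function(sizes) rep(seq_along(sizes), sizes)

# exhaustive minimum SSE over all assignments of n points to K non-empty
# groups (independent oracle; never calls the clustering code)
brute_min_sse <- function(x, K) {
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    if (length(unique(g)) < K) next
    sse <- 0
    for (k in seq_len(K)) {
      xi <- x[g == k, , drop = FALSE]
      sse <- sse + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    if (sse < best) best <- sse
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
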