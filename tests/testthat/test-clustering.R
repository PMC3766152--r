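test_that("fit statistics match a hand computation and the degenerate cases", {
  # 4 points on a line, partition {1,2},{3,4}
  x <- matrix(c(0, 1, 10, 13), ncol = 1,
              dimnames = list(sprintf("F%02d", 1:4), "V1"))
  fs <- fit_stats(x, setNames(c(1, 1, 2, 2), rownames(x)))
  expect_equal(fs$rss, 0.5 + 4.5)  # within-group: (0,1) -> 0.5; (10,13) -> 4.5
  grand <- mean(x)
  expect_equal(fs$tss, sum((x - grand)^2))

  one <- fit_stats(x, setNames(rep(1, 4), rownames(x)))
  expect_equal(one$r2, 0)
  singles <- fit_stats(x, setNames(1:4, rownames(x)))
  expect_equal(singles$r2, 1)

  expect_error(fit_stats(x, setNames(c(1, 1, 2, 2), c("F01", "F02", "F03", "XX"))),
               "unknown")
})

test_that("Ward partitioning recovers separated structure and the exhaustive optimum", {
  x <- clouds(c(3, 3), list(c(0, 0), c(5, 5)), sd = 0.1, seed = 31)
  sol <- ward_partition(x, 2)
  expect_equal(unname(vapply(split(names(sol$assignments), sol$assignments),
                             length, 0L)), c(3, 3))
  expect_identical(sol$assignments[1] == sol$assignments[2], c(F01 = TRUE))

  # n = 6 in 2-D: ward cut at 2 equals the exhaustive minimum-SSE bipartition
  expect_equal(sol$rss, brute_min_sse(x, 2), tolerance = 1e-10)

  expect_equal(ward_partition(x, nrow(x))$rss, 0)
  expect_error(ward_partition(x, 0), "out of range")
  expect_error(ward_partition(x, 7), "out of range")
})

test_that("K-means refinement descends and fixes points at a local optimum", {
  x <- clouds(c(4, 4, 4), list(c(0, 0), c(4, 0), c(0, 4)), sd = 0.2, seed = 32)
  seed_sol <- ward_partition(x, 3)
  ref <- kmeans_refine(x, seed_sol$centers)
  expect_lte(ref$rss, seed_sol$rss + 1e-12)
  # refining from an optimum is a fixed point
  again <- kmeans_refine(x, ref$centers)
  expect_identical(again$assignments, ref$assignments)
  expect_equal(again$rss, ref$rss, tolerance = 1e-12)

  # descent from arbitrary seeds too
  set.seed(33)
  for (r in 1:5) {
    centers <- x[sample(nrow(x), 3), ]
    start_fs <- fit_stats(x, setNames(
      max.col(-as.matrix(dist(rbind(centers, x)))[-(1:3), 1:3]),
      rownames(x)))
    expect_lte(kmeans_refine(x, centers)$rss, start_fs$rss + 1e-12)
  }
})

test_that("refined solutions reach the exhaustive minimum SSE on small fixtures", {
  x <- clouds(c(3, 3, 2), list(c(0, 0), c(3, 0), c(1.5, 3)), sd = 0.15, seed = 34)
  ref <- kmeans_refine(x, ward_partition(x, 3)$centers)
  expect_equal(ref$rss, brute_min_sse(x, 3), tolerance = 1e-10)
})

test_that("refinement agrees with an independent Lloyd implementation", {
  x <- clouds(c(5, 5, 5), list(c(0, 0), c(2, 2), c(4, 0)), sd = 0.4, seed = 35)
  seed_centers <- ward_partition(x, 3)$centers
  ours <- kmeans_refine(x, seed_centers)
  ref <- stats::kmeans(x, centers = seed_centers, algorithm = "Lloyd",
                       iter.max = 1000)
  expect_equal(ours$rss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("an emptied cluster is re-seeded so K is preserved", {
  x <- clouds(c(5, 5), list(c(0, 0), c(10, 10)), sd = 0.1, seed = 36)
  # third seed far from all data: its cluster empties on first assignment
  centers <- rbind(colMeans(x[1:5, ]), colMeans(x[6:10, ]), c(100, 100))
  sol <- kmeans_refine(x, centers)
  expect_equal(sol$K, 3)
  expect_equal(length(unique(sol$assignments)), 3)
  expect_gt(sol$meta$empty_cluster_repairs, 0)
})

test_that("the sweep covers the K grid with the K = 1 reference and sane R2", {
  x <- clouds(c(4, 3, 3), list(c(0, 0), c(4, 0), c(0, 4)), sd = 0.3, seed = 37)
  sw <- cluster_sweep(x)
  expect_identical(names(sw$solutions), as.character(c(1, 2:9)))
  expect_equal(sw$r2[["1"]], 0)
  expect_true(all(diff(sw$r2) >= -1e-9))  # non-decreasing in K
  expect_true(all(sw$r2 >= 0 & sw$r2 <= 1))
  # K = n - 1 has exactly one doubleton
  sizes <- table(sw$solutions[["9"]]$assignments)
  expect_equal(sort(unname(as.vector(sizes))), c(rep(1, 8), 2))

  expect_error(cluster_sweep(x[1:2, ]), "at least 3")
  expect_error(cluster_sweep(x, k_min = 1), "invalid K range")
})

test_that("two runs on the same input are byte-identical end to end", {
  region <- generate_region(seed = 99)
  run <- function() {
    fit <- hospital_groups(region$od, region$dist)
    p <- withr::local_tempfile(fileext = ".csv")
    write_solution(fit$solution, p)
    tools::md5sum(c(p, sub("\\.csv$", ".json", p)))
  }
  expect_identical(unname(run()), unname(run()))
})

test_that("Ward seeding beats or ties the best of many random starts", {
  wins <- 0L
  n_fix <- 10L
  for (s in seq_len(n_fix)) {
    region <- generate_region(seed = 500 + s)
    ci <- compute_ci(region$od)
    r <- rescale_distances(region$dist)
    f <- build_features(ci, r$rescaled, r$d_max)
    ex <- random_start_experiment(f, K = 5, runs = 100, seed = 1000 + s)
    if (ex$seeded_rss <= min(ex$random_rss) + 1e-9) wins <- wins + 1L
  }
  expect_gte(wins / n_fix, 0.9)
})

test_that("the random-start experiment is reproducible and degenerate at K = n", {
  x <- clouds(c(3, 3), list(c(0, 0), c(3, 3)), sd = 0.2, seed = 38)
  a <- random_start_experiment(x, K = 2, runs = 3, seed = 7)
  b <- random_start_experiment(x, K = 2, runs = 3, seed = 7)
  expect_identical(a, b)
  full <- random_start_experiment(x, K = nrow(x), runs = 2, seed = 8)
  expect_equal(full$random_rss, c(0, 0), tolerance = 1e-12)
  expect_error(random_start_experiment(x, 2, 3), "seed")
})
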