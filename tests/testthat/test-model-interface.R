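test_that("the fitted model object carries the full pipeline state", {
  region <- generate_region(seed = 42)
  fit <- hospital_groups(region$od, region$dist)

  expect_s3_class(fit, "hospital_groups")
  expect_equal(fit$K, fit$solution$K)
  expect_setequal(names(fitted(fit)), region$od$facilities)
  expect_equal(dim(coef(fit)), c(fit$K, ncol(fit$features)))
  # centers equal the group means of the selected partition
  g <- fitted(fit)
  for (k in seq_len(fit$K))
    expect_equal(unname(coef(fit)[k, ]),
                 unname(colMeans(fit$features[g == k, , drop = FALSE])),
                 tolerance = 1e-9)
  # rss consistent with an independent recomputation
  fs <- fit_stats(fit$features, g)
  expect_equal(fit$solution$rss, fs$rss, tolerance = 1e-9)

  expect_output(print(fit), "selected K = 5")
  s <- summary(fit)
  expect_output(print(s), "Candidate solutions")
  expect_equal(s$K, 5)
  expect_equal(sum(s$group_members), nrow(fit$features))
})

test_that("facility sets must agree between utilization and distances", {
  region <- generate_region(seed = 8)
  d <- region$dist$d[-1, -1]
  expect_error(hospital_groups(region$od, distance_matrix(d)), "H001")
})

test_that("tandem merging and inactive removal flow through the fit", {
  region <- generate_region(seed = 21)
  counts <- region$od$counts
  counts["H002", ] <- 0  # silence one facility
  od <- utilization_od(counts)
  expect_message(
    fit <- hospital_groups(od, region$dist,
                           tandem_groups = list(H014_15 = c("H014", "H015"))),
    "H002")
  expect_identical(fit$dropped, "H002")
  ids <- names(fitted(fit))
  expect_false("H002" %in% ids)
  expect_true("H014_15" %in% ids)
  expect_false("H014" %in% ids)
  expect_equal(
    fit$facilities$member_count[fit$facilities$facility_id == "H014_15"], 2L)
})

test_that("the CLI subcommands mirror the library results", {
  dir <- withr::local_tempdir()
  expect_equal(hg_cli(c("simulate", "--seed", "42", "--out-dir",
                        file.path(dir, "sim"))), 0L)
  expect_true(file.exists(file.path(dir, "sim", "od.csv")))

  expect_equal(hg_cli(c("cluster", "--od", file.path(dir, "sim", "od.csv"),
                        "--dist", file.path(dir, "sim", "distances.csv"),
                        "--out-dir", file.path(dir, "run"))), 0L)
  membership <- read_solution(file.path(dir, "run", "membership.csv"))
  region <- generate_region(seed = 42)
  fit <- hospital_groups(region$od, region$dist)
  expect_equal(membership, fitted(fit))

  manifest <- jsonlite::read_json(file.path(dir, "run", "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$K, fit$K)
  expect_equal(manifest$d_max, fit$d_max, tolerance = 1e-9)

  # assignment through the CLI equals the library path
  target <- "H007"
  dist_file <- file.path(dir, "new.csv")
  write.csv(data.frame(facility_id = region$od$facilities,
                       distance = region$dist$d[target, ]),
            dist_file, row.names = FALSE)
  out <- capture.output(
    status <- hg_cli(c("assign",
                       "--centers", file.path(dir, "run", "centers_distance_block.csv"),
                       "--manifest", file.path(dir, "run", "manifest.json"),
                       "--distances", dist_file)))
  expect_equal(status, 0L)
  lib_group <- predict(fit, region$dist$d[target, ])$group
  expect_match(out[1], sprintf("assigned group: %d", lib_group))

  # evaluate: a solution against itself is 100% agreement
  out2 <- capture.output(
    status2 <- hg_cli(c("evaluate",
                        "--solution-a", file.path(dir, "run", "membership.csv"),
                        "--solution-b", file.path(dir, "run", "membership.csv"))))
  expect_equal(status2, 0L)
  expect_match(paste(out2, collapse = " "), "100.00%")

  # missing inputs exit with the input-error status
  expect_equal(suppressMessages(
    hg_cli(c("cluster", "--od", "absent.csv", "--dist", "absent.csv",
             "--out-dir", dir))), 2L)
  # selection failure exits with its own status
  cand_file <- file.path(dir, "cand.csv")
  write_candidates(michigan_candidates(), cand_file)
  expect_equal(suppressMessages(
    hg_cli(c("select", "--candidates", cand_file, "--max-group-size", "2"))), 3L)
  out3 <- capture.output(
    status3 <- hg_cli(c("select", "--candidates", cand_file)))
  expect_equal(status3, 0L)
  expect_match(out3[1], "selected K = 33")
})
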