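test_that("incremental F matches direct formula evaluation", {
  # n = 100, R2 0.90 -> 0.92 between K = 10 and 11
  r2 <- setNames(c(0, rep(NA, 10)), 1:11)
  r2[2:11] <- seq(0.5, 0.92, length.out = 10)
  r2[["10"]] <- 0.90; r2[["11"]] <- 0.92
  incf <- incremental_f(r2, n = 100)
  expect_equal(incf[["11"]], (0.02 / 1) / (0.08 / (100 - 10)))
  expect_equal(incf[["11"]], 22.5)

  # K = 2 uses the K = 1 reference
  r2b <- setNames(c(0, 0.5, 0.6), 1:3)
  expect_equal(incremental_f(r2b, n = 50)[["2"]], 0.5 / (0.5 / 49))
  expect_equal(incremental_f(r2b, n = 50)[["2"]], 49)

  # unchanged fit gives incF = 0
  r2c <- setNames(c(0, 0.4, 0.4), 1:3)
  expect_equal(incremental_f(r2c, n = 10)[["3"]], 0)

  # perfect fit is undefined, flagged as NA
  r2d <- setNames(c(0, 0.5, 1), 1:3)
  expect_true(is.na(incremental_f(r2d, n = 10)[["3"]]))

  expect_error(incremental_f(setNames(c(0, 0.5), c(1, 3)), 10), "consecutive")
  expect_error(incremental_f(setNames(c(0.1, 0.5), c(1, 2)), 10), "r2 = 0")
  expect_error(incremental_f(setNames(c(0, 0.5, 0.6), 1:3), 3), "exceed")
})

make_sols <- function(sizes_by_k) {
  # minimal hg_solution stand-ins for candidate annotation
  out <- lapply(names(sizes_by_k), function(K) {
    sizes <- sizes_by_k[[K]]
    g <- rep(seq_along(sizes), sizes)
    names(g) <- sprintf("F%02d", seq_along(g))
    structure(list(K = length(sizes), assignments = g), class = "hg_solution")
  })
  names(out) <- names(sizes_by_k)
  out
}

test_that("candidates are strict local maxima with size annotations", {
  incf <- setNames(c(1, 3, 2, 5, 4), 2:6)
  sols <- make_sols(list(`3` = c(3, 2, 1), `5` = c(2, 1, 1, 1, 1)))
  cand <- find_candidates(incf, sols)
  expect_equal(cand$clusters, c(3L, 5L))
  expect_equal(cand$incF, c(3, 5))
  expect_equal(cand$SH, c(1L, 4L))
  expect_equal(cand$Max, c(3L, 2L))

  mono <- setNames(1:5, 2:6)
  expect_equal(nrow(find_candidates(mono, sols)), 0)

  plateau <- setNames(c(1, 3, 3, 1), 2:5)
  expect_equal(nrow(find_candidates(plateau, sols)), 0)

  expect_error(find_candidates(setNames(c(1, 2), 2:3), sols), "3 grid points")
})

test_that("merged observations count members toward Max and never toward SH", {
  incf <- setNames(c(1, 5, 2), 2:4)
  g <- setNames(c(1, 2, 3), c("AB", "C", "D"))
  sols <- list(`3` = structure(list(K = 3, assignments = g),
                               class = "hg_solution"))
  fac <- facility_table(c("AB", "C", "D"), member_count = c(2L, 1L, 1L))
  cand <- find_candidates(incf, sols, fac)
  expect_equal(cand$SH, 2L)   # AB alone is not a single facility
  expect_equal(cand$Max, 2L)  # AB's group holds 2 underlying facilities
})

test_that("the three-step heuristic reproduces the statewide walk-through", {
  cand <- michigan_candidates()
  expect_equal(nrow(cand), 52)
  expect_equal(cand$incF[cand$clusters == 33], 4.11)
  expect_equal(cand$Max[cand$clusters == 27], 24L)

  sel <- select_k(cand, selection_rules(max_group_size = 20))
  expect_equal(sel$K, 33)
  expect_equal(min(sel$survivors$step1), 29)
  expect_equal(sel$survivors$step2, c(29L, 31L, 33L))
  surv_sh <- cand$SH[cand$clusters %in% sel$survivors$step1]
  expect_equal(min(surv_sh), 1L)
  # every elimination is audited
  expect_setequal(c(sel$audit$clusters, sel$K), cand$clusters)
})

test_that("selection is order-invariant and monotone in max_group_size", {
  cand <- michigan_candidates()
  shuffled <- cand[sample(nrow(cand)), ]
  expect_equal(select_k(shuffled)$K, select_k(cand)$K)

  s20 <- select_k(cand, selection_rules(20))$survivors$step1
  s30 <- select_k(cand, selection_rules(30))$survivors$step1
  expect_true(all(s20 %in% s30))

  expect_error(select_k(cand, selection_rules(2)), "relaxing")
  expect_error(select_k(cand[0, ]), "no candidate")
})

test_that("candidate tables round-trip through the display format", {
  cand <- michigan_candidates()
  p <- withr::local_tempfile(fileext = ".csv")
  write_candidates(cand, p)
  back <- read_candidates(p)
  expect_equal(back$clusters, cand$clusters)
  expect_equal(back$incF, cand$incF)  # 2 dp already in the source table
  expect_match(readLines(p)[2], "^3,94.81,0,91$")
})
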