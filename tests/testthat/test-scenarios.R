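test_that("the 80-80-80 cascade product gives 51% effective coverage", {
  expect_equal(effective_coverage(0.8, 0.8, 0.8), 0.512)
  expect_equal(round(100 * effective_coverage()), 51)
  expect_error(effective_coverage(1.2, 0.8, 0.8), "0, 1")
})

test_that("scale-up increments vanish at the ceiling and peak at its half", {
  prog <- scale_up_curve("progress")
  asp <- scale_up_curve("aspirational")
  grid <- seq(0, 1, by = 1e-4)
  inc_p <- curve_increment(prog, grid)
  inc_a <- curve_increment(asp, grid)
  expect_equal(max(inc_p), 0.03, tolerance = 1e-12)
  expect_equal(max(inc_a), 0.04, tolerance = 1e-12)
  expect_equal(grid[which.max(inc_p)], 0.53 / 2)
  expect_equal(curve_increment(prog, 0.53), 0)
  expect_equal(curve_increment(asp, 0.75), 0)
  expect_true(all(inc_p[grid >= 0.53] == 0))
  # aspirational stays strictly below the antiretroviral 5%/yr bound
  expect_lt(max(inc_a), 0.05)
})

test_that("the bau family is scored by squared error with a low-peak tie-break", {
  fam <- bau_curve_family()
  expect_length(fam, 9)
  expect_equal(purrr::map_dbl(fam, "ceiling"), seq(0.25, 0.65, length.out = 9))
  # exact member recovery for a noiseless trajectory
  target <- coverage_trajectory(fam[[4]], 0.05, 2010, 2019,
                                intervention_start = 2010)$control
  fit <- fit_bau_curve(target)
  expect_identical(attr(fit, "member"), 4L)
  # argmin contract: selected error is minimal over the family
  sse <- purrr::map_dbl(fam, function(cv) {
    c_hat <- Reduce(function(c, .) min(cv$ceiling, c + curve_increment(cv, c)),
                    seq_len(9), accumulate = TRUE, init = target[1])
    sum((c_hat - target)^2)
  })
  expect_equal(attr(fit, "sse"), min(sse))
  # identical-error tie (flat history matched by every curve at ceiling):
  # lower-ceiling member wins
  expect_warning(flatfit <- fit_bau_curve(rep(0, 10)), "flat-zero")
  expect_identical(attr(flatfit, "member"), 1L)
  expect_error(fit_bau_curve(c(0.1, 0.2)), "at least 5")
})

test_that("coverage holds flat through 2022 and then climbs to the ceiling", {
  prog <- scale_up_curve("progress")
  tr <- coverage_trajectory(prog, 0.2, 2019, 2060)
  expect_equal(tr$control[tr$year %in% 2019:2022], rep(0.2, 4))
  expect_true(all(diff(tr$control) >= 0))
  expect_true(all(tr$control <= 0.53 + 1e-12))
  expect_true(all(diff(tr$control) <= 0.03 + 1e-12))
  asp <- coverage_trajectory(scale_up_curve("aspirational"), 0.2, 2019, 2120)
  expect_equal(tail(asp$control, 1), 0.75, tolerance = 1e-6)
  # start at ceiling: constant series
  at_ceiling <- coverage_trajectory(prog, 0.53, 2019, 2030)
  expect_equal(at_ceiling$control, rep(0.53, 12))
  expect_warning(over <- coverage_trajectory(prog, 0.6, 2019, 2030), "flat")
  expect_equal(over$control, rep(0.6, 12))
})

test_that("sodium schedules hit their defining reductions and the floor", {
  prog <- sodium_trajectory(sodium_schedule("progress"), 4)
  expect_equal(prog$intake[prog$year == 2023], 4)
  expect_equal(prog$intake[prog$year == 2030], 3.4)
  expect_equal(prog$intake[prog$year == 2050], 3.4)
  asp <- sodium_trajectory(sodium_schedule("aspirational"), 4)
  expect_equal(asp$intake[asp$year == 2027], 2.8)
  bau <- sodium_trajectory(sodium_schedule("bau"), 4)
  expect_equal(bau$intake, rep(4, nrow(bau)))
  # floor: 2.2 * 0.7 = 1.54 would breach 2 g/day
  floored <- sodium_trajectory(sodium_schedule("aspirational"), 2.2)
  expect_equal(min(floored$intake), 2)
  expect_true(all(diff(floored$intake) <= 0))
  expect_error(sodium_trajectory(sodium_schedule("bau"), 0), "positive")
})

test_that("target-achievement year scans the control series against 0.512", {
  tr <- tibble::tibble(year = 2020:2026,
                       control = c(0.40, 0.47, 0.50, 0.52, 0.55, 0.60, 0.65))
  expect_identical(year_target_achieved(tr), 2023L)
  already <- tibble::tibble(year = 2020:2022, control = c(0.6, 0.6, 0.6))
  expect_identical(year_target_achieved(already), 2020L)
  capped <- tibble::tibble(year = 2020:2060, control = 0.5)
  expect_identical(year_target_achieved(capped), NA_integer_)
  expect_error(year_target_achieved(tibble::tibble()), "non-empty")
})

test_that("scenario trajectories dominate pointwise from identical starts", {
  for (start in c(0.05, 0.2, 0.4)) {
    bau <- coverage_trajectory(scale_up_curve("bau"), start)
    prog <- coverage_trajectory(scale_up_curve("progress"), start)
    asp <- coverage_trajectory(scale_up_curve("aspirational"), start)
    expect_true(all(prog$control >= bau$control - 1e-12))
    expect_true(all(asp$control >= prog$control - 1e-12))
    ys <- c(bau = year_target_achieved(bau), prog = year_target_achieved(prog),
            asp = year_target_achieved(asp))
    ys[is.na(ys)] <- 9999L
    expect_true(ys["asp"] <= ys["prog"] && ys["prog"] <= ys["bau"])
  }
})
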