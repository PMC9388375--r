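test_that("the sick-state update follows the four-state arithmetic", {
  # 100 * (1 - 0.15) + 1000 * 0.01 = 95
  expect_equal(step_sick(100, 1000, ir = 0.01, cf = 0.10, bg = 0.05), 95)
  expect_equal(step_sick(42, 1000, ir = 0, cf = 0, bg = 0), 42)
  # empty well pool: pure decay by the competing risks
  expect_equal(step_sick(200, 0, ir = 0.5, cf = 0.2, bg = 0.1), 200 * 0.7)
  expect_error(step_sick(1, 1, ir = 0, cf = 0.7, bg = 0.5), "exceed 1")
})

test_that("cause deaths are the sick pool times case fatality", {
  expect_equal(step_deaths(100, 0.10), 10)
  expect_equal(step_deaths(100, 0), 0)
  expect_equal(step_deaths(100, 1), 100)
})

test_that("the envelope reconciliation implements the population update", {
  # pop = 1000, cause deaths 20, BG = 0.01: all-cause = 30
  out <- reconcile_envelope(pop = 1000, cause_deaths = matrix(20, 1, 1),
                            bg = 0.01, sick = matrix(50, 1, 1))
  expect_equal(out$all_cause_deaths, 30)
  expect_equal(out$pop_next, 970)
  expect_equal(out$well[1, 1], 1000 - 30 - 50)
  # zero deaths: population constant, well = pop - sick
  out0 <- reconcile_envelope(pop = c(500, 600),
                             cause_deaths = matrix(0, 2, 4), bg = c(0, 0),
                             sick = matrix(10, 2, 4))
  expect_equal(out0$pop_next, c(500, 600))
  expect_true(all(out0$well == c(490, 590)))
  expect_error(
    reconcile_envelope(pop = 100, cause_deaths = matrix(60, 1, 1),
                       bg = 0.3, sick = matrix(50, 1, 1)),
    "inconsistent")
})

test_that("summed model deaths match the all-cause envelope every year", {
  set.seed(11)
  n <- 10
  pop <- runif(n, 1e3, 1e5)
  sick <- matrix(runif(n * 4, 0, 0.1), n, 4) * pop
  cf <- matrix(runif(n * 4, 0.02, 0.2), n, 4)
  bg <- runif(n, 0.001, 0.05)
  deaths <- sick * cf
  out <- reconcile_envelope(pop, deaths, bg, sick)
  expect_equal(out$all_cause_deaths, rowSums(deaths) + pop * bg,
               tolerance = 1e-12)
  expect_equal(sum(pop) - sum(out$pop_next), sum(out$all_cause_deaths),
               tolerance = 1e-9)
})

test_that("flat histories yield transitions with no trend", {
  p <- 0.05; cf <- 0.1
  # stationarity requires incidence replacing deaths and attrition
  hist <- fixture_disease_history(ir = 0, cf = cf, bg = 0, p0 = p)
  # build an exactly flat series instead: prevalence constant, bg 0
  flat <- tibble::tibble(year = 2014:2019, prevalence = p,
                         mortality = p * cf, bg = 1e-8)
  tr <- estimate_transitions(flat)
  expect_equal(tr$cf_trend, 0, tolerance = 1e-6)
  expect_equal(tr$cf, cf, tolerance = 1e-3)
  # forward run from the estimate reproduces the flat series
  sim <- sim_disease(1, p, tr$ir, tr$cf, tr$bg, 5,
                     cf_trend = tr$cf_trend)
  expect_equal(sim$prevalence, rep(p, 5), tolerance = 1e-2)
})

test_that("transitions estimated from a known model reproduce its series", {
  true <- list(ir = 0.004, cf = 0.12, bg = 0.02)
  hist <- fixture_disease_history(true$ir, true$cf, true$bg, p0 = 0.03,
                                  n_years = 6)
  tr <- estimate_transitions(hist)
  expect_equal(tr$ir, true$ir, tolerance = 1e-6)
  expect_equal(tr$cf, true$cf, tolerance = 1e-6)
  expect_equal(tr$cf_trend, 0, tolerance = 1e-6)
  sim <- sim_disease(1, 0.03, tr$ir, tr$cf, tr$bg, 5)
  expect_equal(tail(sim$prevalence, 1), tail(hist$prevalence, 1),
               tolerance = 0.01)
  expect_equal(tail(sim$mortality, 1), tail(hist$mortality, 1),
               tolerance = 0.01)
})

test_that("an exponential mortality decline is recovered as a CF trend", {
  hist <- fixture_disease_history(0.004, 0.12, 0.02, p0 = 0.03, n_years = 10,
                                  cf_trend = log(0.98))
  tr <- estimate_transitions(hist)
  expect_equal(tr$cf_trend, log(0.98), tolerance = 1e-4)
  expect_error(estimate_transitions(dplyr::mutate(hist, prevalence = 0)),
               "positive")
})

test_that("case-fatality projection extrapolates the geometric trend", {
  cf0 <- 0.2
  series <- cf0 * 0.98^(0:9)
  proj <- project_cf_trend(series, 5)
  expect_equal(proj, tail(series, 1) * 0.98^(1:5), tolerance = 1e-12)
  expect_equal(project_cf_trend(rep(0.1, 8), 3), rep(0.1, 3))
  # growth clipped at 1
  expect_true(all(project_cf_trend(c(0.5, 0.9), 10) <= 1))
  expect_error(project_cf_trend(c(0.1, 0), 3), "positive")
})

test_that("calibration returns unit factors for self-generated targets", {
  hist <- fixture_disease_history(0.004, 0.12, 0.02, p0 = 0.03) |>
    dplyr::mutate(cause = "ihd", .before = 1)
  tr <- estimate_transitions(hist)
  cal <- calibrate_transitions(tr, hist, weight_mort = 0.75)
  expect_equal(cal$factor_ir, 1, tolerance = 1e-3)
  expect_equal(cal$factor_cf, 1, tolerance = 1e-3)
  expect_lte(cal$objective, cal$objective_unadjusted + 1e-12)
})

test_that("calibration recovers an injected 1.5x case-fatality scaling", {
  target <- fixture_disease_history(0.004, 0.12 * 1.5, 0.02, p0 = 0.03) |>
    dplyr::mutate(cause = "ihd", .before = 1)
  # transitions believed before calibration: unscaled CF
  believed <- estimate_transitions(
    fixture_disease_history(0.004, 0.12, 0.02, p0 = 0.03) |>
      dplyr::mutate(cause = "ihd", .before = 1))
  cal <- calibrate_transitions(believed, target, weight_mort = 0.75)
  expect_equal(cal$factor_cf, 1.5, tolerance = 0.05)
  expect_true(cal$converged)
  tidied <- tidy(cal)
  expect_true(all(c("parameter", "estimate") %in% names(tidied)))
  expect_equal(nrow(glance(cal)), 1)
})

test_that("mortality-weight bounds reflect the greater trust in death data", {
  hist <- fixture_disease_history(0.004, 0.12, 0.02) |>
    dplyr::mutate(cause = "ihd", .before = 1)
  tr <- estimate_transitions(hist)
  expect_error(calibrate_transitions(tr, hist, weight_mort = 0.4), "weight")
  expect_error(calibrate_transitions(tr, hist, weight_mort = 1), "weight")
})

test_that("state occupancies stay non-negative and respond monotonically", {
  set.seed(21)
  for (rep in 1:20) {
    ir <- runif(1, 0, 0.2); cf <- runif(1, 0, 0.5); bg <- runif(1, 0, 0.4)
    sim <- sim_disease(1, runif(1, 0, 0.3), ir, cf, min(bg, 1 - cf), 15)
    expect_true(all(sim$sick >= 0 & sim$well >= 0 & sim$deaths >= 0))
  }
  base <- sim_disease(1, 0.05, 0.01, 0.1, 0.02, 10)
  more_ir <- sim_disease(1, 0.05, 0.02, 0.1, 0.02, 10)
  expect_true(all(more_ir$prevalence >= base$prevalence - 1e-12))
  more_cf <- sim_disease(1, 0.05, 0.01, 0.15, 0.02, 10)
  expect_true(all(more_cf$deaths[1] >= base$deaths[1] - 1e-12))
})
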