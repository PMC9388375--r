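test_that("SBP distributions recover sd from the 5th percentile", {
  d <- build_sbp_distribution(120, 96)
  expect_equal(d$sd, 24 / qnorm(0.95), tolerance = 1e-6)
  expect_equal(d$sd, 14.59, tolerance = 0.01)
  # normal-CDF oracle for the raised-BP tail
  # discretization of the tail onto the 0.5-mmHg grid is a few percent
  expect_equal(sbp_prop_above(d, 140), 1 - pnorm((140 - 120) / d$sd),
               tolerance = 0.05)
  expect_equal(sbp_prop_above(d, 140), 0.085, tolerance = 0.05)
  expect_equal(sum(sbp_category_mass(d)$mass), 1, tolerance = 1e-9)
  expect_equal(sbp_mean(d), 120, tolerance = 1e-3)
  expect_error(build_sbp_distribution(96, 120), "exceed")
})

test_that("the standardized risk parameter is the mass-weighted relative risk", {
  expect_equal(standardized_alpha(c(1, 0), c(1, 2)), 1)
  expect_equal(standardized_alpha(c(0.5, 0.5), c(1, 2)), 1.5)
  # convex combination bounds
  set.seed(3)
  for (i in 1:10) {
    p <- runif(5); p <- p / sum(p)
    rr <- sort(runif(5, 1, 4))
    a <- standardized_alpha(p, rr)
    expect_gte(a, min(rr)); expect_lte(a, max(rr))
  }
  expect_error(standardized_alpha(c(0.5, 0.2), c(1, 2)), "sum to 1")
  expect_error(standardized_alpha(c(0.5, 0.5), c(1, 2, 3)), "length")
})

test_that("category incidence preserves the average under baseline weights", {
  y <- 0.01; rr <- c(1, 2); p <- c(0.5, 0.5)
  a <- standardized_alpha(p, rr)
  yi <- category_incidence(y, rr, a)
  expect_equal(yi, c(0.0066667, 0.0133333), tolerance = 1e-4)
  expect_equal(sum(p * yi), y, tolerance = 1e-12)
  expect_equal(category_incidence(y, c(1, 1, 1), 1), rep(y, 3))
  expect_error(category_incidence(y, rr, 0), "positive")
})

test_that("intervention incidence reweights by the shifted masses", {
  y <- 0.01; rr <- c(1, 2); p <- c(0.5, 0.5)
  yi <- category_incidence(y, rr, standardized_alpha(p, rr))
  expect_equal(intervention_incidence(p, yi), y, tolerance = 1e-12)
  expect_equal(intervention_incidence(c(1, 0), yi), yi[1])
  # any leftward shift with nondecreasing RR lowers incidence
  set.seed(9)
  for (i in 1:10) {
    move <- runif(1, 0, 0.5)
    p_star <- c(p[1] + move, p[2] - move)
    expect_lte(intervention_incidence(p_star, yi), y + 1e-12)
  }
})

test_that("sodium shifts move the two segments by their slope times dose", {
  d <- build_sbp_distribution(135, 100)
  raised <- d$x >= 140
  mean_raised <- sum(d$x[raised] * d$mass[raised]) / sum(d$mass[raised])
  mean_normal <- sum(d$x[!raised] * d$mass[!raised]) / sum(d$mass[!raised])
  s <- apply_sodium_shift(d, 1)
  # the point masses that made up each segment moved by exactly the slope
  expect_equal(sum(s$x[raised] * s$mass[raised]) / sum(s$mass[raised]),
               mean_raised - 1.12, tolerance = 1e-12)
  expect_equal(sum(s$x[!raised] * s$mass[!raised]) / sum(s$mass[!raised]),
               mean_normal - 0.58, tolerance = 1e-12)
  expect_equal(sum(s$mass), sum(d$mass), tolerance = 1e-12)
  expect_identical(apply_sodium_shift(d, 0), d)
  expect_error(apply_sodium_shift(d, -1), "non-negative")
})

test_that("treatment shifts relocate controlled mass below the threshold", {
  d <- build_sbp_distribution(135, 100)
  above0 <- sbp_prop_above(d, 140)
  expect_identical(apply_treatment_shift(d, 0), d)
  full <- apply_treatment_shift(d, 1)
  expect_equal(sbp_prop_above(full, 140), 0, tolerance = 1e-12)
  expect_equal(sum(full$mass), 1, tolerance = 1e-9)
  # relocated mass lands in the goal category
  goal_bin <- sum(full$mass[full$x >= 125 & full$x < 135]) -
    sum(d$mass[d$x >= 125 & d$x < 135])
  expect_equal(goal_bin, above0, tolerance = 1e-9)
  # mass conservation under random fractions
  set.seed(5)
  for (i in 1:20) {
    f <- runif(1)
    s <- apply_treatment_shift(d, f)
    expect_equal(sum(s$mass), 1, tolerance = 1e-9)
    expect_equal(sbp_prop_above(s, 140), above0 * (1 - f), tolerance = 1e-9)
  }
  expect_error(apply_treatment_shift(d, 0.5, goal = 150), "below")
})

test_that("deeper control strictly lowers incidence while risk remains", {
  d <- build_sbp_distribution(138, 100)
  rr <- default_risk_table()
  rr_ihd <- rr$rr[rr$cause == "ihd"]
  p <- sbp_category_mass(d)$mass
  alpha <- standardized_alpha(p, rr_ihd)
  y_half <- incidence_ratio(apply_treatment_shift(d, 0.5), alpha, rr_ihd)
  y_full <- incidence_ratio(apply_treatment_shift(d, 1), alpha, rr_ihd)
  expect_lt(y_full, y_half)
  expect_lt(y_half, 1)
  # residual-risk property: full control never eliminates incidence
  expect_gt(y_full, 0)
})

test_that("sodium-then-treatment ordering is not commutative", {
  d <- build_sbp_distribution(142, 100)
  a <- apply_treatment_shift(apply_sodium_shift(d, 2), 0.5)
  b <- apply_sodium_shift(apply_treatment_shift(d, 0.5), 2)
  expect_false(isTRUE(all.equal(sbp_category_mass(a)$mass,
                                sbp_category_mass(b)$mass,
                                tolerance = 1e-9)))
})

test_that("secondary prevention scales case fatality by the blended effects", {
  expect_equal(adjust_case_fatality(0.2, 0, "ihd"), 0.2)
  expect_equal(adjust_case_fatality(0.5, 1, "hemorrhagic_stroke"), 0.5 * 0.24)
  expect_equal(adjust_case_fatality(0.5, 1, "ischemic_stroke"), 0.5 * 0.64)
  expect_equal(adjust_case_fatality(0.5, 1, "hhd"), 0.5 * 0.80)
  # IHD blends with/without heart failure: 0.3*0.20 + 0.7*0.26
  expect_equal(adjust_case_fatality(1, 1, "ihd"), 0.758)
  expect_error(adjust_case_fatality(0.2, 0.5, "gout"), "unknown")
})

test_that("the shipped risk table has a monotone log-linear gradient", {
  rt <- default_risk_table()
  for (cs in cvd_causes()) {
    rr <- rt$rr[rt$cause == cs]
    expect_equal(rr[1], 1)
    expect_true(all(diff(rr) > 0))
    expect_equal(diff(log(rr)), rep(diff(log(rr))[1], length(rr) - 1),
                 tolerance = 1e-12)
  }
  fx <- default_treatment_effects()
  expect_equal(fx$sodium_sbp_slope$raised_bp, 1.12)
  expect_equal(fx$sodium_sbp_slope$normal_bp, 0.58)
})
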