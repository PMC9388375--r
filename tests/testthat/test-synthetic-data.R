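test_that("generation is deterministic under a fixed seed and seed-sensitive", {
  a <- generate_country(fixture_config(seed = 1), 0)
  b <- generate_country(fixture_config(seed = 1), 0)
  expect_identical(a, b)
  c <- generate_country(fixture_config(seed = 2), 0)
  expect_false(identical(a$population$count, c$population$count))
  expect_false(identical(a$sodium_intake, c$sodium_intake))
})

test_that("generated inputs satisfy the type invariants across many configs", {
  # wide sweep over seeds and perturbed generator ranges; failures collected
  # so a violation reports its seed
  set.seed(1234)
  bad <- integer(0)
  for (seed in 1:1000) {
    cfg <- generator_config(
      seed = seed,
      mort_base_range = sort(runif(2, 3e-4, 1.5e-3)),
      sodium_range = sort(runif(2, 2, 6)),
      excess_death_fraction = runif(1, 0, 0.1)
    )
    ci <- try(generate_country(cfg, seed %% 4), silent = TRUE)
    if (inherits(ci, "try-error")) { bad <- c(bad, seed); next }
    env <- dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(ci$epi_history, year, sex, age_group),
        cause_sum = sum(mortality), .groups = "drop"),
      ci$all_cause_history, by = c("year", "sex", "age_group"))
    cf <- ci$epi_history$mortality / ci$epi_history$prevalence
    ok <- all(env$cause_sum <= env$rate + 1e-12) &&
      all(cf > 0 & cf <= 1) &&
      all(ci$control_history$control >= 0 & ci$control_history$control <= 1)
    if (!ok) bad <- c(bad, seed)
  }
  expect_identical(bad, integer(0))
})

test_that("generated age patterns are qualitatively realistic", {
  ci <- fixture_country()
  over40 <- function(df, col) {
    df <- dplyr::filter(df, age_start >= 40)
    all(dplyr::group_by(df, sex) |>
          dplyr::summarise(mono = !is.unsorted(.data[[col]][order(age_start)])) |>
          dplyr::pull(mono))
  }
  m2019 <- dplyr::filter(ci$all_cause_history, year == 2019)
  expect_true(over40(m2019, "rate"))
  prev <- dplyr::filter(ci$epi_history, year == 2019, cause == "ihd")
  expect_true(over40(prev, "prevalence"))
  expect_true(over40(ci$mean_sbp, "sbp"))
  expect_true(all(ci$mean_sbp$sbp >= 110 & ci$mean_sbp$sbp <= 150))
})

test_that("control history is bounded by its peak and reproducible", {
  cfg <- fixture_config()
  quiet <- generate_control_history(cfg, peak = 0.5, n_years = 20,
                                    start_level = 0.05, noise_sd = 0)
  expect_true(all(diff(quiet) >= 0))
  expect_true(all(quiet <= 0.5))
  noisy1 <- generate_control_history(cfg, peak = 0.5, n_years = 20)
  noisy2 <- generate_control_history(cfg, peak = 0.5, n_years = 20)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1 <= 0.5 & noisy1 >= 0))
  expect_error(generate_control_history(cfg, peak = 0), "peak")
})

test_that("noiseless control histories round-trip through the bau fit", {
  cfg <- fixture_config()
  for (member in c(2L, 5L, 8L)) {
    q <- seq(0.25, 0.65, length.out = 9)[member]
    series <- generate_control_history(cfg, peak = q, n_years = 10,
                                       start_level = 0.05, noise_sd = 0)
    fit <- fit_bau_curve(series)
    expect_identical(attr(fit, "member"), member)
    expect_equal(fit$ceiling, q)
  }
})

test_that("generated mortality implies life expectancy in a plausible band", {
  for (seed in 1:6) {
    ci <- generate_country(fixture_config(seed = seed), 0)
    m <- dplyr::filter(ci$all_cause_history, year == 2019) |>
      dplyr::group_by(age_start) |>
      dplyr::summarise(m = mean(rate), .groups = "drop") |>
      dplyr::arrange(age_start)
    e20 <- life_expectancy(m$age_start, m$m)$e_first
    expect_gt(e20 + 20, 45)
    expect_lt(e20 + 20, 90)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(sodium_range = c(5, 2)), "sodium_range")
  expect_error(generator_config(control_noise_sd = -1), "noise")
  expect_error(generator_config(n_countries = 0), "n_countries")
  expect_error(generate_country(fixture_config(n = 2), 2), "country_index")
})

test_that("country inputs survive a CSV round trip", {
  ci <- fixture_country()
  dir <- withr::local_tempdir()
  write_country_inputs(ci, dir)
  back <- read_country_inputs(dir)
  expect_equal(back$sodium_intake, ci$sodium_intake)
  expect_equal(back$income_group, ci$income_group)
  expect_equal(as.data.frame(back$population), as.data.frame(ci$population))
  expect_equal(as.data.frame(back$epi_history), as.data.frame(ci$epi_history),
               tolerance = 1e-12)
  expect_equal(back$control_history$control, ci$control_history$control)
})
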