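#' Convert a mortality rate to a death probability
#'
#' For a 5-year age interval with deaths spread evenly (average 2.5 years
#' lived by those dying): `q = M * 5 / (1 + M * 2.5)`. The formula exceeds 1
#' for rates above 0.4/year; such values are clipped to 1 with a warning.
#'
#' @param m Mortality rate(s), per person-year.
#' @return Death probability(ies) in `[0, 1]`.
#' @export
mortality_probability <- function(m) {
  assert_nonneg(m, "m")
  q <- m * 5 / (1 + m * 2.5)
  if (any(q > 1)) {
    warn("mortality rates above 0.4/year give probabilities above 1; clipped")
    q <- pmin(q, 1)
  }
  q
}

#' Probability of dying between exact ages 30 and 80
#'
#' `50q30 = 1 - prod(1 - 5qx)` over the ten 5-year age groups 30-34 through
#' 75-79. Restricted to CVD-cause mortality this is the paper-style summary
#' measure of premature-plus-older-age cardiovascular mortality.
#'
#' @param qx Death probabilities for the ten age groups 30-34 ... 75-79.
#' @return Scalar probability.
#' @export
probability_50q30 <- function(qx) {
  if (length(qx) != 10) abort("`qx` must hold exactly 10 age-group probabilities.")
  assert_probability(qx, "qx")
  1 - prod(1 - qx)
}

#' Abridged life table
#'
#' Standard abridged life-table construction on 5-year age groups: death
#' probabilities via [mortality_probability()] (average 2.5 person-years
#' lived by those dying), an open final interval with `Lx = lx / M`, and
#' remaining life expectancy `ex = Tx / lx`.
#'
#' @param age_start Lower bound of each age group (5-year spacing, last
#'   group open).
#' @param m Mortality rates per age group.
#' @return Tibble with columns `age_start`, `m`, `qx`, `lx`, `Lx`, `ex`.
#' @export
life_table <- function(age_start, m) {
  if (length(age_start) != length(m)) abort("`age_start` and `m` lengths differ.")
  assert_nonneg(m, "m")
  n <- length(m)
  qx <- suppressWarnings(mortality_probability(m))
  qx <- pmin(qx, 1)
  qx[n] <- 1
  lx <- numeric(n)
  lx[1] <- 1
  for (i in seq_len(n - 1)) lx[i + 1] <- lx[i] * (1 - qx[i])
  dx <- lx * qx
  Lx <- 5 * (lx - dx) + 2.5 * dx
  Lx[n] <- if (m[n] > 0) lx[n] / m[n] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  tibble::tibble(age_start = age_start, m = m, qx = qx, lx = lx,
                 Lx = Lx, ex = ex)
}

#' Life expectancy from age-specific mortality
#'
#' @param age_start Lower bound of each age group; must include age 40.
#' @param m Mortality rates per age group.
#' @return Named list with `e_first` (remaining life expectancy at the first
#'   age of the grid) and `e40` (at age 40).
#' @export
life_expectancy <- function(age_start, m) {
  lt <- life_table(age_start, m)
  if (!40 %in% age_start) abort("age grid must include age 40.")
  list(e_first = lt$ex[1], e40 = lt$ex[lt$age_start == 40])
}

#' Decompose projected change into growth, aging and rate components
#'
#' Stepwise counterfactual decomposition of the percentage change in case
#' counts between a base and a projection year: (1) base age structure and
#' rates applied to the projected total population isolates population
#' growth; (2) projected age structure with base rates adds population
#' aging; (3) the remainder of the model-projected change is attributed to
#' changes in age-specific rates. The three components sum to the total
#' change by construction.
#'
#' @param cases_base Model case count in the base year (> 0).
#' @param rates_base,rates_proj Age-specific rates per cell in the base and
#'   projection years.
#' @param structure_base,structure_proj Population age-structure shares per
#'   cell (each summing to 1).
#' @param pop_total_proj Total projected population in the projection year.
#' @param cases_proj Model case count in the projection year; defaults to
#'   the count implied by `structure_proj`, `pop_total_proj` and
#'   `rates_proj`.
#' @return Tibble with columns `component`
#'   (`growth`, `aging`, `rates`, `total`) and `percent`.
#' @export
decompose_change <- function(cases_base, rates_base, structure_base,
                             pop_total_proj, structure_proj, rates_proj,
                             cases_proj = NULL) {
  if (cases_base <= 0) abort("`cases_base` must be positive.")
  cases_proj <- cases_proj %||%
    sum(structure_proj * pop_total_proj * rates_proj)
  cf_growth <- sum(structure_base * pop_total_proj * rates_base)
  cf_aging <- sum(structure_proj * pop_total_proj * rates_base)
  growth <- (cf_growth - cases_base) / cases_base
  aging <- (cf_aging - cases_base) / cases_base - growth
  total <- (cases_proj - cases_base) / cases_base
  rates <- total - growth - aging
  tibble::tibble(component = c("growth", "aging", "rates", "total"),
                 percent = 100 * c(growth, aging, rates, total))
}

#' Cohort health-state trajectory
#'
#' Follows a cohort (defined by the age group it occupies in the first
#' reported year) through a scenario run and returns, for each year, the
#' probabilities of the four mutually exclusive states: alive and free of
#' both hypertension and CVD; alive and hypertensive (SBP at or above the
#' threshold, from the current post-intervention distribution) without CVD;
#' alive with CVD; and dead. The four probabilities sum to 1.
#'
#' @param projection A `cvd_projection` from [run_projection()].
#' @param age_start Lower bound of the cohort's age group in `start_year`.
#' @param start_year First year of the trajectory.
#' @param threshold Hypertension threshold, mmHg.
#' @return Tibble with columns `year`, `age_start`, `free`, `hypertensive`,
#'   `cvd`, `dead`. If the cohort ages beyond the open interval before the
#'   projection horizon the trajectory is truncated, with attribute
#'   `truncated = TRUE`.
#' @export
cohort_health_trajectory <- function(projection, age_start = 35,
                                     start_year = 2020, threshold = 140) {
  starts <- age_group_starts()
  if (!age_start %in% starts) abort("`age_start` must be on the model age grid.")
  cells <- projection$cells
  years <- sort(unique(cells$year))
  years <- years[years >= start_year]
  alive <- 1
  out <- vector("list", length(years))
  truncated <- FALSE
  for (i in seq_along(years)) {
    age_now <- age_start + (years[i] - start_year)
    if (age_now > max(starts)) { truncated <- TRUE; out <- out[seq_len(i - 1)]; break }
    grp <- starts[findInterval(age_now, starts)]
    cell <- cells |>
      dplyr::filter(.data$year == years[i], .data$age_start == grp) |>
      dplyr::summarise(
        pop = sum(.data$pop),
        sick = sum(.data$sick_total),
        deaths = sum(.data$all_cause_deaths),
        p_hyp = sum(.data$prop_raised_bp * .data$pop) / sum(.data$pop)
      )
    prev <- min(cell$sick / cell$pop, 1)
    out[[i]] <- tibble::tibble(
      year = years[i], age_start = grp,
      free = alive * (1 - prev) * (1 - cell$p_hyp),
      hypertensive = alive * (1 - prev) * cell$p_hyp,
      cvd = alive * prev,
      dead = 1 - alive
    )
    alive <- alive * max(1 - cell$deaths / cell$pop, 0)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truncated") <- truncated
  res
}
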