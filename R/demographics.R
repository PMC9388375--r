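#' Build a Leslie matrix
#'
#' Classical cohort-component projection matrix: age-specific fertility in
#' the first row, survival proportions on the sub-diagonal, and the open
#' (final) age group accumulating on the diagonal. With
#' `aging_fraction < 1` the matrix implements sub-interval time steps on a
#' grouped age grid: each step, `aging_fraction` of a group's survivors move
#' up one group and the remainder stay (used by the pipeline to run 1-year
#' steps on 5-year groups).
#'
#' @param fertility Non-negative entry rates per age group (births entering
#'   the first modelled group per member per step).
#' @param survival Survival proportions per age group, in `[0, 1]`.
#' @param aging_fraction Fraction of survivors aging one group per step.
#' @return A square numeric matrix.
#' @export
build_leslie <- function(fertility, survival, aging_fraction = 1) {
  n <- length(survival)
  if (length(fertility) != n) abort("`fertility` and `survival` lengths differ.")
  assert_nonneg(fertility, "fertility")
  assert_probability(survival, "survival")
  assert_probability(aging_fraction, "aging_fraction")
  L <- matrix(0, n, n)
  L[1, ] <- fertility
  for (i in seq_len(n - 1)) {
    L[i + 1, i] <- L[i + 1, i] + survival[i] * aging_fraction
    L[i, i] <- L[i, i] + survival[i] * (1 - aging_fraction)
  }
  L[n, n] <- L[n, n] + survival[n]
  L
}

#' Project a population one step forward
#'
#' Cohort-component update `P_{t+1} = L (P_t + 0.5 I_t) + 0.5 I_t`: half of
#' net migrants are exposed to the projection step, half are added
#' afterwards. Negative resulting counts are clipped to zero with a warning.
#'
#' @param pop Population counts per age group.
#' @param leslie Leslie matrix from [build_leslie()].
#' @param migrants Net migrants per age group (default zero).
#' @return Projected population counts.
#' @export
project_population <- function(pop, leslie, migrants = 0) {
  n <- length(pop)
  if (!is.matrix(leslie) || nrow(leslie) != n || ncol(leslie) != n) {
    abort("`leslie` dimensions do not match `pop`.")
  }
  migrants <- rep_len(migrants, n)
  out <- as.numeric(leslie %*% (pop + 0.5 * migrants)) + 0.5 * migrants
  if (any(out < 0)) {
    warn("negative projected counts clipped to zero")
    out <- pmax(out, 0)
  }
  out
}

#' Smooth grouped rates to a finer grid
#'
#' Shape-preserving (monotone) cubic interpolation of quinquennial rates to
#' single years/ages. Input knots are reproduced exactly and output rates are
#' clamped at zero.
#'
#' @param x Knot positions (e.g. period or age-group midpoints), length >= 3.
#' @param rates Rates at the knots.
#' @param xout Positions at which to evaluate.
#' @return Numeric vector of interpolated rates at `xout`.
#' @export
smooth_rates <- function(x, rates, xout) {
  if (length(x) < 3) abort("need at least 3 knots to smooth rates.")
  if (length(x) != length(rates)) abort("`x` and `rates` lengths differ.")
  f <- splinefun(x, rates, method = "monoH.FC")
  pmax(f(xout), 0)
}

#' Rescale rates to reproduce target aggregate counts
#'
#' Multiplies all rates by the ratio of the target aggregate count to the
#' count implied by applying the rates to the population, so that the
#' rescaled rates reproduce the target exactly.
#'
#' @param rates Rates per cell.
#' @param target Target aggregate count (scalar).
#' @param pop Population per cell.
#' @return Rescaled rates.
#' @export
rescale_rates <- function(rates, target, pop) {
  assert_nonneg(rates, "rates")
  assert_nonneg(pop, "pop")
  implied <- sum(rates * pop)
  if (target == 0) return(rates * 0)
  if (implied == 0) abort("implied aggregate is zero but `target` is not.")
  rates * (target / implied)
}

#' Remove excess deaths from a population
#'
#' Subtracts a total count of excess deaths (e.g. pandemic-era excess
#' mortality) from population cells in proportion to the all-cause death
#' age-sex pattern. Cells are never driven negative: any deficit is
#' redistributed over the remaining cells (with a warning) so that exactly
#' `excess_total` is removed.
#'
#' @param pop Population counts per cell.
#' @param excess_total Total excess deaths to remove (>= 0; must not exceed
#'   the total population).
#' @param pattern Non-negative weights per cell (the all-cause death
#'   pattern).
#' @return Population counts after removal.
#' @export
apply_excess_deaths <- function(pop, excess_total, pattern) {
  assert_nonneg(excess_total, "excess_total")
  assert_nonneg(pattern, "pattern")
  if (length(pattern) != length(pop)) abort("`pattern` length differs from `pop`.")
  if (excess_total > sum(pop)) abort("`excess_total` exceeds total population.")
  if (excess_total == 0) return(pop)
  if (sum(pattern) == 0) abort("`pattern` must have positive total weight.")
  remaining <- excess_total
  removal <- numeric(length(pop))
  w <- pattern
  capped <- FALSE
  while (remaining > 1e-9) {
    open <- (pop - removal) > 0 & w > 0
    if (!any(open)) abort("cannot remove excess deaths without exhausting cells.")
    prop <- numeric(length(pop))
    prop[open] <- w[open] / sum(w[open])
    take <- pmin(remaining * prop, pop - removal)
    if (any(remaining * prop > pop - removal)) capped <- TRUE
    removal <- removal + take
    remaining <- remaining - sum(take)
    w[(pop - removal) <= 0] <- 0
  }
  if (capped) warn("excess-death removal capped in some cells; deficit redistributed")
  pop - removal
}
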