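# Shared fixtures: small, deterministic objects rebuilt in code at test time.

fixture_config <- function(seed = 1L, n = 2L, ...) {
  generator_config(seed = seed, n_countries = n, ...)
}

fixture_country <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, index = 0L) {
    key <- paste(seed, index, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_country(fixture_config(seed = seed), index)
    }
    cache[[key]]
  }
})

# single-stratum disease history generated from known constant transitions,
# in the estimation conventions (prevalence of current pop, deaths per
# person at start of year)
fixture_disease_history <- function(ir, cf, bg, p0 = 0.05, n_years = 6,
                                    cf_trend = 0, bg_trend = 0) {
  sim <- sim_disease(pop0 = 1, sick0 = p0, ir = ir, cf = cf, bg = bg,
                     n_years = n_years - 1, cf_trend = cf_trend,
                     bg_trend = bg_trend)
  tibble::tibble(
    year = 2014:(2014 + n_years - 1),
    # the first-year mortality entry is never consumed by the estimator
    prevalence = c(p0, sim$prevalence),
    mortality = c(cf * p0, sim$mortality),
    bg = rep(bg, n_years)
  )
}
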