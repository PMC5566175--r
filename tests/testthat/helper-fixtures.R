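# Shared fixtures: small synthetic schedules and desk-scale configurations.

tiny_schedule <- function(start = 1970, n_years = 26, tfr_start = 2.5,
                          tfr_end = 1.5, e0_proxy = 0.6) {
  synthesize_schedule(start, n_years, tfr_start, tfr_end, e0_proxy)
}

tiny_config <- function(start_year = 1980, end_year = 1995, burnin_years = 10,
                        population_size = 3000, n_replicates = 2, seed = 42,
                        ...) {
  scenario_config(start_year = start_year, end_year = end_year,
                  burnin_years = burnin_years,
                  population_size = population_size,
                  n_replicates = n_replicates, seed = seed, ...)
}

# A small female-only population of women with given state, for unit tests
# of the demographic primitives.
test_women <- function(n, age = 25L, sp = 0L, p = 0L, so = 0L, tech = FALSE,
                       year = 1980L) {
  structure(
    list(id = seq_len(n), sex = rep(1L, n), birth_year = rep(year - age, n),
         age = rep(as.integer(age), n), sp = rep(as.integer(sp), n),
         p = rep(as.integer(p), n), so = rep(as.integer(so), n),
         tech = rep(tech, n), ab = rep(0L, n),
         mother_id = rep(NA_integer_, n), next_id = n + 1L),
    class = "srb_population"
  )
}
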