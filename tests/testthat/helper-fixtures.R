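# Shared fixtures: scenarios are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

zero_noise <- function() {
  list(swdr_rel = 0, albedo_rel = 0, flux = 0, tair = 0, nee = 0, met = 0)
}

# 1-year noise-free scenario, no rain, no gaps: exact-construction checks
clean_scenario <- function() scenario_spec(
  seed = 101, n_years = 1, noise = zero_noise(),
  gap_fraction = 0, rain_freq = 0)

clean_records <- function() {
  if (is.null(.fixture_cache$clean)) {
    .fixture_cache$clean <- generate_halfhourly(clean_scenario())
  }
  .fixture_cache$clean
}

# 2-year noise-free scenario with the recovery-target effects
recovery_scenario <- function() {
  eff <- default_treatment_effects()
  eff$delta_alpha[eff$site == "NT" & eff$layer == "ecosystem"] <- 0.015
  eff$delta_nee[eff$site == "NT" & eff$layer == "ecosystem"] <- -0.3
  eff$ts_offset[eff$site == "NT" & eff$layer == "ecosystem"] <- 0.8
  scenario_spec(seed = 202, n_years = 2, effects = eff,
                noise = zero_noise(), gap_fraction = 0, rain_freq = 0)
}

recovery_records <- function() {
  if (is.null(.fixture_cache$recovery)) {
    .fixture_cache$recovery <- generate_halfhourly(recovery_scenario())
  }
  .fixture_cache$recovery
}

# noisy 1-year scenario with rain and gaps: filter and robustness checks
noisy_records <- function() {
  if (is.null(.fixture_cache$noisy)) {
    .fixture_cache$noisy <- generate_halfhourly(scenario_spec(seed = 303,
                                                              n_years = 1))
  }
  .fixture_cache$noisy
}

test_calendar <- function() default_season_calendar(2013:2019)

test_kernels <- function() {
  kernel_ensemble(read_kernel_csv(
    system.file("extdata", "synthetic_albedo_kernels.csv",
                package = "ecoforcing")))
}

site_layer <- function(records, site, layer) {
  records[records$site_id == site & records$layer == layer, ]
}

# independent DTW oracle: exhaustive enumeration of monotone warping paths
dtw_brute_force <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible(NULL))
    if (i == n && j == m) { best <<- acc; return(invisible(NULL)) }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    invisible(NULL)
  }
  recurse(1, 1, 0)
  best
}
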