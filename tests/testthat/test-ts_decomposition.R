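test_that("emissivity-albedo relation and bounds", {
  expect_equal(emissivity_from_albedo(0.2), 0.958)
  expect_equal(emissivity_from_albedo(0.5), 0.91)
  expect_true(is.na(emissivity_from_albedo(0)))   # boundary excluded
  expect_true(is.na(emissivity_from_albedo(1.2)))
})

test_that("surface temperature inverts the Stefan-Boltzmann law", {
  sigma <- physical_constants()$sigma
  # forward oracle: build LWUR from a known temperature, invert it back
  expect_equal(ts_from_lwur(sigma * 1 * 300^4, 1), 300, tolerance = 1e-9)
  expect_equal(ts_from_lwur(sigma * 0.97 * 292^4, 0.97), 292,
               tolerance = 1e-9)
  expect_equal(ts_from_lwur(459.3, 1), (459.3 / sigma)^0.25,
               tolerance = 1e-12)
  expect_true(ts_from_lwur(500, 0.97) > ts_from_lwur(400, 0.97))
  expect_true(is.na(ts_from_lwur(-5, 0.97)))
})

test_that("residual imbalance is the unclosed budget", {
  expect_equal(residual_imbalance(100, 20, 300, 280, 40, 30, 10), 20)
  expect_equal(residual_imbalance(100, 20, 300, 280, 60, 30, 10), 0)
  expect_true(is.na(residual_imbalance(NA, 20, 300, 280, 40, 30, 10)))
  # generator truth: closure c leaves I = (1-c) x (Rn - G)
  r <- site_layer(clean_records(), "CT", "ecosystem")
  g <- combine_soil_heat_flux(r$G_open, r$G_canopy, 0.2)
  rn <- with(r, SWDR - SWUR + LWDR - LWUR)
  i <- residual_imbalance(r$SWDR, r$SWUR, r$LWDR, r$LWUR, r$LE, r$H, g)
  expect_lt(max(abs(i - 0.12 * (rn - g))), 1e-9)
})

test_that("single-perturbation decompositions match arithmetic oracles", {
  base <- list(SWDR = 200, LWDR = 300, LE = 80, H = 60, G = 10, I = 20,
               albedo = 0.2, ts = 300)
  base$albedo <- (0.99 - 0.96) / 0.16  # albedo giving eps = 0.96
  sigma <- physical_constants()$sigma
  D <- 4 * sigma * 0.96 * 300^3
  expect_equal(D, 5.879, tolerance = 1e-3)

  # all-zero differences
  z <- decompose_delta_ts(base, base)
  expect_equal(z$dts_cal, 0)
  expect_true(all(abs(z[, c("d_alpha", "d_swdr", "d_lwdr", "d_eps",
                            "d_le", "d_h", "d_g", "d_i")]) < 1e-15))

  # LE perturbation alone of exactly D W m-2 cools by 1 degC
  t1 <- base; t1$LE <- base$LE + D
  d1 <- decompose_delta_ts(t1, base)
  expect_equal(d1$dts_cal, -1, tolerance = 1e-12)
  expect_equal(d1$d_le, -1, tolerance = 1e-12)

  # emissivity perturbation alone: -Ts deps / (4 eps)
  t2 <- base; t2$albedo <- base$albedo - 0.01 / 0.16  # deps = +0.01
  d2 <- decompose_delta_ts(t2, base)
  expect_equal(d2$d_eps, -300 * 0.01 / (4 * 0.96), tolerance = 1e-6)
  expect_equal(d2$d_eps, -0.781, tolerance = 1e-3)

  # antisymmetry: swapping sites negates all components (same reference
  # state, so compare against the mirrored perturbation)
  t3 <- base
  t3$LE <- base$LE + 10; t3$H <- base$H - 5; t3$LWDR <- base$LWDR + 8
  fwd <- decompose_delta_ts(t3, base)
  t4 <- base
  t4$LE <- base$LE - 10; t4$H <- base$H + 5; t4$LWDR <- base$LWDR - 8
  rev <- decompose_delta_ts(t4, base)
  for (comp in c("d_le", "d_h", "d_lwdr", "dts_cal")) {
    expect_equal(rev[[comp]], -fwd[[comp]], tolerance = 1e-12, label = comp)
  }
})

test_that("components close exactly and track observed dTs on clean data", {
  rec <- clean_records()
  cal <- test_calendar()
  comps <- c("d_alpha", "d_swdr", "d_lwdr", "d_eps", "d_le", "d_h",
             "d_g", "d_i")
  for (layer in c("ecosystem", "understory")) {
    st_t <- daily_site_state(site_layer(rec, "NT", layer), 39.94)
    st_c <- daily_site_state(site_layer(rec, "CT", layer), 39.94)
    dc <- decomposition_daily(st_t, st_c, cal)
    expect_gt(nrow(dc), 300)
    expect_lt(max(abs(rowSums(dc[, comps]) - dc$dts_cal)), 1e-9)
    expect_lt(max(abs(dc$dts_cal - dc$dts_obs)), 0.05)
  }
})

test_that("observed dTs difference recovers the injected offset exactly", {
  expect_equal(delta_ts_obs(293.15, 292.15), 1.0)
  expect_equal(delta_ts_obs(290, 290), 0)
  rec <- clean_records()
  st_t <- daily_site_state(site_layer(rec, "NT", "understory"), 39.94)
  st_c <- daily_site_state(site_layer(rec, "CT", "understory"), 39.94)
  d <- delta_ts_obs(st_t$ts, st_c$ts)
  expect_equal(mean(d, na.rm = TRUE), 0.63, tolerance = 1e-9)
})
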