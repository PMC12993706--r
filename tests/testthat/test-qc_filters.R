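test_that("clear-sky index divides by expected irradiance with a low-sun guard", {
  expect_equal(clear_sky_index(750, 1000, 1.0), 0.75)
  expect_true(is.na(clear_sky_index(5, 10, 1.0)))    # expected <= 20 W m-2
  expect_true(is.na(clear_sky_index(NA, 1000, 0.75)))
  # generator clear days at matching transmissivity give CSI 1 at midday
  rec <- site_layer(clean_records(), "CT", "ecosystem")
  hour <- (as.numeric(rec$timestamp) / 3600 - 0.25) %% 24
  mid <- hour >= 11 & hour < 14.5
  doy <- as.integer(strftime(rec$timestamp - 900, "%j", tz = "UTC"))
  csi <- clear_sky_index(rec$SWDR, potential_radiation(39.94, doy, hour), 0.75)
  expect_lt(max(abs(csi[mid] - 1), na.rm = TRUE), 1e-9)
})

test_that("midday albedo averages qualifying ratios and excludes rain", {
  ts <- as.POSIXct("2020-06-01 00:30", tz = "UTC") + 1800 * (0:47)
  hour <- ((as.numeric(ts) - 900) %% 86400) / 3600
  doy <- 153
  swdr <- 0.75 * potential_radiation(40, doy, hour)
  rec <- data.frame(timestamp = ts, SWDR = swdr, SWUR = 0.18 * swdr,
                    precip = 0)
  out <- midday_albedo_daily(rec, 40)
  expect_equal(out$albedo, 0.18, tolerance = 1e-12)

  # albedo ramp across the window: arithmetic mean of the valid ratios
  win <- hour >= 11 & hour < 14.5
  ramp <- seq(0.17, 0.19, length.out = sum(win))
  rec2 <- rec
  rec2$SWUR[win] <- ramp * rec2$SWDR[win]
  out2 <- midday_albedo_daily(rec2, 40)
  expect_equal(out2$albedo, mean(ramp), tolerance = 1e-12)

  rec$precip[30] <- 2
  expect_true(is.na(midday_albedo_daily(rec, 40)$albedo))
})

test_that("soil heat flux combination is the canopy-weighted mean", {
  expect_equal(combine_soil_heat_flux(50, 20, 0.2), 44)
  expect_equal(combine_soil_heat_flux(50, 20, 0), 50)
  expect_equal(combine_soil_heat_flux(50, 20, 1), 20)
  expect_true(is.na(combine_soil_heat_flux(NA, 20, 0.2)))
})

test_that("day flags apply the 66% day/night missingness rule and rain", {
  rec <- site_layer(clean_records(), "CT", "ecosystem")[1:(48 * 3), ]
  fl <- day_flags(rec, 39.94)
  expect_true(all(fl$passes_missingness))

  # drop 70% of night-time LE on day 2
  hour <- ((as.numeric(rec$timestamp) - 900) %% 86400) / 3600
  doy <- as.integer(strftime(rec$timestamp - 900, "%j", tz = "UTC"))
  night <- potential_radiation(39.94, doy, hour) == 0
  d2 <- seq(49, 96)
  n2 <- intersect(d2, which(night))
  rec$LE[n2[seq_len(ceiling(0.7 * length(n2)))]] <- NA
  fl2 <- day_flags(rec, 39.94)
  expect_false(fl2$passes_missingness[2])
  expect_true(fl2$passes_missingness[1])

  # monotone: removing data never turns a failing day into a passing one
  rec$H[d2] <- NA
  fl3 <- day_flags(rec, 39.94)
  expect_false(fl3$passes_missingness[2])
})

test_that("agreement filter keeps identical signs within the threshold", {
  expect_true(delta_ts_agreement(0.5, 1.9))
  expect_false(delta_ts_agreement(0.5, -0.5))
  expect_false(delta_ts_agreement(0.5, 2.6))   # 2.1 degC difference
  expect_true(delta_ts_agreement(0, -0.5))     # zero agrees either way
  expect_false(delta_ts_agreement(NA, 1))
  # analytically enumerable 10-day table
  obs <- c(0.5, -0.3, 1.1, 0.0, 2.5, -1.0, 0.2, 0.9, -0.4, 1.5)
  cal <- c(0.6, 0.3, 1.0, 0.4, 0.3, -0.8, 2.3, 1.0, -0.2, -1.5)
  keep <- delta_ts_agreement(obs, cal)
  expect_equal(keep, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                       TRUE, FALSE))
})

test_that("closure regression recovers constructed and injected slopes", {
  set.seed(1)
  x <- runif(100, 50, 400)
  cl <- energy_balance_closure(0.88 * x, 0 * x, x, 0 * x)
  expect_equal(cl$slope, 0.88, tolerance = 1e-12)
  expect_equal(cl$ratio, 0.88, tolerance = 1e-12)
  cl2 <- energy_balance_closure(0.6 * x, 0.4 * x, x, 0 * x)
  expect_equal(cl2$slope, 1.0, tolerance = 1e-12)
  expect_error(energy_balance_closure(1:5, 1:5, 1:5, 1:5), ">= 30")

  # generator truth: understory closure 0.6 under noise, 365 days
  st <- daily_site_state(site_layer(noisy_records(), "CT", "understory"),
                        39.94)
  cl3 <- energy_balance_closure(st$LE, st$H,
                                st$SWDR - st$SWUR + st$LWDR - st$LWUR, st$G)
  expect_lt(abs(cl3$slope - 0.60), 0.02)
})
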