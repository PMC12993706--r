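test_that("psychrometric helpers agree with tabulated values", {
  # reference values: standard meteorological tables at 101.325 kPa
  p0 <- psychrometrics(0); p20 <- psychrometrics(20); p40 <- psychrometrics(40)
  expect_equal(p0$esat, 0.611, tolerance = 0.01)
  expect_equal(p20$esat, 2.339, tolerance = 0.01)
  expect_equal(p40$esat, 7.38, tolerance = 0.01)
  expect_equal(p0$slope, 0.0444, tolerance = 0.01)
  expect_equal(p20$slope, 0.145, tolerance = 0.01)
  expect_equal(p40$slope, 0.394, tolerance = 0.01)
  expect_equal(p20$lambda, 2.454e6, tolerance = 0.01)
  expect_equal(p20$gamma, 0.0665, tolerance = 0.01)
  expect_equal(p20$rho, 1.204, tolerance = 0.01)
})

test_that("WUE and ET conversion follow the latent-heat relation", {
  expect_equal(water_use_efficiency(4, 2), 2)
  expect_equal(water_use_efficiency(0, 2), 0)
  expect_true(is.na(water_use_efficiency(4, 0.05)))  # ET below floor
  # LE 28.94 W m-2 daily mean at 20 degC: lambda = 2.454 MJ kg-1
  expect_equal(et_from_le(28.94, 20), 28.94 * 86400 / 2.4536e6,
               tolerance = 1e-6)
  expect_equal(et_from_le(28.94, 20), 1.02, tolerance = 0.01)
})

test_that("evaporative fraction partitions turbulent flux", {
  expect_equal(evaporative_fraction(60, 40), 0.6)
  expect_equal(evaporative_fraction(50, 0), 1.0)
  expect_true(is.na(evaporative_fraction(4, 4)))  # denominator at floor
})

test_that("aerodynamic conductance matches the arithmetic oracle", {
  expect_equal(aerodynamic_conductance(2, 0.3),
               1 / (2 / 0.3^2 + 6.2 * 0.3^(-2 / 3)), tolerance = 1e-12)
  expect_lt(abs(aerodynamic_conductance(2, 0.3) - 0.02773), 1e-4)
  expect_equal(aerodynamic_conductance(1, 1), 1 / 7.2)
  # monotone: more wind at fixed ustar means more resistance
  expect_lt(aerodynamic_conductance(3, 0.3), aerodynamic_conductance(2, 0.3))
  expect_true(is.na(aerodynamic_conductance(0, 0.3)))
})

test_that("surface conductance inverts Penman-Monteith", {
  expect_equal(surface_conductance(0, 400, 20, 1.5, 25, 95, 0.04), 0)
  # independent big-leaf oracle coded from scratch
  gs_oracle <- function(LE, Rn, G, VPD, Ta, P, Ga) {
    es <- 0.6108 * exp(17.27 * Ta / (Ta + 237.3))
    s <- 4098 * es / (Ta + 237.3)^2
    lam <- (2.501 - 0.00237 * Ta) * 1e6
    gam <- 1004.834 * P / (0.622 * lam)
    rho <- P * 1000 / (287.058 * (Ta + 273.15))
    gam * LE * Ga / (s * (Rn - G) + rho * 1004.834 * VPD * Ga -
                       LE * (s + gam))
  }
  got <- surface_conductance(150, 400, 0, 1.5, 25, 101.325, 0.04)
  expect_equal(got, gs_oracle(150, 400, 0, 1.5, 25, 101.325, 0.04),
               tolerance = 1e-9)

  # master oracle: inversion then forward reproduces LE, 1000 draws
  set.seed(77)
  n <- 1000
  Rn <- runif(n, 100, 600); G <- runif(n, 0, 60); VPD <- runif(n, 0.3, 4)
  Ta <- runif(n, 5, 35); P <- runif(n, 92, 102); Ga <- runif(n, 0.005, 0.08)
  Gs_true <- runif(n, 2e-4, 0.02)
  LE <- penman_monteith_le(Gs_true, Rn, G, VPD, Ta, P, Ga)
  Gs_inv <- surface_conductance(LE, Rn, G, VPD, Ta, P, Ga)
  LE_back <- penman_monteith_le(Gs_inv, Rn, G, VPD, Ta, P, Ga)
  expect_equal(Gs_inv, Gs_true, tolerance = 1e-9)
  expect_lt(max(abs(LE_back - LE) / pmax(abs(LE), 1e-12)), 1e-6)
})

test_that("decoupling coefficient has the right limits and monotonicity", {
  om <- decoupling_coefficient(1e-9, 0.01, 20)
  expect_equal(om, 1, tolerance = 1e-6)       # Ga/Gs -> 0: decoupled
  # eps = 1 at the temperature where slope equals gamma
  f <- function(Ta) {
    p <- psychrometrics(Ta)
    p$slope / p$gamma - 1
  }
  Ta1 <- uniroot(f, c(0, 20))$root
  expect_equal(decoupling_coefficient(0.01, 0.01, Ta1), 2 / 3,
               tolerance = 1e-6)
  ratios <- c(0.5, 1, 2, 5, 20)
  oms <- decoupling_coefficient(0.01 * ratios, 0.01, 20)
  expect_true(all(diff(oms) < 0))
  expect_true(all(oms > 0 & oms < 1))
  expect_true(is.na(decoupling_coefficient(-0.01, 0.01, 20)))
})

test_that("daily ecophysiology recovers generator parameters", {
  rec <- site_layer(clean_records(), "CT", "ecosystem")
  eco <- ecophys_daily(rec, 39.94, test_calendar())
  # evaporative fraction parameter by season (noise-free construction)
  base <- default_season_baselines()
  for (s in base$season) {
    got <- mean(eco$EF[eco$season == s], na.rm = TRUE)
    expect_equal(got, base$EF[base$season == s], tolerance = 1e-6, label = s)
  }
  expect_true(all(eco$Omega > 0 & eco$Omega < 1, na.rm = TRUE))
  expect_true(all(eco$Ga > 0, na.rm = TRUE))
  expect_gt(sum(!is.na(eco$Gs)), 200)
})
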