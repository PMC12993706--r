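test_that("mole-fraction perturbation follows the unit-propagation chain", {
  expect_equal(cumulative_delta_chi(0), 0)
  # 0.44 * (-100) * 2.414 / 5.15e21
  expect_equal(cumulative_delta_chi(-100, 1), 0.44 * -100 * 2.414 / 5.15e21,
               tolerance = 1e-12)
  expect_equal(cumulative_delta_chi(-200), 2 * cumulative_delta_chi(-100))
})

test_that("CO2 forcing linearisation matches the log form to first order", {
  chi <- cumulative_delta_chi(-100)
  expect_equal(rf_delta_nee(chi), 5.35 * chi / 399.4e-6, tolerance = 1e-12)
  expect_equal(rf_delta_nee(0), 0)

  chi0 <- 399.4e-6
  dchi <- 1e-4 * chi0
  rel <- abs(rf_delta_nee(dchi) - rf_delta_nee(dchi, form = "log")) /
    abs(rf_delta_nee(dchi))
  # second-order series term: relative difference is (dchi/chi0)/2
  expect_lt(rel, 1e-4 / 2 * 1.01)
  expect_gt(rel, 1e-4 / 2 * 0.99)
  expect_warning(rf_delta_nee(0.02 * chi0), "linearisation")
})

test_that("albedo forcing has kernel antisymmetry and correct magnitude", {
  rf <- rf_delta_alpha(0.01, 100)
  expect_equal(rf$rf, -100 * 0.01 / 5.1e14, tolerance = 1e-12)
  expect_equal(rf_delta_alpha(0, 100)$rf, 0)
  expect_equal(rf_delta_alpha(-0.01, 100)$rf, -rf$rf)
  expect_equal(rf_delta_alpha(0.01, 100, kernel_sd = 10)$rf_sd,
               10 * 0.01 / 5.1e14)
})

test_that("forcing combination is additive with a running CO2 sum", {
  comb <- combine_rf(c(0, 0), c(0, 0))
  expect_true(all(comb$rf_total == 0))
  expect_error(combine_rf(1:3, 1:2), "misaligned")

  set.seed(4)
  rfa <- rnorm(24, -4e-15, 1e-15)
  rfn <- rnorm(24, -1e-16, 2e-17)
  comb <- combine_rf(rfa, rfn)
  # independent re-sum
  for (m in c(1, 7, 24)) {
    expect_equal(comb$rf_nee_cum[m], sum(rfn[1:m]), tolerance = 1e-25)
    expect_equal(comb$rf_total[m], rfa[m] + sum(rfn[1:m]), tolerance = 1e-25)
  }
  # monotone non-increasing cumulative term when all increments negative
  expect_true(all(diff(comb$rf_nee_cum) < 0))
})

test_that("kernel reader normalises per-0.01 units and checks coverage", {
  kern <- read_kernel_csv(system.file("extdata",
                                      "synthetic_albedo_kernels.csv",
                                      package = "ecoforcing"))
  expect_equal(sort(unique(kern$month)), 1:12)
  # the per-0.01 model lands on the same scale as the per-unit models
  ens <- kernel_ensemble(kern)
  jul <- kern[kern$month == 7, ]
  expect_true(all(jul$kernel > 150 & jul$kernel < 200))
  expect_equal(ens$kernel_mean[ens$month == 7], mean(jul$kernel))

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model,month,kernel", "X,1,100"), tmp)
  expect_error(read_kernel_csv(tmp), "months 1-12")
})

test_that("GWP conversion is linear and inverts the forcing chain", {
  expect_equal(gwp_delta_alpha(0), 0)
  expect_equal(gwp_delta_alpha(-4e-15), 2 * gwp_delta_alpha(-2e-15))
  # round trip: the returned sustained emission, accumulated to half the
  # horizon and run through the NEE forcing chain, reproduces the input
  const <- physical_constants()
  rf_in <- -3.7e-15
  e_kg_co2_ha_yr <- gwp_delta_alpha(rf_in, horizon = 100)
  e_gC_m2_yr <- e_kg_co2_ha_yr * 1000 / 1e4 * const$M_C / const$M_CO2
  rf_back <- rf_delta_nee(cumulative_delta_chi(e_gC_m2_yr * 50))
  expect_equal(rf_back, rf_in, tolerance = 1e-9 * abs(rf_in))
  expect_lt(e_kg_co2_ha_yr, 0)  # cooling maps to avoided emission
})

test_that("monthly table recovers injected forcing on a clean scenario", {
  rec <- clean_records()
  a_t <- midday_albedo_daily(site_layer(rec, "NT", "ecosystem"), 39.94)
  a_c <- midday_albedo_daily(site_layer(rec, "CT", "ecosystem"), 39.94)
  alb <- data.frame(date = a_t$date, albedo_treated = a_t$albedo,
                    albedo_control = a_c$albedo)
  nee <- data.frame(date = a_t$date, dnee = -0.2)
  kern <- data.frame(month = 1:12, kernel_mean = 100, kernel_sd = 0)
  tab <- monthly_rf_table(alb, nee, kern, as.Date("2015-01-01"))
  # constant kernel 100, dalpha 0.015: -100*0.015/5.1e14 = -0.294e-14
  expect_equal(mean(tab$rf_alpha_e14), -100 * 0.015 / 5.1e14 * 1e14,
               tolerance = 1e-3)
  # additivity holds every month
  expect_equal(tab$rf_total_e14, tab$rf_alpha_e14 + tab$rf_nee_cum_e14,
               tolerance = 1e-12)
  # cumulative CO2 term: 365 days x -0.2 g C m-2 d-1 by year end
  chi <- cumulative_delta_chi(-0.2 * 365)
  expect_equal(tab$rf_nee_cum_e14[12], rf_delta_nee(chi) * 1e14,
               tolerance = 1e-6)
})
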