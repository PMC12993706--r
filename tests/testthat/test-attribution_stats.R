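test_that("DTW equals the exhaustive-path oracle on short series", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3))$distance, 0)
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1))$distance, 3)
  set.seed(12)
  for (rep in 1:200) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    a <- round(rnorm(n), 2); b <- round(rnorm(m), 2)
    got <- dtw_distance(a, b)
    expect_equal(got$distance, dtw_brute_force(a, b), tolerance = 1e-12)
    expect_equal(got$distance, dtw_distance(b, a)$distance,
                 tolerance = 1e-12)  # symmetric
  }
  expect_true(is.na(dtw_distance(c(1, 2), c(1, 2, 3))$distance))
})

test_that("gap handling splits series and length-weights segments", {
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  whole <- dtw_segments(a, b)
  expect_equal(whole, dtw_distance(a, b)$distance /
                 dtw_distance(a, b)$path_length)
  a2 <- a; a2[15] <- NA
  seg1 <- dtw_distance(a[1:14], b[1:14]); seg2 <- dtw_distance(a[16:30], b[16:30])
  expected <- (seg1$distance / seg1$path_length * 14 +
                 seg2$distance / seg2$path_length * 15) / 29
  expect_equal(dtw_segments(a2, b), expected)
  expect_true(is.na(dtw_segments(rep(NA_real_, 10), b[1:10])))
})

test_that("component ranking identifies constructed temporal matches", {
  set.seed(9)
  n <- 40
  target <- sin(seq(0, 4 * pi, length.out = n)) + rnorm(n, 0, 0.05)
  decomp <- data.frame(
    date = as.Date("2020-01-01") + 0:(n - 1),
    season = "winter", dts_cal = target, kept = TRUE,
    d_alpha = rnorm(n, 0, 1),
    d_swdr = rnorm(n, 0, 1),
    d_lwdr = -target,                    # sign-flipped
    d_eps = target + 0.3,                # constant offset
    d_le = rnorm(n, 0, 1),
    d_h = rnorm(n, 0, 1),
    d_g = target,                        # identical
    d_i = rnorm(n, 0, 1)
  )
  rep <- normalized_component_ranking(decomp, "season", min_days = 10)
  expect_equal(sort(rep$rank), 1:8)      # ranks are a permutation
  expect_true(all(rep$normalized >= 0 & rep$normalized <= 1))
  expect_equal(rep$component[rep$rank == 1], "d_g")
  expect_equal(rep$normalized[rep$component == "d_g"], 0)
  # constant offset is temporally closer than the sign flip
  expect_lt(rep$raw_distance[rep$component == "d_eps"],
            rep$raw_distance[rep$component == "d_lwdr"])

  # scale-order preservation: affine rescaling of the series rescales raw
  # distances but leaves ranks unchanged
  decomp2 <- decomp
  for (c in c("dts_cal", "d_alpha", "d_swdr", "d_lwdr", "d_eps", "d_le",
              "d_h", "d_g", "d_i")) decomp2[[c]] <- 3 * decomp2[[c]]
  rep2 <- normalized_component_ranking(decomp2, "season", min_days = 10)
  expect_equal(rep2$rank, rep$rank)
  expect_equal(rep2$normalized, rep$normalized, tolerance = 1e-12)

  expect_null(normalized_component_ranking(decomp[1:5, ], "season", 10))
})

test_that("soil heat flux tracks dTs_cal at the understory on generated data", {
  rec <- noisy_records()
  cal <- test_calendar()
  st_t <- daily_site_state(site_layer(rec, "NPT", "understory"), 39.94)
  st_c <- daily_site_state(site_layer(rec, "CT", "understory"), 39.94)
  dc <- decomposition_daily(st_t, st_c, cal)
  rep <- normalized_component_ranking(dc, "season", 10)
  top <- rep$component[rep$rank == 1]
  expect_true("d_g" %in% top)
})

test_that("seasonal tests pick branches and flag known effects", {
  # identical distributions: one shared letter
  set.seed(21)
  v <- rnorm(150); s <- rep(c("CT", "NT", "NPT"), each = 50)
  res <- seasonal_group_test(v, s)
  expect_true(res$p_value > 0.05 || length(unique(res$letters)) == 1)
  expect_equal(length(unique(res$letters)), 1)

  # a 3-SD shifted third group is always flagged and distinctly lettered
  v2 <- c(rnorm(50), rnorm(50), rnorm(50, 3))
  res2 <- seasonal_group_test(v2, s)
  expect_lt(res2$p_value, 0.05)
  expect_false(res2$letters["NPT"] %in% res2$letters[c("CT", "NT")])
  expect_equal(unname(res2$letters["CT"]), unname(res2$letters["NT"]))

  # heavy-tailed data select the rank-based branch
  v3 <- c(rcauchy(50), rcauchy(50), rcauchy(50))
  res3 <- seasonal_group_test(v3, s)
  expect_equal(res3$test, "Kruskal-Wallis")

  expect_null(seasonal_group_test(rnorm(10), rep(c("A", "B"), 5)))
})

test_that("type-I error stays near nominal over null simulations", {
  set.seed(31)
  n_sim <- 1000
  rejections <- 0L
  s <- rep(c("CT", "NT", "NPT"), each = 30)
  for (i in seq_len(n_sim)) {
    v <- rnorm(90)
    res <- seasonal_group_test(v, s)
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_sim, 0.07)
})
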