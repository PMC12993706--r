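# Synthetic dual-layer tower generator. Three co-located sites (CT control,
# NT, NPT treated) x two layers (ecosystem, understory) with seasonal
# phenology, diurnal solar forcing, injected treatment effects, rain events
# and gaps. Construction keeps the surface energy budget exactly consistent
# with the stored fluxes so the temperature decomposition has a known truth.

#' Potential (top-of-atmosphere projected) solar radiation
#'
#' Clear-sky upper bound used for the clear-sky index and the day/night
#' split: the solar constant projected on a horizontal surface from standard
#' solar-position geometry (declination from day of year, hour angle about
#' local solar noon at 12:00).
#'
#' @param latitude decimal degrees, in [-90, 90].
#' @param doy day of year (1-366).
#' @param hour decimal local hour.
#' @param S0 solar constant (W m-2).
#' @return potential radiation (W m-2); 0 when the sun is below the horizon.
#' @export
potential_radiation <- function(latitude, doy, hour, S0 = 1361) {
  stopifnot(all(abs(latitude) <= 90))
  phi <- latitude * pi / 180
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  ha <- (hour - 12) * 15 * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  S0 * pmax(0, cosz)
}

#' Scenario specification for the synthetic towers
#'
#' Defines seasonal baselines, layer properties, per-site injected treatment
#' effects, noise levels and event rates. Defaults emulate a semi-arid
#' Mediterranean tree-grass system: five phenological seasons with a spring
#' productivity peak and a dry summer; treated sites brighter (positive
#' albedo offsets), stronger carbon uptake (negative NEE offsets), a shifted
#' evaporative fraction, and a surface-temperature offset that cools the
#' treated ecosystem but warms the treated understory.
#'
#' @param seed integer RNG seed; generation is bit-reproducible given it.
#' @param n_years number of years generated from \code{start}.
#' @param start first day (period-end stamps begin at 00:30 that day).
#' @param latitude site latitude (decimal degrees).
#' @param seasons data.frame of per-season baselines (see defaults):
#'   mean/diurnal-amplitude air temperature (degC), midday VPD scale (kPa),
#'   light-saturated GPP (umol m-2 s-1), respiration (umol m-2 s-1),
#'   evaporative fraction, and albedo per layer.
#' @param layers named list of per-layer physics: energy-balance closure
#'   fraction, soil-heat-flux share of net radiation, mean wind speed,
#'   friction-velocity ratio, and which albedo column applies.
#' @param effects data.frame of injected treatment effects per site x layer:
#'   \code{delta_alpha} (albedo offset), \code{delta_nee} (g C m-2 d-1 NEE
#'   offset, negative = extra uptake), \code{ef_shift} (evaporative-fraction
#'   repartition), \code{ts_offset} (degC surface-temperature offset).
#' @param noise named list of noise standard deviations (relative for SWDR
#'   and the albedo ratio, absolute otherwise); set all to 0 for the
#'   noise-free construction.
#' @param gap_fraction fraction of half-hours whose measurements are dropped.
#' @param rain_freq probability a day is rainy.
#' @param rain_depth mean daily rain depth (mm) on rainy days.
#' @param transmissivity clear-sky atmospheric transmissivity applied to
#'   potential radiation.
#' @return list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(seed = 1L, n_years = 2, start = "2015-01-01",
                          latitude = 39.94,
                          seasons = default_season_baselines(),
                          layers = default_layer_params(),
                          effects = default_treatment_effects(),
                          noise = list(swdr_rel = 0.03, albedo_rel = 0.02,
                                       flux = 12, tair = 0.3, nee = 1.2,
                                       met = 0.05),
                          gap_fraction = 0.08,
                          rain_freq = 0.10,
                          rain_depth = 4,
                          transmissivity = 0.75) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1,
            rain_freq >= 0, rain_freq <= 1,
            all(vapply(layers, function(l) l$closure > 0 && l$closure <= 1,
                       logical(1))))
  ab <- outer(c(seasons$albedo_ecosystem, seasons$albedo_understory),
              effects$delta_alpha, "+")
  stopifnot(all(ab > 0 & ab < 1))
  structure(list(seed = as.integer(seed), n_years = n_years,
                 start = as.Date(start), latitude = latitude,
                 seasons = seasons, layers = layers, effects = effects,
                 noise = noise, gap_fraction = gap_fraction,
                 rain_freq = rain_freq, rain_depth = rain_depth,
                 transmissivity = transmissivity),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
default_season_baselines <- function() {
  data.frame(
    season    = c("autumn", "winter", "spring", "drydown", "summer"),
    Tair_mean = c(13, 8, 14, 21, 27),
    Tair_amp  = c(7, 6, 9, 11, 13),
    VPD_base  = c(0.8, 0.5, 1.0, 2.2, 3.5),
    Pmax      = c(10, 6, 18, 8, 2.5),
    Reco      = c(2.5, 1.5, 3.0, 2.2, 1.2),
    EF        = c(0.50, 0.55, 0.60, 0.35, 0.15),
    albedo_ecosystem  = c(0.185, 0.180, 0.190, 0.200, 0.210),
    albedo_understory = c(0.195, 0.190, 0.200, 0.215, 0.230),
    stringsAsFactors = FALSE
  )
}

#' @rdname scenario_spec
#' @export
default_layer_params <- function() {
  list(
    ecosystem  = list(closure = 0.88, g_frac = 0.10, u_mean = 2.5,
                      ustar_frac = 0.14, albedo_col = "albedo_ecosystem",
                      ts_gain = 8),
    understory = list(closure = 0.60, g_frac = 0.22, u_mean = 1.2,
                      ustar_frac = 0.12, albedo_col = "albedo_understory",
                      ts_gain = 11)
  )
}

#' @rdname scenario_spec
#' @export
default_treatment_effects <- function() {
  data.frame(
    site        = rep(c("CT", "NT", "NPT"), each = 2),
    layer       = rep(c("ecosystem", "understory"), 3),
    delta_alpha = c(0, 0, 0.015, 0.017, 0.013, 0.015),
    delta_nee   = c(0, 0, -0.20, -0.15, -0.25, -0.30),
    ef_shift    = c(0, 0, 0.05, 0.02, 0.02, 0.06),
    ts_offset   = c(0, 0, -0.41, 0.63, 0.03, 0.80),
    stringsAsFactors = FALSE
  )
}

#' Injected-effect truth table
#'
#' Exact injected treatment effects per site and layer, for
#' parameter-recovery tests against pipeline estimates.
#'
#' @param scenario a \code{\link{scenario_spec}}.
#' @return data.frame with site, layer, delta_alpha, delta_nee, ef_shift,
#'   ts_offset.
#' @export
truth_table <- function(scenario) {
  scenario$effects
}

# internal: the half-hourly time grid shared by all sites and layers
.scenario_grid <- function(scenario) {
  start <- as.POSIXct(paste(scenario$start, "00:30"), tz = "UTC")
  end_day <- seq(scenario$start, by = paste(scenario$n_years, "years"),
                 length.out = 2)[2] - 1
  n_days <- as.integer(end_day - scenario$start) + 1L
  ts <- start + 1800 * (seq_len(n_days * 48L) - 1L)
  mid <- as.numeric(ts) - 900
  date <- as.Date(as.POSIXct(mid, origin = "1970-01-01", tz = "UTC"))
  list(timestamp = ts, date = date,
       doy = as.integer(strftime(date, "%j")),
       hour = (mid %% 86400) / 3600,
       n_days = n_days)
}

#' Generate the half-hourly synthetic dataset
#'
#' Deterministic given the scenario seed. The control site carries the
#' seasonal baselines; treated sites add the injected offsets. By
#' construction SWUR = albedo x SWDR, LWUR = sigma eps(albedo) Ts^4 with the
#' emissivity-albedo relation used by the retrieval, and LE + H + G equals
#' the layer's closure fraction times the available energy Rn - G at every
#' half-hour, so the closure diagnostic recovers the parameter and the
#' residual imbalance is exactly (1 - closure) x (Rn - G) before noise; with
#' closure 1 the budget closes identically.
#'
#' @param scenario a \code{\link{scenario_spec}}.
#' @param const \code{\link{physical_constants}}.
#' @return data.frame of half-hourly records for 3 sites x 2 layers, in the
#'   same column layout as \code{\link{read_halfhourly_csv}}.
#' @export
generate_halfhourly <- function(scenario, const = physical_constants()) {
  set.seed(scenario$seed)
  g <- .scenario_grid(scenario)
  cal <- default_season_calendar(
    seq(as.integer(format(scenario$start, "%Y")) - 1L,
        length.out = scenario$n_years + 2L))
  season <- assign_seasons(g$date, cal)
  si <- match(season, scenario$seasons$season)
  sb <- scenario$seasons

  sw_pot <- potential_radiation(scenario$latitude, g$doy, g$hour,
                                const$solar_constant)
  # shared weather draws (identical across sites: co-located towers)
  rain_day <- stats::runif(g$n_days) < scenario$rain_freq
  depth <- stats::rexp(g$n_days, 1 / max(scenario$rain_depth, 1e-9))
  day_idx <- as.integer(g$date - g$date[1]) + 1L
  rainy <- rain_day[day_idx]
  # rain falls on six afternoon half-hours of a rainy day
  rain_slot <- g$hour >= 15 & g$hour < 18
  precip <- ifelse(rainy & rain_slot, depth[day_idx] / 6, 0)
  cloud <- ifelse(rainy, 0.3, 1)

  swdr_base <- scenario$transmissivity * sw_pot * cloud
  tair_base <- sb$Tair_mean[si] +
    (sb$Tair_amp[si] / 2) * (-cos(2 * pi * (g$hour - 2) / 24))
  nz <- scenario$noise

  out <- vector("list", 6L)
  k <- 0L
  for (site in c("CT", "NT", "NPT")) {
    for (layer in names(scenario$layers)) {
      k <- k + 1L
      lp <- scenario$layers[[layer]]
      eff <- scenario$effects[scenario$effects$site == site &
                                scenario$effects$layer == layer, ]
      stopifnot(nrow(eff) == 1)
      n <- length(sw_pot)

      swdr <- swdr_base * (1 + stats::rnorm(n, 0, nz$swdr_rel))
      alpha <- sb[[lp$albedo_col]][si] + eff$delta_alpha
      swur <- alpha * swdr * (1 + stats::rnorm(n, 0, nz$albedo_rel))
      tair <- tair_base + stats::rnorm(n, 0, nz$tair)
      ts_c <- tair + lp$ts_gain * swdr / 1000 + eff$ts_offset
      eps <- emissivity_from_albedo(alpha)
      lwur <- const$sigma * eps * (ts_c + 273.15)^4
      lwdr <- const$sigma * ifelse(rainy, 0.92, 0.76) * (tair + 273.15)^4
      rn <- swdr - swur + lwdr - lwur

      g_comb <- lp$g_frac * rn
      turb <- lp$closure * (rn - g_comb)
      ef <- pmin(0.95, pmax(0.02, sb$EF[si] + eff$ef_shift))
      # EF applies at all hours; negative night-time LE plays dewfall
      le <- ef * turb
      h <- turb - le
      le <- le + stats::rnorm(n, 0, nz$flux)
      h <- h + stats::rnorm(n, 0, nz$flux)
      # open vs below-canopy sensors differ but their weighted mean is exact
      g_canopy <- 0.6 * g_comb
      g_open <- (g_comb - 0.2 * g_canopy) / 0.8

      gpp <- sb$Pmax[si] * 0.06 * swdr / (0.06 * swdr + sb$Pmax[si])
      nee_off <- eff$delta_nee * 1e6 / (const$M_C * 86400)
      gpp <- gpp - nee_off
      reco <- sb$Reco[si]
      nee <- reco - gpp + stats::rnorm(n, 0, nz$nee)

      vpd <- pmax(0.05, sb$VPD_base[si] * (0.3 + 0.7 * swdr / 1000) +
                    stats::rnorm(n, 0, nz$met))
      u <- pmax(0.2, lp$u_mean * (0.7 + 0.6 * swdr / 1000) +
                  stats::rnorm(n, 0, nz$met))
      ustar <- lp$ustar_frac * u

      rec <- data.frame(
        timestamp = g$timestamp, site_id = site, layer = layer,
        NEE = nee, GPP = pmax(gpp, 0), Reco = reco,
        LE = le, H = h, G_open = g_open, G_canopy = g_canopy,
        SWDR = swdr, SWUR = swur, LWDR = lwdr, LWUR = lwur,
        Tair = tair, VPD = vpd, pressure = 95.0, precip = precip,
        u = u, ustar = ustar, qc_nee = 0,
        stringsAsFactors = FALSE
      )
      if (scenario$gap_fraction > 0) {
        gap <- stats::runif(n) < scenario$gap_fraction
        for (col in .hh_numeric_cols) rec[[col]][gap] <- NA_real_
      }
      out[[k]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Write a full synthetic scenario to disk
#'
#' One CSV per site x layer in the dialect \code{\link{read_halfhourly_csv}}
#' reads, plus the truth table as CSV.
#'
#' @param scenario a \code{\link{scenario_spec}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_halfhourly(scenario)
  paths <- character(0)
  for (site in unique(recs$site_id)) {
    for (layer in unique(recs$layer)) {
      p <- file.path(dir, sprintf("%s_%s.csv", site, layer))
      write_halfhourly_csv(recs[recs$site_id == site & recs$layer == layer, ], p)
      paths <- c(paths, p)
    }
  }
  tp <- file.path(dir, "truth_table.csv")
  utils::write.csv(truth_table(scenario), tp, row.names = FALSE)
  invisible(c(paths, tp))
}
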