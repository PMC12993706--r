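# Surface temperature from outgoing longwave and the first-order Taylor
# decomposition of the daily between-site temperature difference into
# radiative (albedo, incoming shortwave/longwave, emissivity) and
# non-radiative (latent, sensible, soil heat, residual) components, all in
# temperature units.

#' Surface emissivity from albedo
#'
#' Empirical linear relation eps = -0.16 * albedo + 0.99.
#'
#' @param albedo surface albedo in (0, 1).
#' @return emissivity; NA where albedo is outside (0, 1) or missing.
#' @export
emissivity_from_albedo <- function(albedo) {
  eps <- -0.16 * albedo + 0.99
  eps[is.na(albedo) | albedo <= 0 | albedo >= 1] <- NA_real_
  eps
}

#' Radiometric surface temperature from outgoing longwave
#'
#' Inverts the Stefan-Boltzmann law LWUR = sigma * eps * Ts^4. No
#' reflected-downwelling correction is applied.
#'
#' @param LWUR outgoing longwave (W m-2), positive.
#' @param eps surface emissivity in (0, 1].
#' @param sigma Stefan-Boltzmann constant.
#' @return surface temperature (K); NA for non-positive LWUR or invalid eps.
#' @export
ts_from_lwur <- function(LWUR, eps, sigma = physical_constants()$sigma) {
  ts <- (LWUR / (sigma * eps))^0.25
  ts[is.na(LWUR) | LWUR <= 0 | is.na(eps) | eps <= 0 | eps > 1] <- NA_real_
  ts
}

#' Residual energy-budget imbalance
#'
#' I = Rn - LE - H - G with Rn = SWDR - SWUR + LWDR - LWUR. Collects energy
#' not captured by the turbulent and soil fluxes: storage, photosynthesis,
#' and systematic/random flux errors.
#'
#' @param SWDR,SWUR,LWDR,LWUR radiation streams (W m-2).
#' @param LE,H,G turbulent and soil fluxes (W m-2).
#' @return residual (W m-2); NA where any input is NA.
#' @export
residual_imbalance <- function(SWDR, SWUR, LWDR, LWUR, LE, H, G) {
  (SWDR - SWUR + LWDR - LWUR) - LE - H - G
}

#' Observed surface-temperature difference
#'
#' @param ts_treated,ts_control daily surface temperatures (K).
#' @return treated minus control (degC difference).
#' @export
delta_ts_obs <- function(ts_treated, ts_control) {
  ts_treated - ts_control
}

#' Decompose a daily surface-temperature difference
#'
#' First-order Taylor decomposition of the between-site temperature
#' difference about the control site's daily state. With denominator
#' D = 4 sigma eps Ts^3 the components are
#' \itemize{
#'   \item d_alpha = -SWDR * dalpha / D
#'   \item d_swdr = (1 - alpha) * dSWDR / D
#'   \item d_lwdr = dLWDR / D
#'   \item d_le = -dLE / D, d_h = -dH / D, d_g = -dG / D, d_i = -dI / D
#'   \item d_eps = -sigma Ts^4 deps / D = -Ts deps / (4 eps)
#' }
#' where every d-quantity is treated minus control and the reference SWDR,
#' alpha, eps and Ts (K) are the control site's daily means. The stored
#' components sum to \code{dts_cal} to machine precision.
#'
#' @param treated,control one-row data.frames (or lists) of daily means with
#'   elements SWDR, LWDR, LE, H, G, I, albedo, ts (K).
#' @param const \code{\link{physical_constants}}.
#' @return one-row data.frame with dts_obs, dts_cal, the eight components
#'   (degC), and the reference ts and eps.
#' @export
decompose_delta_ts <- function(treated, control,
                               const = physical_constants()) {
  eps_t <- emissivity_from_albedo(treated$albedo)
  eps_c <- emissivity_from_albedo(control$albedo)
  ts <- control$ts
  need <- c(control$SWDR, control$albedo, eps_c, eps_t, ts,
            treated$SWDR, treated$LWDR, control$LWDR,
            treated$LE, control$LE, treated$H, control$H,
            treated$G, control$G, treated$I, control$I)
  if (anyNA(need)) {
    return(data.frame(dts_obs = NA_real_, dts_cal = NA_real_,
                      d_alpha = NA_real_, d_swdr = NA_real_,
                      d_lwdr = NA_real_, d_eps = NA_real_, d_le = NA_real_,
                      d_h = NA_real_, d_g = NA_real_, d_i = NA_real_,
                      ref_ts = NA_real_, ref_eps = NA_real_))
  }
  D <- 4 * const$sigma * eps_c * ts^3
  d_alpha <- -control$SWDR * (treated$albedo - control$albedo) / D
  d_swdr <- (1 - control$albedo) * (treated$SWDR - control$SWDR) / D
  d_lwdr <- (treated$LWDR - control$LWDR) / D
  d_le <- -(treated$LE - control$LE) / D
  d_h <- -(treated$H - control$H) / D
  d_g <- -(treated$G - control$G) / D
  d_i <- -(treated$I - control$I) / D
  d_eps <- -const$sigma * ts^4 * (eps_t - eps_c) / D
  dts_cal <- d_alpha + d_swdr + d_lwdr + d_le + d_h + d_g + d_i + d_eps
  data.frame(dts_obs = delta_ts_obs(treated$ts, control$ts),
             dts_cal = dts_cal,
             d_alpha = d_alpha, d_swdr = d_swdr, d_lwdr = d_lwdr,
             d_eps = d_eps, d_le = d_le, d_h = d_h, d_g = d_g, d_i = d_i,
             ref_ts = ts, ref_eps = eps_c)
}

#' Daily site state for the decomposition
#'
#' Builds the per-day state the decomposition consumes from one site-layer's
#' half-hourly records: daily means of the radiation streams and fluxes,
#' soil heat flux combined across sensor groups, the residual imbalance,
#' filtered midday albedo (monthly mean substituted where a day lacks it),
#' surface temperature from outgoing longwave via the albedo-derived
#' emissivity, and the day-flag pass.
#'
#' @param records half-hourly data.frame for one site and layer.
#' @param latitude site latitude.
#' @param config \code{\link{analysis_config}}.
#' @param canopy_fraction soil-heat-flux weighting.
#' @param min_valid_fraction minimum valid half-hours for a daily mean.
#' @return data.frame with one row per day: date, SWDR, SWUR, LWDR, LWUR,
#'   LE, H, G, I, albedo, eps, ts (K), passes flag.
#' @export
daily_site_state <- function(records, latitude, config = analysis_config(),
                             canopy_fraction = 0.2,
                             min_valid_fraction = 0.34) {
  records$G <- combine_soil_heat_flux(records$G_open, records$G_canopy,
                                      canopy_fraction)
  dm <- function(v) resample_daily(records, v, "mean",
                                   min_valid_fraction, config)$value
  base <- resample_daily(records, "SWDR", "mean", min_valid_fraction, config)
  st <- data.frame(date = base$date, SWDR = base$value)
  for (v in c("SWUR", "LWDR", "LWUR", "LE", "H", "G")) st[[v]] <- dm(v)
  st$I <- residual_imbalance(st$SWDR, st$SWUR, st$LWDR, st$LWUR,
                             st$LE, st$H, st$G)

  alb <- midday_albedo_daily(records, latitude, config)
  st$albedo <- alb$albedo[match(st$date, alb$date)]
  mon <- format(st$date, "%Y-%m")
  mon_mean <- tapply(st$albedo, mon, function(a)
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE))
  fill <- is.na(st$albedo)
  st$albedo[fill] <- mon_mean[mon[fill]]
  st$eps <- emissivity_from_albedo(st$albedo)

  # daily Ts: mean of half-hourly inversions using the day's emissivity
  eps_hh <- st$eps[match(.record_date(records), st$date)]
  records$ts_hh <- ts_from_lwur(records$LWUR, eps_hh)
  st$ts <- resample_daily(records, "ts_hh", "mean",
                          min_valid_fraction, config)$value

  fl <- day_flags(records, latitude, config, canopy_fraction)
  st$passes <- fl$passes_missingness[match(st$date, fl$date)]
  st
}

#' Daily decomposition table for a site pair
#'
#' Runs \code{\link{decompose_delta_ts}} on every day both sites pass the
#' day flags, applies the sign/threshold agreement filter, and tags seasons.
#'
#' @param state_treated,state_control outputs of
#'   \code{\link{daily_site_state}} for the treated and control site.
#' @param calendar \code{\link{season_calendar}}.
#' @param config \code{\link{analysis_config}}.
#' @param const \code{\link{physical_constants}}.
#' @return data.frame: date, season, dts_obs, dts_cal, the eight components,
#'   reference state, and the \code{kept} flag.
#' @export
decomposition_daily <- function(state_treated, state_control, calendar,
                                config = analysis_config(),
                                const = physical_constants()) {
  dates <- intersect(state_treated$date, state_control$date)
  dates <- as.Date(dates, origin = "1970-01-01")
  it <- match(dates, state_treated$date)
  ic <- match(dates, state_control$date)
  ok <- !is.na(state_treated$passes[it]) & state_treated$passes[it] &
    !is.na(state_control$passes[ic]) & state_control$passes[ic]
  rows <- lapply(which(ok), function(j) {
    out <- decompose_delta_ts(state_treated[it[j], ], state_control[ic[j], ],
                              const)
    out$date <- dates[j]
    out
  })
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab$season <- assign_seasons(tab$date, calendar)
  tab$kept <- delta_ts_agreement(tab$dts_obs, tab$dts_cal,
                                 config$dts_agreement_threshold)
  tab[, c("date", "season", "dts_obs", "dts_cal", "d_alpha", "d_swdr",
          "d_lwdr", "d_eps", "d_le", "d_h", "d_g", "d_i",
          "ref_ts", "ref_eps", "kept")]
}
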