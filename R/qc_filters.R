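# Data-selection rules applied before the forcing and decomposition stages:
# clear-sky screening of albedo, rain exclusion, day/night missingness
# budgets, the sign/threshold agreement filter on the temperature
# decomposition, and the energy-balance closure diagnostic.

#' Clear-sky index
#'
#' Measured incoming shortwave relative to the expected clear-sky irradiance
#' (transmissivity-scaled potential radiation). Returns NA when the expected
#' irradiance is at or below 20 W m-2 (low-sun guard) or when SWDR is
#' negative or missing.
#'
#' @param SWDR measured incoming shortwave (W m-2).
#' @param SW_pot potential radiation (W m-2), from
#'   \code{\link{potential_radiation}}.
#' @param transmissivity clear-sky atmospheric transmissivity.
#' @return clear-sky index (unitless), NA where undefined.
#' @export
clear_sky_index <- function(SWDR, SW_pot, transmissivity = 0.75) {
  stopifnot(all(SW_pot >= 0, na.rm = TRUE))
  expected <- transmissivity * SW_pot
  csi <- ifelse(expected > 20 & !is.na(SWDR) & SWDR >= 0,
                SWDR / expected, NA_real_)
  csi
}

#' Daily midday albedo
#'
#' Surface albedo as the ratio of outgoing to incoming shortwave, averaged
#' over half-hours in the midday window (default 11:00-14:30) that have a
#' clear-sky index above threshold and SWDR above a floor, on non-rainy days.
#' Ratios outside (0, 1) are discarded. Days with no qualifying half-hour
#' yield NA.
#'
#' @param records half-hourly data.frame for one site and layer.
#' @param latitude site latitude for potential radiation.
#' @param config \code{\link{analysis_config}}.
#' @return data.frame with \code{date}, \code{albedo}, \code{n_halfhours},
#'   \code{is_rainy}.
#' @export
midday_albedo_daily <- function(records, latitude, config = analysis_config()) {
  date <- .record_date(records)
  hour <- .record_hour(records)
  doy <- as.integer(strftime(date, "%j"))
  sw_pot <- potential_radiation(latitude, doy, hour)
  csi <- clear_sky_index(records$SWDR, sw_pot, config$transmissivity)
  ratio <- ifelse(!is.na(records$SWDR) & !is.na(records$SWUR) &
                    records$SWDR > config$swdr_floor,
                  records$SWUR / records$SWDR, NA_real_)
  ratio[!is.na(ratio) & (ratio <= 0 | ratio >= 1)] <- NA_real_
  in_window <- hour >= config$midday_start & hour < config$midday_end
  ok <- in_window & !is.na(csi) & csi > config$clear_sky_threshold &
    !is.na(ratio)

  rain <- tapply(records$precip, date, function(p) any(p > 0, na.rm = TRUE))
  dates <- as.Date(names(rain))
  val <- tapply(ifelse(ok, ratio, NA_real_), date,
                function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  nhh <- tapply(ok, date, sum)
  out <- data.frame(date = dates, albedo = as.numeric(val),
                    n_halfhours = as.integer(nhh),
                    is_rainy = as.logical(rain), row.names = NULL)
  out$albedo[out$is_rainy] <- NA_real_
  out
}

#' Combine open-land and below-canopy soil heat flux
#'
#' Ecosystem-scale soil heat flux as the canopy-cover-weighted mean of the
#' below-canopy and open-land sensor groups.
#'
#' @param G_open,G_canopy soil heat flux (W m-2) in the open and below the
#'   tree canopy.
#' @param canopy_fraction tree canopy cover fraction in [0, 1].
#' @return weighted soil heat flux; NA where either input is NA.
#' @export
combine_soil_heat_flux <- function(G_open, G_canopy, canopy_fraction = 0.2) {
  stopifnot(canopy_fraction >= 0, canopy_fraction <= 1)
  canopy_fraction * G_canopy + (1 - canopy_fraction) * G_open
}

#' Per-day quality flags
#'
#' Rain occurrence and day/night missingness of the variables the
#' temperature decomposition needs (LE, H, G, four radiation streams). The
#' day/night split uses potential radiation > 0. A day passes when neither
#' the night-time nor the daytime missing fraction exceeds the configured
#' maxima and the day is not rainy.
#'
#' @param records half-hourly data.frame for one site and layer.
#' @param latitude site latitude.
#' @param config \code{\link{analysis_config}}.
#' @param canopy_fraction used to combine the soil-heat-flux sensors when
#'   assessing their availability.
#' @return data.frame with date, is_rainy, night/day missing fractions, and
#'   \code{passes_missingness}.
#' @export
day_flags <- function(records, latitude, config = analysis_config(),
                      canopy_fraction = 0.2) {
  date <- .record_date(records)
  hour <- .record_hour(records)
  doy <- as.integer(strftime(date, "%j"))
  is_day <- potential_radiation(latitude, doy, hour) > 0
  g <- combine_soil_heat_flux(records$G_open, records$G_canopy, canopy_fraction)
  need <- cbind(records$LE, records$H, g,
                records$SWDR, records$SWUR, records$LWDR, records$LWUR)
  missing_hh <- rowSums(is.na(need)) > 0

  frac <- function(m) if (length(m) == 0) 0 else mean(m)
  sp_day <- split(missing_hh[is_day], date[is_day])
  sp_night <- split(missing_hh[!is_day], date[!is_day])
  dates <- sort(unique(date))
  day_miss <- vapply(as.character(dates), function(d)
    frac(sp_day[[d]]), numeric(1))
  night_miss <- vapply(as.character(dates), function(d)
    frac(sp_night[[d]]), numeric(1))
  rain <- vapply(split(records$precip, date),
                 function(p) any(p > 0, na.rm = TRUE), logical(1))
  day_miss[is.na(day_miss)] <- 0; night_miss[is.na(night_miss)] <- 0
  data.frame(
    date = dates,
    is_rainy = as.logical(rain),
    night_missing_fraction = unname(night_miss),
    day_missing_fraction = unname(day_miss),
    passes_missingness = unname(!rain &
                                  night_miss <= config$max_missing_night &
                                  day_miss <= config$max_missing_day),
    row.names = NULL
  )
}

#' Sign/threshold agreement filter for the temperature decomposition
#'
#' A day is retained when the observed and calculated surface-temperature
#' differences have identical signs and differ by less than the threshold.
#' Exact zero agrees with either sign. NA in either input drops the day.
#'
#' @param dts_obs,dts_cal observed and calculated daily surface-temperature
#'   differences (degC).
#' @param threshold agreement threshold (degC), default 2.
#' @return logical vector: TRUE = keep.
#' @export
delta_ts_agreement <- function(dts_obs, dts_cal, threshold = 2) {
  ok <- !is.na(dts_obs) & !is.na(dts_cal)
  same_sign <- sign(dts_obs) == sign(dts_cal) | dts_obs == 0 | dts_cal == 0
  keep <- ok & same_sign & abs(dts_obs - dts_cal) < threshold
  keep[is.na(keep)] <- FALSE
  keep
}

#' Energy-balance closure
#'
#' Closure of the daily surface energy budget: the slope of the no-intercept
#' ordinary-least-squares regression of turbulent flux (LE + H) on available
#' energy (Rn - G), plus the ratio of sums.
#'
#' @param LE,H,Rn,G daily means (W m-2), equal length, NA tolerated.
#' @param min_days minimum complete days required.
#' @return list with \code{slope}, \code{ratio}, \code{n_days}.
#' @export
energy_balance_closure <- function(LE, H, Rn, G, min_days = 30) {
  y <- LE + H
  x <- Rn - G
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_days) {
    stop("energy_balance_closure: need >= ", min_days, " valid days, got ",
         sum(ok))
  }
  fit <- stats::lm(y ~ x + 0, data = data.frame(x = x[ok], y = y[ok]))
  list(slope = unname(stats::coef(fit)[1]),
       ratio = sum(y[ok]) / sum(x[ok]),
       n_days = sum(ok))
}
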