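# Daily ecophysiological diagnostics: water-use efficiency, evaporative
# fraction, bulk aerodynamic conductance from wind statistics, surface
# conductance by Penman-Monteith inversion, and the surface-atmosphere
# decoupling coefficient. Psychrometrics use Magnus-type saturation vapour
# pressure and a linear temperature dependence of the latent heat of
# vaporisation.

#' Psychrometric state of moist air
#'
#' @param Tair air temperature (degC).
#' @param pressure air pressure (kPa).
#' @param const \code{\link{physical_constants}}.
#' @return list with \code{esat} (kPa), \code{slope} (kPa K-1, saturation
#'   curve slope), \code{lambda} (J kg-1, latent heat of vaporisation),
#'   \code{gamma} (kPa K-1, psychrometric constant), \code{rho} (kg m-3, air
#'   density).
#' @export
psychrometrics <- function(Tair, pressure = 101.325,
                           const = physical_constants()) {
  esat <- 0.6108 * exp(17.27 * Tair / (Tair + 237.3))
  slope <- 4098 * esat / (Tair + 237.3)^2
  lambda <- (const$lambda_a + const$lambda_b * Tair) * 1e6
  gamma <- const$Cp * pressure / (const$eps_ratio * lambda)
  rho <- pressure * 1000 / (const$Rd * (Tair + 273.15))
  list(esat = esat, slope = slope, lambda = lambda, gamma = gamma, rho = rho)
}

#' Evapotranspiration from latent heat flux
#'
#' @param LE daily-mean latent heat flux (W m-2).
#' @param Tair daily-mean air temperature (degC), for the latent heat of
#'   vaporisation.
#' @param const \code{\link{physical_constants}}.
#' @return evapotranspiration (kg H2O m-2 d-1).
#' @export
et_from_le <- function(LE, Tair, const = physical_constants()) {
  lambda <- (const$lambda_a + const$lambda_b * Tair) * 1e6
  LE * 86400 / lambda
}

#' Water-use efficiency
#'
#' Daily carbon gain per unit water loss, GPP / ET. Days with ET below the
#' floor yield NA (division guard).
#'
#' @param GPP daily gross primary productivity (g C m-2 d-1).
#' @param ET daily evapotranspiration (kg H2O m-2 d-1).
#' @param et_floor minimum ET (kg m-2 d-1).
#' @return WUE (g C per kg H2O).
#' @export
water_use_efficiency <- function(GPP, ET, et_floor = 0.1) {
  wue <- GPP / ET
  wue[is.na(ET) | ET < et_floor] <- NA_real_
  wue
}

#' Evaporative fraction
#'
#' Share of the turbulent energy flux carried by latent heat,
#' LE / (LE + H), on daytime means. NA below the denominator floor.
#'
#' @param LE,H daytime-mean latent and sensible heat flux (W m-2).
#' @param floor minimum LE + H (W m-2).
#' @return evaporative fraction (unitless).
#' @export
evaporative_fraction <- function(LE, H, floor = 10) {
  den <- LE + H
  ef <- LE / den
  ef[is.na(den) | den <= floor] <- NA_real_
  ef
}

#' Bulk aerodynamic conductance
#'
#' Ga = [u / u*^2 + 6.2 u*^(-2/3)]^-1, combining the momentum-transfer term
#' with the excess resistance of the quasi-laminar boundary layer.
#'
#' @param u wind speed (m s-1).
#' @param ustar friction velocity (m s-1).
#' @return aerodynamic conductance (m s-1); NA for non-positive inputs.
#' @export
aerodynamic_conductance <- function(u, ustar) {
  ga <- 1 / (u / ustar^2 + 6.2 * ustar^(-2 / 3))
  ga[is.na(u) | is.na(ustar) | u <= 0 | ustar <= 0] <- NA_real_
  ga
}

#' Surface conductance by Penman-Monteith inversion
#'
#' Inverts the big-leaf Penman-Monteith equation for the measured latent
#' heat flux:
#' Gs = gamma LE Ga / [slope (Rn - G) + rho Cp VPD Ga - LE (slope + gamma)].
#' Near-zero denominators, negative inversions, and values above a physical
#' ceiling are returned as NA (inversion artifacts).
#'
#' @param LE latent heat flux (W m-2), daytime daily mean.
#' @param Rn,G net radiation and soil heat flux (W m-2).
#' @param VPD vapour pressure deficit (kPa).
#' @param Tair air temperature (degC).
#' @param pressure air pressure (kPa).
#' @param Ga aerodynamic conductance (m s-1).
#' @param gs_max physical ceiling (m s-1).
#' @param const \code{\link{physical_constants}}.
#' @return surface conductance (m s-1).
#' @export
surface_conductance <- function(LE, Rn, G, VPD, Tair, pressure = 101.325,
                                Ga, gs_max = 0.1,
                                const = physical_constants()) {
  p <- psychrometrics(Tair, pressure, const)
  # slope and gamma in kPa K-1, VPD in kPa: rho Cp VPD Ga then carries the
  # same kPa W m-2 K-1 units as slope (Rn - G)
  den <- p$slope * (Rn - G) + p$rho * const$Cp * VPD * Ga - LE * (p$slope + p$gamma)
  gs <- p$gamma * LE * Ga / den
  bad <- is.na(Ga) | Ga <= 0 | is.na(den) | abs(den) < 1 |
    is.na(gs) | gs < 0 | gs > gs_max
  gs[bad & !(!is.na(LE) & LE == 0)] <- NA_real_
  gs[!is.na(LE) & LE == 0 & !is.na(Ga) & Ga > 0] <- 0
  gs
}

#' Forward big-leaf Penman-Monteith latent heat flux
#'
#' LE = [slope (Rn - G) + rho Cp VPD Ga] / [slope + gamma (1 + Ga/Gs)].
#' The inverse of \code{\link{surface_conductance}}; used as the round-trip
#' oracle for the inversion.
#'
#' @param Gs surface conductance (m s-1).
#' @inheritParams surface_conductance
#' @return latent heat flux (W m-2).
#' @export
penman_monteith_le <- function(Gs, Rn, G, VPD, Tair, pressure = 101.325,
                               Ga, const = physical_constants()) {
  p <- psychrometrics(Tair, pressure, const)
  (p$slope * (Rn - G) + p$rho * const$Cp * VPD * Ga) /
    (p$slope + p$gamma * (1 + Ga / Gs))
}

#' Surface-atmosphere decoupling coefficient
#'
#' Omega = (eps + 1) / (eps + 1 + Ga/Gs) with eps the ratio of the
#' saturation-curve slope to the psychrometric constant at air temperature.
#' Near 0 the surface is well coupled to the atmosphere; near 1 it is
#' radiatively decoupled.
#'
#' @param Ga,Gs aerodynamic and surface conductance (m s-1).
#' @param Tair air temperature (degC).
#' @param pressure air pressure (kPa).
#' @param const \code{\link{physical_constants}}.
#' @return decoupling coefficient in (0, 1); NA for non-positive
#'   conductances.
#' @export
decoupling_coefficient <- function(Ga, Gs, Tair, pressure = 101.325,
                                   const = physical_constants()) {
  p <- psychrometrics(Tair, pressure, const)
  eps <- p$slope / p$gamma
  om <- (eps + 1) / (eps + 1 + Ga / Gs)
  om[is.na(Ga) | is.na(Gs) | Ga <= 0 | Gs <= 0] <- NA_real_
  om
}

#' Daily ecophysiology table for one site and layer
#'
#' Computes daily WUE (from summed GPP and ET), daytime evaporative
#' fraction, and daytime-mean aerodynamic/surface conductance and decoupling
#' coefficient. Daytime is potential radiation > 0; conductances
#' additionally require available energy Rn - G > 20 W m-2.
#'
#' @param records half-hourly data.frame for one site and layer.
#' @param latitude site latitude.
#' @param calendar \code{\link{season_calendar}} for season tags.
#' @param config \code{\link{analysis_config}}.
#' @param canopy_fraction soil-heat-flux weighting.
#' @param const \code{\link{physical_constants}}.
#' @return data.frame: date, season, GPP, ET, WUE, EF, Ga, Gs, Omega.
#' @export
ecophys_daily <- function(records, latitude, calendar,
                          config = analysis_config(), canopy_fraction = 0.2,
                          const = physical_constants()) {
  date <- .record_date(records)
  hour <- .record_hour(records)
  doy <- as.integer(strftime(date, "%j"))
  is_day <- potential_radiation(latitude, doy, hour) > 0
  g <- combine_soil_heat_flux(records$G_open, records$G_canopy,
                              canopy_fraction)
  rn <- with(records, SWDR - SWUR + LWDR - LWUR)

  dmean <- function(v, sel = rep(TRUE, length(v)), min_n = 8) {
    out <- tapply(ifelse(sel, v, NA_real_), date, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < min_n) NA_real_ else mean(x)
    })
    as.numeric(out)
  }
  dates <- sort(unique(date))
  gpp_d <- dmean(records$GPP, min_n = 24) * 86400 * const$M_C * 1e-6  # g C m-2 d-1
  le_d <- dmean(records$LE, min_n = 24)
  tair_d <- dmean(records$Tair, min_n = 24)
  et_d <- et_from_le(le_d, tair_d, const)
  wue <- water_use_efficiency(gpp_d, et_d, config$et_floor)

  le_day <- dmean(records$LE, is_day)
  h_day <- dmean(records$H, is_day)
  ef <- evaporative_fraction(le_day, h_day)

  cond <- is_day & !is.na(rn) & !is.na(g) & (rn - g) > 20
  le_cond <- dmean(records$LE, cond)
  u_day <- dmean(records$u, cond)
  ustar_day <- dmean(records$ustar, cond)
  rn_day <- dmean(rn, cond)
  g_day <- dmean(g, cond)
  vpd_day <- dmean(records$VPD, cond)
  tair_day <- dmean(records$Tair, cond)
  p_day <- dmean(records$pressure, cond)
  p_day[is.na(p_day)] <- 101.325

  ga <- aerodynamic_conductance(u_day, ustar_day)
  gs <- surface_conductance(le_cond, rn_day, g_day, vpd_day, tair_day, p_day,
                            ga, config$gs_max, const)
  omega <- decoupling_coefficient(ga, gs, tair_day, p_day, const)

  data.frame(date = dates, season = assign_seasons(dates, calendar),
             GPP = gpp_d, ET = et_d, WUE = wue, EF = ef,
             Ga = ga, Gs = gs, Omega = omega)
}
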