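#' Physical constants used throughout the pipeline
#'
#' Returns the set of physical constants behind the radiative-forcing chain
#' and the surface-temperature decomposition. Values follow the conventions of
#' the flux-tower forcing literature: the CO2 radiative-efficiency coefficient
#' (5.35 W m-2), a fixed airborne fraction, and a fixed 2014 baseline CO2 dry
#' mole fraction.
#'
#' @param ... name-value pairs overriding individual defaults.
#' @return A list with components:
#'   \describe{
#'     \item{sigma}{Stefan-Boltzmann constant (W m-2 K-4).}
#'     \item{m_a}{mass of the atmosphere (g).}
#'     \item{Ma_over_Mc}{molar-mass ratio of air to carbon (unitless), for NEE
#'       expressed in g C.}
#'     \item{beta}{airborne fraction of emitted CO2 (unitless).}
#'     \item{chi0_CO2}{baseline atmospheric CO2 dry mole fraction (ppm).}
#'     \item{rf_coeff}{CO2 radiative-efficiency coefficient (W m-2).}
#'     \item{A_earth}{surface area of the Earth (m2).}
#'     \item{Cp}{specific heat of air at constant pressure (J kg-1 K-1).}
#'     \item{Rd}{specific gas constant of dry air (J kg-1 K-1).}
#'     \item{eps_ratio}{ratio of molar masses of water vapour and dry air
#'       (0.622), used in the psychrometric constant.}
#'     \item{lambda_a, lambda_b}{coefficients of the linear temperature
#'       dependence of the latent heat of vaporisation,
#'       lambda = lambda_a + lambda_b * Tair (MJ kg-1, Tair in degC).}
#'     \item{solar_constant}{top-of-atmosphere solar irradiance (W m-2).}
#'     \item{M_C, M_CO2}{molar masses of carbon and CO2 (g mol-1).}
#'   }
#' @export
physical_constants <- function(...) {
  const <- list(
    sigma          = 5.670374419e-8,
    m_a            = 5.15e21,
    Ma_over_Mc     = 2.414,
    beta           = 0.44,
    chi0_CO2       = 399.4,
    rf_coeff       = 5.35,
    A_earth        = 5.1e14,
    Cp             = 1004.834,
    Rd             = 287.058,
    eps_ratio      = 0.622,
    lambda_a       = 2.501,
    lambda_b       = -0.00237,
    solar_constant = 1361,
    M_C            = 12.011,
    M_CO2          = 44.009
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(const))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    const[names(over)] <- over
  }
  stopifnot(all(vapply(const, function(x) is.numeric(x) && x != 0, logical(1))))
  const
}

#' Analysis configuration
#'
#' Bundles the data-selection thresholds and numerical settings used by the
#' quality-control, decomposition, and attribution stages.
#'
#' @param midday_start,midday_end decimal hours delimiting the midday albedo
#'   window (period-end convention), default 11.0 to 14.5.
#' @param clear_sky_threshold minimum clear-sky index for albedo half-hours.
#' @param swdr_floor minimum incoming shortwave (W m-2) for an albedo ratio.
#' @param dts_agreement_threshold maximum |dTs_obs - dTs_cal| (degC) retained
#'   by the sign/threshold agreement filter.
#' @param max_missing_night,max_missing_day maximum tolerated missing fraction
#'   of night-time / daytime half-hours per day.
#' @param transmissivity atmospheric transmissivity scaling potential
#'   radiation into the expected clear-sky irradiance.
#' @param min_albedo_days minimum filtered albedo days required to form a
#'   monthly mean albedo difference.
#' @param gs_max physical upper bound for surface conductance (m s-1);
#'   inversions above it are treated as artifacts.
#' @param et_floor minimum daily evapotranspiration (kg m-2 d-1) for a
#'   water-use-efficiency ratio.
#' @param alpha significance level for the seasonal tests.
#' @param dtw_min_days minimum kept days per group for a DTW ranking.
#' @return A list of class \code{ecoforcing_config}.
#' @export
analysis_config <- function(midday_start = 11.0, midday_end = 14.5,
                            clear_sky_threshold = 0.7,
                            swdr_floor = 50,
                            dts_agreement_threshold = 2,
                            max_missing_night = 0.66, max_missing_day = 0.66,
                            transmissivity = 0.75,
                            min_albedo_days = 3,
                            gs_max = 0.1,
                            et_floor = 0.1,
                            alpha = 0.05,
                            dtw_min_days = 10) {
  stopifnot(
    midday_start >= 0, midday_end <= 24, midday_start < midday_end,
    clear_sky_threshold > 0, clear_sky_threshold < 1,
    max_missing_night > 0, max_missing_night < 1,
    max_missing_day > 0, max_missing_day < 1,
    transmissivity > 0, transmissivity <= 1,
    dts_agreement_threshold > 0, alpha > 0, alpha < 1
  )
  structure(list(
    midday_start = midday_start, midday_end = midday_end,
    clear_sky_threshold = clear_sky_threshold,
    swdr_floor = swdr_floor,
    dts_agreement_threshold = dts_agreement_threshold,
    max_missing_night = max_missing_night,
    max_missing_day = max_missing_day,
    transmissivity = transmissivity,
    min_albedo_days = min_albedo_days,
    gs_max = gs_max,
    et_floor = et_floor,
    alpha = alpha,
    dtw_min_days = dtw_min_days
  ), class = "ecoforcing_config")
}

#' Site metadata
#'
#' @param site_id site identifier (e.g. "CT", "NT", "NPT").
#' @param latitude,longitude site coordinates in decimal degrees.
#' @param canopy_fraction tree canopy cover fraction used to combine the
#'   open-land and below-canopy soil-heat-flux sensors.
#' @param treatment_start Date of first nutrient addition.
#' @param A_site treated surface area (m2); 1 m2 gives per-square-metre
#'   forcing.
#' @return A list of class \code{site_meta}.
#' @export
site_meta <- function(site_id, latitude = 39.94, longitude = -5.77,
                      canopy_fraction = 0.2,
                      treatment_start = as.Date("2015-03-01"),
                      A_site = 1.0) {
  stopifnot(canopy_fraction >= 0, canopy_fraction <= 1, A_site > 0,
            abs(latitude) <= 90)
  structure(list(site_id = site_id, latitude = latitude, longitude = longitude,
                 canopy_fraction = canopy_fraction,
                 treatment_start = as.Date(treatment_start),
                 A_site = A_site),
            class = "site_meta")
}
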