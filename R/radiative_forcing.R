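# Top-of-atmosphere radiative forcing of the treatment: the albedo term via
# monthly albedo radiative kernels, and the CO2 term via cumulative NEE
# differences propagated into an atmospheric mole-fraction perturbation.
# Units: forcing is W m-2 (global) per m-2 of treated surface; tables report
# it scaled by 1e14 following the flux-site forcing literature.

#' Read a monthly albedo-kernel series from CSV
#'
#' Kernel files give the top-of-atmosphere shortwave flux sensitivity to a
#' unit change in surface albedo, one value per calendar month, at the site
#' location. Accepted columns: \code{model}, \code{month} (1-12),
#' \code{kernel}, and optionally \code{units} ("per_unit" or "per_0.01");
#' per-0.01-albedo kernels are normalised to per-unit.
#'
#' @param path CSV path holding one or more models.
#' @return data.frame (class \code{kernel_series}) with model, month, kernel
#'   (W m-2 per unit albedo), complete January-December per model.
#' @export
read_kernel_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("model", "month", "kernel") %in% names(raw)))
  k <- raw$kernel
  if ("units" %in% names(raw)) {
    per001 <- raw$units == "per_0.01"
    k[per001] <- k[per001] * 100
  }
  out <- data.frame(model = raw$model, month = as.integer(raw$month),
                    kernel = as.numeric(k), stringsAsFactors = FALSE)
  for (m in unique(out$model)) {
    mo <- sort(out$month[out$model == m])
    if (!identical(mo, 1:12)) {
      stop("kernel model ", m, " does not cover months 1-12")
    }
  }
  class(out) <- c("kernel_series", "data.frame")
  out
}

#' Ensemble mean and spread of albedo kernels
#'
#' @param kernels \code{kernel_series} data.frame (multiple models).
#' @return data.frame with month, \code{kernel_mean}, \code{kernel_sd} (SD
#'   across models), \code{n_models}.
#' @export
kernel_ensemble <- function(kernels) {
  sp <- split(kernels$kernel, kernels$month)
  data.frame(month = as.integer(names(sp)),
             kernel_mean = vapply(sp, mean, numeric(1)),
             kernel_sd = vapply(sp, stats::sd, numeric(1)),
             n_models = vapply(sp, length, numeric(1)),
             row.names = NULL)
}

#' Atmospheric CO2 mole-fraction perturbation from cumulative NEE change
#'
#' Converts a cumulative NEE difference (treated minus control, g C per m2 of
#' treated surface since treatment start) into the implied change of the
#' global atmospheric CO2 dry mole fraction, discounting by the airborne
#' fraction. Negative NEE (extra uptake) lowers the mole fraction.
#'
#' @param delta_nee_cum cumulative NEE difference (g C m-2).
#' @param A_site treated surface area (m2).
#' @param const \code{\link{physical_constants}}.
#' @return mole-fraction change (dimensionless fraction, not ppm).
#' @export
cumulative_delta_chi <- function(delta_nee_cum, A_site = 1,
                                 const = physical_constants()) {
  const$beta * delta_nee_cum * A_site * const$Ma_over_Mc / const$m_a
}

#' Radiative forcing of the CO2 mole-fraction perturbation
#'
#' Linearised logarithmic CO2 forcing: RF = 5.35 * dchi / chi0, valid for
#' |dchi| much smaller than the baseline chi0 (399.4 ppm). The exact
#' logarithmic form is available via \code{form = "log"} for validation.
#'
#' @param delta_chi mole-fraction change (fraction), from
#'   \code{\link{cumulative_delta_chi}}.
#' @param const \code{\link{physical_constants}}.
#' @param form "linear" (default) or "log".
#' @return forcing (W m-2 global per m-2 treated surface); negative = cooling.
#' @export
rf_delta_nee <- function(delta_chi, const = physical_constants(),
                         form = c("linear", "log")) {
  form <- match.arg(form)
  chi0 <- const$chi0_CO2 * 1e-6
  rel <- abs(delta_chi) / chi0
  if (any(rel > 0.01, na.rm = TRUE)) {
    warning("rf_delta_nee: |delta_chi|/chi0 exceeds 1% somewhere; ",
            "linearisation dubious")
  }
  if (form == "linear") const$rf_coeff * delta_chi / chi0
  else const$rf_coeff * log1p(delta_chi / chi0)
}

#' Radiative forcing of a surface-albedo change
#'
#' TOA forcing of a local albedo difference through the kernel ensemble:
#' RF = -K * dalpha * A_site / A_earth. A brightening (positive dalpha) under
#' a positive kernel cools (negative RF). The kernel-spread SD propagates the
#' same way.
#'
#' @param delta_alpha monthly mean albedo difference (treated minus control).
#' @param kernel_mean ensemble-mean kernel for the month (W m-2 per unit
#'   albedo).
#' @param kernel_sd SD across kernel models (same units), optional.
#' @param A_site treated surface area (m2).
#' @param const \code{\link{physical_constants}}.
#' @return list with \code{rf} and \code{rf_sd} (W m-2 m-2).
#' @export
rf_delta_alpha <- function(delta_alpha, kernel_mean, kernel_sd = 0,
                           A_site = 1, const = physical_constants()) {
  scale <- A_site / const$A_earth
  list(rf = -kernel_mean * delta_alpha * scale,
       rf_sd = abs(kernel_sd * delta_alpha) * scale)
}

#' Combine the albedo and CO2 forcing series
#'
#' Elementwise total forcing per month: the albedo term enters as the
#' current month's value, the CO2 term as the running cumulative sum since
#' the first month after treatment.
#'
#' @param rf_alpha monthly albedo-forcing values (W m-2 m-2), month index
#'   1..m since treatment start.
#' @param rf_nee_monthly monthly (non-cumulative) CO2-forcing increments
#'   aligned with \code{rf_alpha}.
#' @return data.frame with month index, rf_alpha, rf_nee_cum, rf_total.
#' @export
combine_rf <- function(rf_alpha, rf_nee_monthly) {
  if (length(rf_alpha) != length(rf_nee_monthly)) {
    stop("combine_rf: misaligned monthly series (",
         length(rf_alpha), " vs ", length(rf_nee_monthly), ")")
  }
  rf_nee_cum <- cumsum(ifelse(is.na(rf_nee_monthly), 0, rf_nee_monthly))
  data.frame(month_index = seq_along(rf_alpha),
             rf_alpha = rf_alpha,
             rf_nee_cum = rf_nee_cum,
             rf_total = rf_alpha + rf_nee_cum)
}

#' CO2-equivalent emission of the albedo forcing (GWP conversion)
#'
#' Mass of CO2 whose sustained emission per hectare and year, discounted by
#' the airborne fraction and accumulated over the horizon, produces the same
#' mean forcing as the given albedo forcing. Inverts the package's own
#' NEE-to-forcing chain under a continuous-time mean (the horizon-mean
#' forcing of a constant emission rate e equals the forcing of the
#' half-horizon cumulative emission e*H/2). Cooling forcing maps to negative
#' CO2-equivalents (avoided emission).
#'
#' @param rf_alpha_annual annual-mean albedo forcing (W m-2 global per m-2
#'   treated surface).
#' @param horizon time horizon (years), default 100.
#' @param const \code{\link{physical_constants}}.
#' @return CO2-equivalent emission rate (kg CO2 ha-1 yr-1).
#' @export
gwp_delta_alpha <- function(rf_alpha_annual, horizon = 100,
                            const = physical_constants()) {
  stopifnot(horizon > 0)
  chi0 <- const$chi0_CO2 * 1e-6
  # rf per (g C m-2 cumulative): d RF / d NEE_cum
  rf_per_gC <- const$rf_coeff * const$beta * const$Ma_over_Mc /
    (const$m_a * chi0)
  # sustained rate e (g C m-2 yr-1): horizon-mean RF = rf_per_gC * e * H / 2
  e_gC_m2_yr <- rf_alpha_annual / (rf_per_gC * horizon / 2)
  e_gC_m2_yr * (const$M_CO2 / const$M_C) * 1e4 / 1e3  # kg CO2 ha-1 yr-1
}

#' Monthly forcing table for one site pair
#'
#' Aggregates filtered daily albedo differences and daily NEE differences to
#' months since treatment start and runs the full forcing chain.
#'
#' @param daily_albedo_pair data.frame with date, albedo_treated,
#'   albedo_control (filtered midday albedo).
#' @param daily_nee_pair data.frame with date, dnee (treated minus control
#'   daily NEE, g C m-2 d-1).
#' @param kernels ensemble table from \code{\link{kernel_ensemble}}.
#' @param treatment_start Date of first nutrient addition.
#' @param A_site treated area (m2).
#' @param config \code{\link{analysis_config}} (minimum albedo days/month).
#' @param const \code{\link{physical_constants}}.
#' @return data.frame of monthly records: month index, calendar month,
#'   delta_alpha, dnee_monthly (g C m-2 month-1), rf_alpha, rf_alpha_sd,
#'   rf_nee_cum, rf_total, all forcings in 1e-14 W m-2 m-2.
#' @export
monthly_rf_table <- function(daily_albedo_pair, daily_nee_pair, kernels,
                             treatment_start, A_site = 1,
                             config = analysis_config(),
                             const = physical_constants()) {
  treatment_start <- as.Date(treatment_start)
  mon_of <- function(d) {
    (as.integer(format(d, "%Y")) - as.integer(format(treatment_start, "%Y"))) * 12 +
      (as.integer(format(d, "%m")) - as.integer(format(treatment_start, "%m"))) + 1L
  }
  da <- daily_albedo_pair[daily_albedo_pair$date >= treatment_start, ]
  dn <- daily_nee_pair[daily_nee_pair$date >= treatment_start, ]
  da$m <- mon_of(da$date); dn$m <- mon_of(dn$date)
  m_max <- max(c(da$m, dn$m), na.rm = TRUE)

  rows <- lapply(seq_len(m_max), function(m) {
    ai <- da[da$m == m & !is.na(da$albedo_treated) & !is.na(da$albedo_control), ]
    dalpha <- if (nrow(ai) >= config$min_albedo_days) {
      mean(ai$albedo_treated - ai$albedo_control)
    } else NA_real_
    ni <- dn[dn$m == m & !is.na(dn$dnee), ]
    # scale available daily differences to the full month length
    mdate <- seq(treatment_start, by = "month", length.out = m)[m]
    ndays <- as.integer(seq(mdate, by = "month", length.out = 2)[2] - mdate)
    dnee_m <- if (nrow(ni) > 0) mean(ni$dnee) * ndays else 0
    cal_month <- as.integer(format(mdate, "%m"))
    data.frame(month_index = m, calendar_month = cal_month,
               delta_alpha = dalpha, dnee_monthly = dnee_m)
  })
  tab <- do.call(rbind, rows)

  kk <- kernels[match(tab$calendar_month, kernels$month), ]
  rfa <- rf_delta_alpha(tab$delta_alpha, kk$kernel_mean, kk$kernel_sd,
                        A_site, const)
  chi_inc <- cumulative_delta_chi(tab$dnee_monthly, A_site, const)
  rf_nee_inc <- rf_delta_nee(chi_inc, const)
  comb <- combine_rf(ifelse(is.na(rfa$rf), 0, rfa$rf), rf_nee_inc)
  s <- 1e14
  data.frame(month_index = tab$month_index,
             calendar_month = tab$calendar_month,
             delta_alpha = tab$delta_alpha,
             dnee_monthly = tab$dnee_monthly,
             rf_alpha_e14 = rfa$rf * s,
             rf_alpha_sd_e14 = rfa$rf_sd * s,
             rf_nee_cum_e14 = comb$rf_nee_cum * s,
             rf_total_e14 = (ifelse(is.na(rfa$rf), 0, rfa$rf) +
                               comb$rf_nee_cum) * s)
}
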