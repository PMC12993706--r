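# Shared data model: half-hourly tower records are plain data.frames with one
# row per (site, layer, timestamp). Gaps are NA; files use -9999 sentinels in
# the flux-community CSV dialect. Timestamps are period-end local standard
# time throughout.

.hh_numeric_cols <- c("NEE", "GPP", "Reco", "LE", "H", "G_open", "G_canopy",
                      "SWDR", "SWUR", "LWDR", "LWUR", "Tair", "VPD",
                      "pressure", "precip", "u", "ustar", "qc_nee")

#' Read a half-hourly tower CSV
#'
#' Parses a FLUXNET-style half-hourly file for one site and measurement layer.
#' Missing values encoded as -9999 (any trailing decimals) or empty cells
#' become NA. Timestamps must be strictly increasing at 30-min spacing.
#'
#' @param path CSV path with a \code{timestamp} column (\code{YYYY-mm-dd
#'   HH:MM}, period-end local standard time) and any subset of the standard
#'   flux/radiation/meteorology columns.
#' @param site_id,layer identifiers attached to every row; \code{layer} is
#'   \code{"ecosystem"} or \code{"understory"}.
#' @param verbose log parsed/dropped row counts.
#' @return data.frame with columns \code{timestamp} (POSIXct, UTC-stored
#'   local standard time), \code{site_id}, \code{layer}, and the numeric
#'   measurement columns.
#' @export
read_halfhourly_csv <- function(path, site_id, layer, verbose = FALSE) {
  layer <- match.arg(layer, c("ecosystem", "understory"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA", "-9999", "-9999.0"))
  if (!"timestamp" %in% names(raw)) stop("missing 'timestamp' column in ", path)
  ts <- tryCatch(as.POSIXct(raw$timestamp, tz = "UTC"),
                 error = function(e) rep(as.POSIXct(NA), nrow(raw)))
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1], " of ", path)
  }
  dt <- diff(as.numeric(ts))
  if (any(dt <= 0)) {
    stop("non-monotonic or duplicated timestamp at row ",
         which(dt <= 0)[1] + 1L, " of ", path)
  }
  if (any(dt != 1800)) {
    stop("timestamps not at 30-min spacing at row ", which(dt != 1800)[1] + 1L)
  }
  out <- data.frame(timestamp = ts, site_id = site_id, layer = layer,
                    stringsAsFactors = FALSE)
  for (col in .hh_numeric_cols) {
    out[[col]] <- if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  for (col in c("SWDR", "SWUR", "precip", "ustar")) {
    bad <- !is.na(out[[col]]) & out[[col]] < 0
    if (any(bad)) out[[col]][bad] <- NA_real_
  }
  if (verbose) message(nrow(out), " rows parsed from ", basename(path))
  out
}

#' Write a half-hourly tower CSV
#'
#' Canonical serialisation matching \code{\link{read_halfhourly_csv}}:
#' NA encoded as -9999, timestamps as \code{YYYY-mm-dd HH:MM}. The
#' write/read round trip is lossless including gap patterns.
#'
#' @param records data.frame from \code{read_halfhourly_csv} or
#'   \code{\link{generate_halfhourly}}.
#' @param path output path.
#' @export
write_halfhourly_csv <- function(records, path) {
  out <- records[, c("timestamp", .hh_numeric_cols)]
  out$timestamp <- format(records$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  for (col in .hh_numeric_cols) out[[col]][is.na(out[[col]])] <- -9999
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Season calendar from transition dates
#'
#' Builds a lookup from phenological transition dates to the five seasons of
#' the hydrological year (autumn, winter, spring, drydown, summer). Each
#' transition date opens the season named on its row; a day belongs to the
#' most recent transition at or before it (closed-start, open-end intervals).
#'
#' @param transitions data.frame with columns \code{site} (or "all"),
#'   \code{season}, \code{start_date}.
#' @return data.frame of class \code{season_calendar}, sorted by site and
#'   date.
#' @export
season_calendar <- function(transitions) {
  stopifnot(all(c("site", "season", "start_date") %in% names(transitions)))
  cal <- data.frame(site = as.character(transitions$site),
                    season = as.character(transitions$season),
                    start_date = as.Date(transitions$start_date),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(cal$season),
                 c("autumn", "winter", "spring", "drydown", "summer"))
  if (length(bad)) stop("unknown season label(s): ", paste(bad, collapse = ", "))
  cal <- cal[order(cal$site, cal$start_date), ]
  for (s in unique(cal$site)) {
    d <- cal$start_date[cal$site == s]
    if (anyDuplicated(d)) stop("duplicated transition date for site ", s)
  }
  class(cal) <- c("season_calendar", "data.frame")
  cal
}

#' Read a season calendar CSV
#'
#' @param path CSV with columns site, season, start_date.
#' @return \code{\link{season_calendar}} object.
#' @export
read_season_calendar <- function(path) {
  season_calendar(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Default five-season calendar
#'
#' Transition dates typical of a Mediterranean tree-grass system: autumn
#' greenup after the first rains (late September), winter dormancy, spring
#' growth, late-spring drydown, and dry summer. Applied identically to all
#' sites (site = "all").
#'
#' @param years integer vector of calendar years to cover.
#' @return \code{\link{season_calendar}} object.
#' @export
default_season_calendar <- function(years) {
  tpl <- data.frame(
    season = c("winter", "spring", "drydown", "summer", "autumn"),
    md = c("01-01", "02-15", "05-01", "06-15", "09-25"),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(years, function(y) {
    data.frame(site = "all", season = tpl$season,
               start_date = as.Date(paste0(y, "-", tpl$md)),
               stringsAsFactors = FALSE)
  }))
  season_calendar(rows)
}

#' Assign seasons to dated records
#'
#' Maps each record date to exactly one season using the calendar's
#' transition dates; a transition date belongs to the season it opens.
#'
#' @param dates Date vector (or anything coercible via \code{as.Date}).
#' @param calendar a \code{\link{season_calendar}}.
#' @param site site id to look up; falls back to the calendar's "all" rows.
#' @return character vector of season labels, same length as \code{dates}.
#' @export
assign_seasons <- function(dates, calendar, site = "all") {
  dates <- as.Date(dates)
  cal <- calendar[calendar$site == site, ]
  if (nrow(cal) == 0) cal <- calendar[calendar$site == "all", ]
  if (nrow(cal) == 0) stop("calendar has no rows for site ", site)
  cal <- cal[order(cal$start_date), ]
  idx <- findInterval(as.numeric(dates), as.numeric(cal$start_date))
  if (any(idx == 0, na.rm = TRUE)) {
    uncovered <- range(dates[idx == 0])
    stop("dates before calendar coverage: ", uncovered[1], " to ", uncovered[2])
  }
  cal$season[idx]
}

#' Daily aggregation of a half-hourly variable
#'
#' @param records half-hourly data.frame with a \code{timestamp} column.
#' @param variable column name to aggregate.
#' @param aggregator one of \code{"mean"}, \code{"sum"},
#'   \code{"midday-mean"} (mean within the config's midday window).
#' @param min_valid_fraction minimum fraction of non-NA half-hours (of the 48
#'   expected, or of the midday window) required; days below it yield NA.
#'   Sums (precipitation) use available values with a completeness flag.
#' @param config \code{\link{analysis_config}} (for the midday window).
#' @return data.frame with \code{date}, \code{value}, \code{n_valid},
#'   \code{complete}.
#' @export
resample_daily <- function(records, variable, aggregator = "mean",
                           min_valid_fraction = 0.5,
                           config = analysis_config()) {
  aggregator <- match.arg(aggregator, c("mean", "sum", "midday-mean"))
  x <- records[[variable]]
  if (is.null(x)) stop("unknown variable: ", variable)
  # period-end: the half-hour stamped t covers (t-30min, t]
  mid <- as.numeric(records$timestamp) - 900
  date <- as.Date(as.POSIXct(mid, origin = "1970-01-01", tz = "UTC"))
  hour <- (mid %% 86400) / 3600
  if (aggregator == "midday-mean") {
    keep <- hour >= config$midday_start & hour < config$midday_end
    x <- x[keep]; date <- date[keep]
    n_expected <- (config$midday_end - config$midday_start) * 2
  } else {
    n_expected <- 48
  }
  sp <- split(x, date)
  n_valid <- vapply(sp, function(v) sum(!is.na(v)), numeric(1))
  value <- vapply(sp, function(v) {
    if (aggregator == "sum") sum(v, na.rm = TRUE)
    else if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  complete <- n_valid >= min_valid_fraction * n_expected
  if (aggregator != "sum") value[!complete] <- NA_real_
  data.frame(date = as.Date(names(sp)), value = unname(value),
             n_valid = unname(n_valid), complete = unname(complete),
             row.names = NULL)
}

# internal: nominal date/hour helpers shared by QC and decomposition
.record_date <- function(records) {
  mid <- as.numeric(records$timestamp) - 900
  as.Date(as.POSIXct(mid, origin = "1970-01-01", tz = "UTC"))
}
.record_hour <- function(records) {
  ((as.numeric(records$timestamp) - 900) %% 86400) / 3600
}
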