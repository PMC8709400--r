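#' Construct an hourly ozone / meteorology series
#'
#' @param timestamp `POSIXct` vector on an hourly grid (hour starts).
#' @param o3_nl_l Hourly mean ozone mixing ratio, nL/L (ppb), `NA` allowed
#'   for monitor outages.
#' @param t_c,rh_pct,par_umol Optional air temperature (deg C), relative
#'   humidity (%) and photosynthetically active radiation (umol m-2 s-1).
#' @return data.frame of class `hourly_series`.
#' @export
hourly_series <- function(timestamp, o3_nl_l, t_c = NULL, rh_pct = NULL,
                          par_umol = NULL) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct", call. = FALSE)
  }
  if (length(timestamp) != length(o3_nl_l)) {
    stop("timestamp and o3_nl_l must have equal length", call. = FALSE)
  }
  d <- as.numeric(difftime(timestamp[-1], timestamp[-length(timestamp)],
                           units = "hours"))
  if (length(d) && any(abs(d - 1) > 1e-6)) {
    stop("timestamps must be hourly and consecutive", call. = FALSE)
  }
  if (any(o3_nl_l < 0, na.rm = TRUE) || any(is.infinite(o3_nl_l))) {
    stop("ozone values must be finite and >= 0", call. = FALSE)
  }
  out <- data.frame(timestamp = timestamp, o3_nl_l = as.numeric(o3_nl_l))
  if (!is.null(t_c)) out$t_c <- as.numeric(t_c)
  if (!is.null(rh_pct)) out$rh_pct <- as.numeric(rh_pct)
  if (!is.null(par_umol)) out$par_umol <- as.numeric(par_umol)
  class(out) <- c("hourly_series", "data.frame")
  out
}

#' Read an hourly series from CSV
#'
#' Expects columns `timestamp` (ISO 8601, parsed as UTC), `o3_nl_l` and
#' optionally `t_c`, `rh_pct`, `par_umol`.
#'
#' @param path CSV path.
#' @return An [hourly_series()].
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("series file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "o3_nl_l") %in% names(raw))) {
    stop("series CSV needs columns timestamp, o3_nl_l", call. = FALSE)
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC")
  hourly_series(ts, raw$o3_nl_l, t_c = raw$t_c, rh_pct = raw$rh_pct,
                par_umol = raw$par_umol)
}

series_hours <- function(series) as.integer(format(series$timestamp, "%H"))

in_window <- function(series, window) {
  h <- series_hours(series)
  h >= window[1] & h < window[2]
}

#' AOT40 ozone exposure index
#'
#' Accumulated hourly ozone exceedance over a threshold (40 nL/L) during
#' the daylight fumigation window, by default hour starts 07:00-14:00
#' (eight hourly values per day, the 7-15 h fumigation window). Hours with
#' missing ozone are skipped and counted in the coverage report; no
#' gap-filling is attempted.
#'
#' @param series An [hourly_series()].
#' @param threshold Exceedance threshold, nL/L.
#' @param window Length-2 integer `[from, to)` in hours of day.
#' @return List: `aot40_nl_l_h`, `n_window_hours`, `n_used`, `n_missing`.
#' @export
aot40 <- function(series, threshold = 40, window = c(7, 15)) {
  stopifnot(inherits(series, "hourly_series"))
  w <- in_window(series, window)
  if (!any(w)) stop("series contains no in-window hours", call. = FALSE)
  o3 <- series$o3_nl_l[w]
  used <- !is.na(o3)
  list(aot40_nl_l_h = sum(pmax(o3[used] - threshold, 0)),
       n_window_hours = sum(w), n_used = sum(used),
       n_missing = sum(!used))
}

#' Daylight-window and daily mean ozone
#'
#' @param series An [hourly_series()].
#' @param window Length-2 `[from, to)` hours of day.
#' @return Mean of in-window (or all, for [daily_mean()]) non-missing
#'   hourly values, nL/L.
#' @export
window_mean <- function(series, window = c(7, 15)) {
  stopifnot(inherits(series, "hourly_series"))
  w <- in_window(series, window)
  if (!any(w)) stop("series contains no in-window hours", call. = FALSE)
  mean(series$o3_nl_l[w], na.rm = TRUE)
}

#' @rdname window_mean
#' @export
daily_mean <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  if (all(is.na(series$o3_nl_l))) stop("no ozone data", call. = FALSE)
  mean(series$o3_nl_l, na.rm = TRUE)
}

#' Charcoal-filtration efficiency
#'
#' Percent reduction of the filtered-air ozone mean relative to ambient:
#' `100 (1 - mean_cfa / mean_amb)`.
#'
#' @param mean_cfa,mean_amb Window-mean ozone in filtered air and ambient,
#'   nL/L; `mean_amb > 0`.
#' @return Percent.
#' @export
filtration_efficiency <- function(mean_cfa, mean_amb) {
  if (mean_amb <= 0) stop("ambient mean must be > 0", call. = FALSE)
  100 * (1 - mean_cfa / mean_amb)
}

#' Percent or absolute difference between two summary values
#'
#' `relative`: `100 (a/b - 1)`, the percent difference of `a` from the
#' reference `b`; `absolute`: `a - b`.
#'
#' @param a,b Values to compare (`b` is the reference).
#' @param mode `"relative"` or `"absolute"`.
#' @return The difference.
#' @export
percent_difference <- function(a, b, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "relative") {
    if (b == 0) stop("reference must be nonzero for relative mode",
                     call. = FALSE)
    100 * (a / b - 1)
  } else {
    a - b
  }
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Saturation vapour pressure by the Magnus form
#' `es = 0.6108 exp(17.27 t / (t + 237.3))` (kPa), then
#' `VPD = es (1 - rh/100)`. VPD is nonlinear in temperature, so period-mean
#' VPD must be computed per hourly record and then averaged (see
#' [mean_vpd()]); applying this function to period-mean T and RH gives a
#' different (biased) number.
#'
#' @param t_c Air temperature, deg C, in [-20, 60].
#' @param rh_pct Relative humidity, percent, in [0, 100].
#' @return VPD in kPa (vectorized).
#' @export
vpd_from_t_rh <- function(t_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  }
  if (any(t_c < -20 | t_c > 60, na.rm = TRUE)) {
    stop("temperature outside plausible range [-20, 60] degC", call. = FALSE)
  }
  es <- 0.6108 * exp(17.27 * t_c / (t_c + 237.3))
  es * (1 - rh_pct / 100)
}

#' Mean hourly VPD of a series
#'
#' @param series An [hourly_series()] with `t_c` and `rh_pct` columns.
#' @param window Optional `[from, to)` hour window; `NULL` uses all hours.
#' @return Mean of hourly VPD values, kPa.
#' @export
mean_vpd <- function(series, window = NULL) {
  stopifnot(inherits(series, "hourly_series"))
  if (is.null(series$t_c) || is.null(series$rh_pct)) {
    stop("series lacks t_c / rh_pct columns", call. = FALSE)
  }
  keep <- if (is.null(window)) rep(TRUE, nrow(series)) else
    in_window(series, window)
  mean(vpd_from_t_rh(series$t_c[keep], series$rh_pct[keep]), na.rm = TRUE)
}

#' Exposure summary for one treatment series
#'
#' @param series An [hourly_series()].
#' @param treatment Treatment label.
#' @return data.frame row: `treatment`, `aot40_nl_l_h`, `mean_7_15_nl_l`,
#'   `daily_mean_nl_l`.
#' @export
exposure_summary <- function(series, treatment = NA_character_) {
  data.frame(treatment = treatment,
             aot40_nl_l_h = aot40(series)$aot40_nl_l_h,
             mean_7_15_nl_l = window_mean(series),
             daily_mean_nl_l = daily_mean(series),
             stringsAsFactors = FALSE)
}

#' Reference OTC exposure and microclimate summary table
#'
#' Bundled summary table from a 37-day open-top-chamber ozone-fumigation
#' trial, used as the worked example for the chamber-comparison
#' arithmetic: per-treatment AOT40, daylight-window (7-15 h) and daily
#' ozone means, and daylight-hour microclimate means outside (ambient) and
#' inside the chambers.
#'
#' @return List with `ozone` (data.frame: `treatment`, `aot40_nl_l_h`,
#'   `mean_7_15_nl_l`, `daily_mean_nl_l`) and `microclimate` (data.frame:
#'   `plot`, `mean_t_c`, `max_t_c`, `rh_pct`, `vpd_kpa`, `par_umol`).
#' @export
otc_reference_table <- function() {
  list(
    ozone = data.frame(
      treatment = c("AMB", "CFA", "NFA", "FU+"),
      aot40_nl_l_h = c(2922.7, 23.7, 2333.2, 12121.5),
      mean_7_15_nl_l = c(41.3, 21.7, 40.1, 64.6),
      daily_mean_nl_l = c(36, 17.3, 35.2, 48.8),
      stringsAsFactors = FALSE
    ),
    microclimate = data.frame(
      plot = c("ambient", "OTC"),
      mean_t_c = c(15.8, 19.1),
      max_t_c = c(28.6, 33.6),
      rh_pct = c(52.5, 56.5),
      vpd_kpa = c(0.78, 1.06),
      par_umol = c(841, 698.2),
      stringsAsFactors = FALSE
    )
  )
}

#' Chamber-effect and filtration arithmetic from a summary table
#'
#' Recomputes the standard comparisons from a per-treatment exposure and
#' microclimate summary (shaped like [otc_reference_table()]): charcoal
#' filtration efficiency (CFA vs AMB), relative ozone differences of NFA
#' and FU+ vs AMB, and the OTC-minus-ambient microclimate deltas
#' (temperature in deg C, relative humidity in percentage points, VPD and
#' PAR as percent differences).
#'
#' @param table A list like [otc_reference_table()].
#' @return data.frame with columns `quantity`, `value`, `units`.
#' @export
chamber_effect_summary <- function(table = otc_reference_table()) {
  oz <- table$ozone
  mc <- table$microclimate
  m <- function(tr) oz$mean_7_15_nl_l[oz$treatment == tr]
  amb <- mc[mc$plot == "ambient", ]
  otc <- mc[mc$plot == "OTC", ]
  data.frame(
    quantity = c("filtration_efficiency_cfa", "o3_nfa_vs_amb",
                 "o3_fuplus_vs_amb", "delta_mean_t", "delta_rh",
                 "vpd_otc_vs_ambient", "par_otc_vs_ambient"),
    value = c(
      filtration_efficiency(m("CFA"), m("AMB")),
      percent_difference(m("NFA"), m("AMB"), "relative"),
      percent_difference(m("FU+"), m("AMB"), "relative"),
      percent_difference(otc$mean_t_c, amb$mean_t_c, "absolute"),
      percent_difference(otc$rh_pct, amb$rh_pct, "absolute"),
      percent_difference(otc$vpd_kpa, amb$vpd_kpa, "relative"),
      percent_difference(otc$par_umol, amb$par_umol, "relative")
    ),
    units = c("%", "%", "%", "degC", "percentage points", "%", "%"),
    stringsAsFactors = FALSE
  )
}
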