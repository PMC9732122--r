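#' Gross O2 evolution from electrode measurements
#'
#' Gross photosynthetic O2 evolution is the net evolution measured at
#' saturating irradiance plus the magnitude of respiratory O2 consumption
#' measured in the dark immediately after the light exposure. Respiration
#' is stored as a positive magnitude throughout the package; signs are
#' applied only here.
#'
#' @param net_light Net O2 evolution in the light (may be negative).
#' @param resp_dark_after_light Respiratory consumption magnitude (>= 0).
#' @return Gross O2 evolution rate(s), same units as the inputs.
#' @export
gross_o2 <- function(net_light, resp_dark_after_light) {
  assert_num(net_light, "net_light", len = NULL)
  assert_num(resp_dark_after_light, "resp_dark_after_light", lower = 0,
             len = NULL)
  if (length(net_light) != length(resp_dark_after_light)) {
    dzd_stop("parse_error", "net and respiration series differ in length")
  }
  net_light + resp_dark_after_light
}

#' Diel rate time series
#'
#' @param t_h Sampling hours since light onset, strictly increasing,
#'   in `[0, 24)`.
#' @param value Rates (finite; consumption as positive magnitude for
#'   respiration series).
#' @param label One of `gross_o2, net_o2, respiration, n2fix, etr`.
#' @return A `rate_timeseries` object.
#' @export
rate_timeseries <- function(t_h, value,
                            label = c("gross_o2", "net_o2", "respiration",
                                      "n2fix", "etr")) {
  label <- match.arg(label)
  assert_num(t_h, "t_h", lower = 0, len = NULL)
  if (any(t_h >= 24) || is.unsorted(t_h, strictly = TRUE)) {
    dzd_stop("domain_error", "t_h must be strictly increasing within [0, 24)")
  }
  if (!is.numeric(value) || length(value) != length(t_h) ||
      any(!is.finite(value))) {
    dzd_stop("domain_error", "values must be finite and match t_h in length")
  }
  structure(list(t_h = t_h, value = value, label = label),
            class = "rate_timeseries")
}

#' Integrate a diel rate series into 12-h phase totals
#'
#' Rates are taken as piecewise linear between samples (composite
#' trapezoid); phase edges at 0, 12 and 24 h are filled by extending the
#' nearest measured value, never by extrapolating its trend. The
#' alternative `"mean12"` convention (phase mean rate x 12 h) is available
#' for comparison with sparser bookkeeping.
#'
#' @param series A [rate_timeseries()].
#' @param light_phase,dark_phase Phase boundaries in hours.
#' @param method `"trapezoid"` (default) or `"mean12"`.
#' @return A `phase_budget`: list with `day_total`, `night_total`.
#' @export
phase_totals <- function(series, light_phase = c(0, 12),
                         dark_phase = c(12, 24),
                         method = c("trapezoid", "mean12")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "rate_timeseries"))
  one <- function(bounds) {
    # closed interval: a sample exactly on a phase boundary informs the
    # edge of both adjacent phases (the rate at the transition instant)
    sel <- series$t_h >= bounds[1L] & series$t_h <= bounds[2L]
    if (!any(sel)) {
      dzd_stop("missing_phase", "no samples in phase [%g, %g]",
               bounds[1L], bounds[2L])
    }
    if (sum(sel) < 2L) {
      dzd_stop("missing_phase", ">= 2 samples per phase are required")
    }
    t <- series$t_h[sel]; v <- series$value[sel]
    if (method == "mean12") {
      return(mean(v) * (bounds[2L] - bounds[1L]))
    }
    if (t[1L] > bounds[1L]) {
      t <- c(bounds[1L], t); v <- c(v[1L], v)
    }
    if (t[length(t)] < bounds[2L]) {
      t <- c(t, bounds[2L]); v <- c(v, v[length(v)])
    }
    trapz_int(t, v)
  }
  structure(list(day_total = one(light_phase),
                 night_total = one(dark_phase),
                 label = series$label, method = method),
            class = "phase_budget")
}

#' @export
print.phase_budget <- function(x, ...) {
  cat(sprintf("Phase budget (%s, %s): day %.4g, night %.4g per 12 h\n",
              x$label, x$method, x$day_total, x$night_total))
  invisible(x)
}

#' Read an O2 electrode CSV (`t_h,net_light,resp_dark`)
#' @param path File path.
#' @return Data frame.
#' @export
read_o2 <- function(path) {
  read_dzd_csv(path, c("t_h", "net_light", "resp_dark"))
}

#' Write phase budgets for several series
#'
#' @param budgets Named list of `phase_budget`s (names = series labels).
#' @param path Output CSV (`species,series,day_total,night_total,units`).
#' @param species Species name for the `species` column.
#' @param units Units string per series (recycled).
#' @export
write_phase_budgets <- function(budgets, path, species,
                                units = "umol (ug Chl)-1 12 h-1") {
  df <- data.frame(
    species = species,
    series = names(budgets),
    day_total = vapply(budgets, `[[`, numeric(1), "day_total"),
    night_total = vapply(budgets, `[[`, numeric(1), "night_total"),
    units = rep_len(units, length(budgets)))
  write_dzd_csv(df, path)
}
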