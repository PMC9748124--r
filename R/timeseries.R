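#' Unit-tagged time series
#'
#' The common container for every measured or simulated curve in the package:
#' serum protein concentrations (ng/mL vs min), antibody fluorescence
#' (RFU vs h), OGTT glucose / insulin / C-peptide, and secretion rates.
#' A `gutpk_ts` is a plain list with strictly increasing `time`, matching
#' `value`, the units of both axes, and an optional constant basal level
#' (the pre-dose measurement the incremental models sit on top of).
#'
#' @param time numeric vector, strictly increasing, first element >= 0.
#' @param value numeric vector, same length as `time`.
#' @param time_unit unit of the time axis, e.g. `"min"` or `"h"`.
#' @param value_unit unit of the value axis, e.g. `"ng/mL"`.
#' @param basal constant basal level in `value_unit`; `NA` when the notion
#'   does not apply (e.g. an inflow-rate curve).
#'
#' @return an object of class `gutpk_ts`.
#' @export
timeseries <- function(time, value, time_unit = "min", value_unit = "",
                       basal = NA_real_) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty time series", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time))) {
    stop("non-finite timestamps", call. = FALSE)
  }
  d <- diff(time)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L] + 1L
    stop(sprintf("timestamps must be strictly increasing (row %d, t = %g)",
                 i, time[i]), call. = FALSE)
  }
  if (time[1L] < 0) stop("first timestamp must be >= 0", call. = FALSE)
  structure(
    list(time = time, value = value, time_unit = time_unit,
         value_unit = value_unit, basal = as.numeric(basal)),
    class = "gutpk_ts"
  )
}

#' @export
print.gutpk_ts <- function(x, ...) {
  cat(sprintf("<time series: %d points, t in [%g, %g] %s, value in %s>\n",
              length(x$time), x$time[1L], x$time[length(x$time)],
              x$time_unit, if (nzchar(x$value_unit)) x$value_unit else "(unitless)"))
  if (!is.na(x$basal)) cat(sprintf("  basal: %g %s\n", x$basal, x$value_unit))
  print(utils::head(data.frame(time = x$time, value = x$value), 8L))
  if (length(x$time) > 8L) cat(sprintf("  ... %d more rows\n", length(x$time) - 8L))
  invisible(x)
}

#' @export
as.data.frame.gutpk_ts <- function(x, ...) {
  data.frame(time = x$time, value = x$value)
}

#' @export
length.gutpk_ts <- function(x) length(x$time)

#' Linear interpolation of a time series at arbitrary times
#'
#' Constant extrapolation beyond the record (rule = 2), matching how forcing
#' functions are handled inside the ODE integrators.
#'
#' @param x a [timeseries()].
#' @param t times at which to evaluate.
#' @return numeric vector of interpolated values.
#' @export
ts_interp <- function(x, t) {
  stats::approx(x$time, x$value, xout = t, rule = 2)$y
}

#' Trapezoidal integral of a time series
#'
#' @param x a [timeseries()] or a pair of vectors via `t`/`y`.
#' @return the trapezoidal-rule integral over the record.
#' @export
ts_trapz <- function(x) {
  trapz_(x$time, x$value)
}

# plain trapezoid on vectors (used everywhere an AUC is needed)
trapz_ <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)
}

#' Time and value of the maximum of a series
#'
#' @param x a [timeseries()].
#' @return list with `tmax` and `cmax` (first occurrence of the maximum).
#' @export
ts_peak <- function(x) {
  i <- which.max(x$value)
  list(tmax = x$time[i], cmax = x$value[i], index = i)
}
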