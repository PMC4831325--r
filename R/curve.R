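#' Uniformly sampled time-series curve
#'
#' Container for an ROI-averaged signal (or concentration-proxy) curve
#' sampled on a uniform time grid. Times are in seconds; values are in
#' arbitrary units. `n_precontrast` counts the leading baseline samples
#' acquired before contrast injection.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing with constant spacing (relative tolerance 1e-9).
#' @param values Numeric vector of finite sample values, same length as
#'   `times`.
#' @param n_precontrast Integer count of leading precontrast (baseline)
#'   samples; must be smaller than the curve length. Zero is allowed for
#'   derived/model curves that carry no baseline.
#' @param baseline_mean,baseline_sd Optional baseline summary metadata,
#'   normally filled in by [enhancement_curve()].
#'
#' @return An object of class `ts_curve`: a list with elements `times`,
#'   `values`, `n_precontrast`, `baseline_mean`, `baseline_sd`.
#' @seealso [enhancement_curve()], [plasma_correct()]
#' @examples
#' ts_curve(seq(0, 17, by = 1.7), rnorm(11, 100, 1), n_precontrast = 10)
#' @export
ts_curve <- function(times, values, n_precontrast = 0L,
                     baseline_mean = NA_real_, baseline_sd = NA_real_) {
  if (!is.numeric(times) || !is.numeric(values)) {
    stop("`times` and `values` must be numeric vectors", call. = FALSE)
  }
  n <- length(times)
  if (n < 2L || length(values) != n) {
    stop("`times` and `values` must have equal length >= 2", call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop("curve times and values must be finite", call. = FALSE)
  }
  d <- diff(times)
  if (any(d <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  dt <- d[1L]
  if (any(abs(d - dt) > 1e-9 * max(abs(dt), 1))) {
    stop("`times` must be uniformly spaced (constant dt)", call. = FALSE)
  }
  n_precontrast <- as.integer(n_precontrast)
  if (is.na(n_precontrast) || n_precontrast < 0L || n_precontrast >= n) {
    stop("`n_precontrast` must be in [0, length(times) - 1]", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         n_precontrast = n_precontrast,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd),
    class = "ts_curve"
  )
}

#' Sampling interval of a curve
#'
#' @param curve A [ts_curve()].
#' @return The sampling interval dt in seconds.
#' @export
curve_dt <- function(curve) {
  stopifnot(inherits(curve, "ts_curve"))
  (curve$times[length(curve$times)] - curve$times[1L]) /
    (length(curve$times) - 1L)
}

#' @export
print.ts_curve <- function(x, ...) {
  cat(sprintf(
    "<ts_curve> %d samples, dt = %.4g s, t = [%.4g, %.4g] s, %d precontrast\n",
    length(x$times), curve_dt(x), x$times[1L], x$times[length(x$times)],
    x$n_precontrast
  ))
  invisible(x)
}

#' @export
length.ts_curve <- function(x) length(x$times)
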