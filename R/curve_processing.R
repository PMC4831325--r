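#' Detection configuration
#'
#' Tunable parameters of the postaortic-rise and end-of-uptake detectors.
#'
#' @param smoothing_window Odd number of samples for the centered moving
#'   average applied to the renal curve before differentiation (default 5).
#' @param rise_sigma_k Baseline-SD multiplier for the aortic rise threshold
#'   (default 3).
#' @param plateau_fraction Fraction theta of the filtration-phase maximum
#'   derivative delimiting the "no significant slope" band (default 0.1).
#' @param persistence Number m of consecutive samples a condition must hold
#'   to be accepted (default 3).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(smoothing_window = 5L, rise_sigma_k = 3,
                             plateau_fraction = 0.1, persistence = 3L) {
  smoothing_window <- as.integer(smoothing_window)
  persistence <- as.integer(persistence)
  if (is.na(smoothing_window) || smoothing_window < 1L ||
      smoothing_window %% 2L == 0L) {
    stop("`smoothing_window` must be an odd integer >= 1", call. = FALSE)
  }
  if (!is.finite(rise_sigma_k) || rise_sigma_k <= 0) {
    stop("`rise_sigma_k` must be > 0", call. = FALSE)
  }
  if (!is.finite(plateau_fraction) || plateau_fraction <= 0 ||
      plateau_fraction >= 1) {
    stop("`plateau_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (is.na(persistence) || persistence < 1L) {
    stop("`persistence` must be >= 1", call. = FALSE)
  }
  structure(list(smoothing_window = smoothing_window,
                 rise_sigma_k = rise_sigma_k,
                 plateau_fraction = plateau_fraction,
                 persistence = persistence),
            class = "detection_config")
}

#' Signal enhancement relative to the precontrast baseline
#'
#' Subtracts the mean of the precontrast samples from a raw signal curve.
#' Signal change between pre- and postcontrast images serves as the
#' concentration proxy. The baseline mean and SD are retained as metadata
#' for downstream rise detection.
#'
#' @param raw A [ts_curve()] with `n_precontrast >= 1`.
#' @return A [ts_curve()] of enhancement values (precontrast mean exactly
#'   zero), with `baseline_mean` and `baseline_sd` filled in.
#' @export
enhancement_curve <- function(raw) {
  stopifnot(inherits(raw, "ts_curve"))
  np <- raw$n_precontrast
  if (np < 1L) {
    stop("enhancement requires at least one precontrast sample", call. = FALSE)
  }
  base <- raw$values[seq_len(np)]
  m <- mean(base)
  s <- if (np > 1L) stats::sd(base) else 0
  ts_curve(raw$times, raw$values - m, n_precontrast = np,
           baseline_mean = m, baseline_sd = s)
}

# Start of the filtration phase in a derivative series `d` scanned from
# `from`. The first-pass vascular transient is the maximum-upslope sample;
# if a sustained (m-sample) negative-derivative run follows (the
# post-bolus vascular dip), the filtration phase starts at the sustained
# recovery after it; a negative run with no recovery is the outflow
# descent itself, so the scan stays at the upslope maximum. Without a dip
# the transient ends where the derivative stops falling for m samples.
# Persistence makes the segmentation robust to sample noise.
filtration_start <- function(d, from, m = 3L) {
  n1 <- length(d)
  i_v <- from - 1L + which.max(d[from:n1])
  neg <- first_run_start(d[i_v:n1] < 0, m)
  if (!is.na(neg)) {
    j0 <- i_v - 1L + neg
    rec <- first_run_start(d[j0:n1] >= 0, m)
    return(if (!is.na(rec)) j0 - 1L + rec else i_v)
  }
  i_f <- i_v
  while (i_f < n1 - 1L) {
    ahead <- d[(i_f + 1L):min(i_f + m, n1)]
    if (min(ahead) >= d[i_f]) break
    i_f <- i_f + 1L
  }
  i_f
}

# first start index of a run of at least m consecutive TRUEs, NA if none
first_run_start <- function(flag, m) {
  r <- rle(as.logical(flag))
  hit <- which(r$values & r$lengths >= m)
  if (length(hit) == 0L) return(NA_integer_)
  ends <- cumsum(r$lengths)
  as.integer(ends[hit[1L]] - r$lengths[hit[1L]] + 1L)
}

#' Detect the postaortic rise
#'
#' Finds the sample immediately before the first contrast-driven increase
#' of the aortic enhancement curve: the first index whose value exceeds
#' `rise_sigma_k` times the precontrast SD for `persistence` consecutive
#' samples marks the rise; the returned index is the sample before it.
#' If the baseline SD is zero, any strictly positive value counts as a
#' rise.
#'
#' @param aorta_enh Aortic enhancement curve from [enhancement_curve()]
#'   (baseline metadata required).
#' @param config A [detection_config()].
#' @return The 1-based postaortic rise index.
#' @export
detect_postaortic_rise <- function(aorta_enh, config = detection_config()) {
  stopifnot(inherits(aorta_enh, "ts_curve"))
  sd0 <- aorta_enh$baseline_sd
  if (is.na(sd0)) {
    stop("curve carries no baseline metadata; run enhancement_curve() first",
         call. = FALSE)
  }
  thr <- if (sd0 > 0) config$rise_sigma_k * sd0 else 0
  i <- first_run_start(aorta_enh$values > thr, config$persistence)
  if (is.na(i)) {
    stop("no aortic rise detected: no sustained supra-threshold enhancement",
         call. = FALSE)
  }
  if (i <= 1L) {
    stop("aortic rise at the first sample; no preceding baseline sample",
         call. = FALSE)
  }
  i - 1L
}

#' Centered moving-average smoothing
#'
#' Smooths a curve with a centered moving average of odd width; at the
#' boundaries the window shrinks symmetrically to the available samples, so
#' the output has the same length as the input.
#'
#' @param curve A [ts_curve()].
#' @param window Odd window width in samples; `window = 1` is the identity.
#' @return The smoothed [ts_curve()] (metadata preserved).
#' @export
smooth_curve <- function(curve, window) {
  stopifnot(inherits(curve, "ts_curve"))
  window <- as.integer(window)
  n <- length(curve$values)
  if (is.na(window) || window < 1L || window %% 2L == 0L || window > n) {
    stop("`window` must be an odd integer in [1, length(curve)]",
         call. = FALSE)
  }
  if (window == 1L) return(curve)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, curve$values))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  ts_curve(curve$times, vals, n_precontrast = curve$n_precontrast,
           baseline_mean = curve$baseline_mean,
           baseline_sd = curve$baseline_sd)
}

#' Detect the subject-specific end-of-uptake point
#'
#' Segments the renal enhancement curve into its vascular, filtration and
#' outflow/plateau phases and returns the end of the uptake phase. The
#' curve is smoothed, differentiated, and scanned after `rise_index`:
#' the maximum derivative of the filtration phase (after the first-pass
#' vascular transient) sets the scale `d_max`. If the derivative drops to
#' `<= -plateau_fraction * d_max` for `persistence` consecutive samples, an
#' outflow phase is present and the index of maximum enhancement before
#' that descent is returned (`mode = "outflow_defined"`). Otherwise, if the
#' derivative stays within `(-theta*d_max, +theta*d_max)` for `persistence`
#' samples, the first index of that run is returned (`mode = "plateau"`,
#' the end of the initial upslope of a plateau/slowly increasing curve).
#'
#' @param kidney_enh Renal enhancement curve ([enhancement_curve()]).
#' @param rise_index Postaortic rise index from [detect_postaortic_rise()].
#' @param config A [detection_config()].
#' @param override_index Optional hand-picked end-of-uptake index; when
#'   supplied, detection is skipped and `mode = "manual"`.
#' @return An object of class `uptake_detection`: a list with
#'   `postaortic_rise_index`, `end_of_uptake_index`, `uptake_interval`
#'   (seconds) and `mode`.
#' @export
detect_end_of_uptake <- function(kidney_enh, rise_index,
                                 config = detection_config(),
                                 override_index = NULL) {
  stopifnot(inherits(kidney_enh, "ts_curve"))
  n <- length(kidney_enh$values)
  dt <- curve_dt(kidney_enh)
  rise_index <- as.integer(rise_index)
  if (is.na(rise_index) || rise_index < 1L || rise_index > n - 2L) {
    stop("`rise_index` out of range", call. = FALSE)
  }
  if (!is.null(override_index)) {
    end_idx <- as.integer(override_index)
    if (end_idx <= rise_index || end_idx > n) {
      stop("`override_index` must lie in (rise_index, n]", call. = FALSE)
    }
    return(new_uptake_detection(rise_index, end_idx, dt, "manual"))
  }
  s <- smooth_curve(kidney_enh, config$smoothing_window)$values
  d <- diff(s)
  m <- config$persistence
  i_f <- filtration_start(d, rise_index, m)
  if (i_f >= n - 1L) {
    stop("end-of-uptake detection failed: no filtration phase before the end of acquisition",
         call. = FALSE)
  }
  seg <- d[i_f:(n - 1L)]
  d_max <- max(seg, 0)
  thr <- config$plateau_fraction * d_max
  descent <- if (thr > 0) seg <= -thr else seg < 0
  j_off <- first_run_start(descent, m)
  if (!is.na(j_off)) {
    j_abs <- i_f - 1L + j_off
    # maximum enhancement of the filtration phase before the descent
    end_idx <- i_f - 1L + which.max(s[i_f:j_abs])
    mode <- "outflow_defined"
  } else {
    flat <- abs(seg) < thr
    j_pl <- first_run_start(flat, m)
    if (is.na(j_pl)) {
      stop("end-of-uptake detection failed: curve truncated mid-uptake (no outflow or plateau phase)",
           call. = FALSE)
    }
    end_idx <- i_f - 1L + j_pl
    mode <- "plateau"
  }
  if (end_idx <= rise_index) {
    stop("end-of-uptake detection failed: detected point does not follow the rise",
         call. = FALSE)
  }
  new_uptake_detection(rise_index, end_idx, dt, mode)
}

new_uptake_detection <- function(rise_index, end_idx, dt, mode) {
  structure(
    list(postaortic_rise_index = as.integer(rise_index),
         end_of_uptake_index = as.integer(end_idx),
         uptake_interval = (end_idx - rise_index) * dt,
         mode = mode),
    class = "uptake_detection"
  )
}

#' @export
print.uptake_detection <- function(x, ...) {
  cat(sprintf(
    "<uptake_detection> rise @ %d, end-of-uptake @ %d (%s), interval %.1f s\n",
    x$postaortic_rise_index, x$end_of_uptake_index, x$mode, x$uptake_interval
  ))
  invisible(x)
}
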