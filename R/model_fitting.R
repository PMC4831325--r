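#' Fitting configuration
#'
#' Optimizer settings shared by [fit_aif()] and [fit_kidney_model()]:
#' bounded Levenberg-Marquardt (via \pkg{minpack.lm}) started from a
#' deterministic grid of initial points.
#'
#' @param n_starts Number of multi-start initial points (default 5).
#' @param maxiter Maximum LM iterations per start.
#' @param ftol,ptol Relative convergence tolerances on the residual sum of
#'   squares and on the parameters.
#' @param refine Grid refinement factor passed to the forward models.
#' @return An object of class `fit_control`.
#' @export
fit_control <- function(n_starts = 5L, maxiter = 300L,
                        ftol = 1e-13, ptol = 1e-13, refine = 10L) {
  n_starts <- as.integer(n_starts)
  if (is.na(n_starts) || n_starts < 1L) stop("`n_starts` must be >= 1",
                                             call. = FALSE)
  structure(list(n_starts = n_starts, maxiter = as.integer(maxiter),
                 ftol = ftol, ptol = ptol, refine = as.integer(refine)),
            class = "fit_control")
}

new_fit_result <- function(params, r_squared, residual_norm, method,
                           gfr_ml_min = NA_real_, hct_mode = NA_character_,
                           fit_window = c(NA_integer_, NA_integer_),
                           provenance = NULL) {
  structure(
    list(params = params, r_squared = r_squared,
         residual_norm = residual_norm, gfr_ml_min = gfr_ml_min,
         method = method, hct_mode = hct_mode,
         fit_window = as.integer(fit_window), provenance = provenance),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> method=%s R^2=%.5f residual=%.4g",
              x$method, x$r_squared, x$residual_norm))
  if (!is.na(x$gfr_ml_min)) cat(sprintf(" GFR=%.1f mL/min", x$gfr_ml_min))
  cat("\n")
  print(x$params)
  invisible(x)
}

# run bounded LM from each start; keep converged fits; pick the lowest
# deviance, breaking near-ties (1 + 1e-9 relative) by the tie_break value
run_multistart_lm <- function(residual_fn, starts, lower, upper, control,
                              tie_break = NULL) {
  best <- NULL
  best_tie <- Inf
  ctl <- minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                    ftol = control$ftol, ptol = control$ptol)
  for (k in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(starts[k, ], lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = residual_fn, control = ctl),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4) next
    tie <- if (is.null(tie_break)) 0 else tie_break(fit$par)
    take <- is.null(best) ||
      fit$deviance < best$deviance * (1 - 1e-9) ||
      (fit$deviance <= best$deviance * (1 + 1e-9) && tie < best_tie)
    if (take) {
      best <- fit
      best_tie <- tie
    }
  }
  if (is.null(best)) {
    stop("optimizer failed to converge from any start", call. = FALSE)
  }
  best
}

#' Fit a two-gamma-variate AIF to an aortic plasma curve
#'
#' Bounded Levenberg-Marquardt least squares of the two-lobe gamma-variate
#' model over the samples from the postaortic rise to the end of the
#' acquisition. Initialization is a deterministic multi-start grid: the
#' first-pass lobe is seeded at the curve maximum and the recirculation
#' lobe 25 s later, with several shape-parameter combinations.
#'
#' @param aorta_plasma_enh Aortic plasma enhancement curve (output of
#'   [enhancement_curve()] + [plasma_correct()]).
#' @param rise_index Postaortic rise index ([detect_postaortic_rise()]).
#' @param control A [fit_control()].
#' @return A `fit_result` whose `params` is the fitted [aif_model()].
#' @export
fit_aif <- function(aorta_plasma_enh, rise_index, control = fit_control()) {
  stopifnot(inherits(aorta_plasma_enh, "ts_curve"))
  n <- length(aorta_plasma_enh$values)
  rise_index <- as.integer(rise_index)
  if (is.na(rise_index) || rise_index < 1L || rise_index > n - 8L) {
    stop("`rise_index` leaves too few samples to fit an AIF", call. = FALSE)
  }
  idx <- rise_index:n
  tt <- aorta_plasma_enh$times[idx]
  y <- aorta_plasma_enh$values[idx]
  ss_tot <- sum((y - mean(y))^2)
  if (!is.finite(ss_tot) || ss_tot <= 0 || max(abs(y)) == 0) {
    stop("degenerate aortic curve: no signal variation to fit", call. = FALSE)
  }
  ip <- which.max(y)
  tp <- tt[ip]
  yp <- y[ip]
  t1_0 <- tt[1L]
  t_end <- tt[length(tt)]

  # deterministic multi-start grid (recycled to n_starts)
  b1s <- c(2, 3, 1.5, 4, 2.5)
  b2s <- c(1, 1.5, 2, 0.8, 1.2)
  c2s <- c(45, 60, 80, 40, 90)
  fr <- c(0.2, 0.15, 0.25, 0.2, 0.3)
  ns <- control$n_starts
  starts <- matrix(NA_real_, nrow = ns, ncol = 8)
  colnames(starts) <- c("a1", "b1", "c1", "t1", "a2", "b2", "c2", "dt2")
  for (k in seq_len(ns)) {
    j <- (k - 1L) %% 5L + 1L
    b1 <- b1s[j]
    c1 <- max((tp - t1_0) / max(b1, 0.5), 1)
    a1 <- yp / ((b1 * c1)^b1 * exp(-b1))
    b2 <- b2s[j]
    c2 <- c2s[j]
    a2 <- fr[j] * yp / ((b2 * c2)^b2 * exp(-b2))
    starts[k, ] <- c(a1, b1, c1, t1_0, a2, b2, c2, tp + 25 - t1_0)
  }
  lower <- c(0, 0, 0.5, max(0, t1_0 - 2 * (tt[2L] - tt[1L])), 0, 0, 1, 0)
  upper <- c(Inf, 8, 300, tp, Inf, 8, 500, max(t_end - t1_0, 1))

  resid_fn <- function(p) {
    a <- gamma_variate(tt, p[1L], p[2L], p[3L], p[4L]) +
      gamma_variate(tt, p[5L], p[6L], p[7L], p[4L] + p[8L])
    a - y
  }
  best <- run_multistart_lm(resid_fn, starts, lower, upper, control)
  p <- unname(best$par)
  model <- aif_model(a1 = p[1L], b1 = p[2L], c1 = p[3L], t1 = p[4L],
                     a2 = p[5L], b2 = p[6L], c2 = p[7L], t2 = p[4L] + p[8L])
  new_fit_result(model,
                 r_squared = 1 - best$deviance / ss_tot,
                 residual_norm = sqrt(best$deviance),
                 method = "aif",
                 fit_window = c(rise_index, n))
}

kidney_fit_methods <- c("ss", "fixed90", "fixed110", "inflow_outflow")

#' Fit a two-compartment kidney model
#'
#' Bounded Levenberg-Marquardt least squares of the 2C uptake model (or the
#' inflow-outflow model) to a renal enhancement curve over the window
#' `[rise_index, end_index]`. Free parameters are `v_p` (bounds 0-1),
#' `gfr_v` (0-2 min^-1), `delay` (0-10 s), `t_disp` (0.5-30 s) and, for the
#' inflow-outflow model, `t_tub` (10-1e4 s). Initialization is a
#' deterministic multi-start grid; near-ties are broken by the lower
#' `delay`.
#'
#' @param kidney_enh Renal enhancement curve ([enhancement_curve()]).
#' @param aif Fitted [aif_model()] of the aortic plasma input.
#' @param method One of `"ss"`, `"fixed90"`, `"fixed110"`,
#'   `"inflow_outflow"` (recorded; the first three fit the uptake model and
#'   differ only in how `end_index` was chosen).
#' @param rise_index,end_index Fit window (1-based, inclusive).
#' @param volume Renal parenchymal volume in mL, used to convert the fitted
#'   `gfr_v` to whole-kidney GFR.
#' @param control A [fit_control()].
#' @return A `fit_result` with fitted [kidney_params()], `r_squared`,
#'   `residual_norm` and `gfr_ml_min`.
#' @export
fit_kidney_model <- function(kidney_enh, aif, method = kidney_fit_methods,
                             rise_index, end_index, volume,
                             control = fit_control()) {
  stopifnot(inherits(kidney_enh, "ts_curve"), inherits(aif, "aif_model"))
  method <- match.arg(method)
  n <- length(kidney_enh$values)
  rise_index <- as.integer(rise_index)
  end_index <- as.integer(end_index)
  if (is.na(end_index) || is.na(rise_index) || rise_index < 1L ||
      end_index > n || end_index <= rise_index) {
    stop("invalid fit window: need 1 <= rise_index < end_index <= n",
         call. = FALSE)
  }
  if (!is.finite(volume) || volume <= 0) {
    stop("`volume` must be a positive parenchymal volume in mL",
         call. = FALSE)
  }
  outflow <- method == "inflow_outflow"
  grid <- refine_grid(kidney_enh$times, 2L * control$refine)
  idx <- rise_index:end_index
  y <- kidney_enh$values[idx]
  ss_tot <- sum((y - mean(y))^2)
  if (!is.finite(ss_tot) || ss_tot <= 0) {
    stop("degenerate kidney curve: no signal variation in the fit window",
         call. = FALSE)
  }

  vp0 <- c(0.15, 0.25, 0.10, 0.30, 0.20)
  g0 <- c(0.30, 0.45, 0.20, 0.55, 0.35)
  de0 <- c(1, 2, 0.5, 3, 1.5)
  td0 <- c(4, 8, 2, 12, 6)
  tt0 <- c(200, 1000, 60, 4000, 500)
  ns <- control$n_starts
  np <- if (outflow) 5L else 4L
  starts <- matrix(NA_real_, nrow = ns, ncol = np)
  for (k in seq_len(ns)) {
    j <- (k - 1L) %% 5L + 1L
    starts[k, 1:4] <- c(vp0[j], g0[j], de0[j], td0[j])
    if (outflow) starts[k, 5L] <- tt0[j]
  }
  lower <- c(0, 0, 0, 0.5, if (outflow) 10)
  upper <- c(1, 2, 10, 30, if (outflow) 1e4)
  names(lower) <- names(upper) <-
    c("v_p", "gfr_v", "delay", "t_disp", if (outflow) "t_tub")
  colnames(starts) <- names(lower)

  resid_fn <- function(p) {
    names(p) <- names(lower)
    forward_kidney_values(p, aif, grid, outflow)[idx] - y
  }
  best <- run_multistart_lm(resid_fn, starts, lower, upper, control,
                            tie_break = function(p) p[3L])
  p <- unname(best$par)
  params <- kidney_params(v_p = p[1L], gfr_v = p[2L], delay = p[3L],
                          t_disp = p[4L],
                          t_tub = if (outflow) p[5L] else NA_real_)
  new_fit_result(params,
                 r_squared = 1 - best$deviance / ss_tot,
                 residual_norm = sqrt(best$deviance),
                 method = method,
                 gfr_ml_min = gfr_from_gfrv(params$gfr_v, volume),
                 fit_window = c(rise_index, end_index))
}

#' Pipeline configuration
#'
#' Bundles the stage configurations of the subject-level GFR pipeline.
#' Unknown fields are rejected.
#'
#' @param detection A [detection_config()].
#' @param fitting A [fit_control()].
#' @param hct_fixed Literature hematocrit used when `hct_mode = "fixed41"`
#'   (fraction; default 0.41).
#' @param end_override Optional hand-picked end-of-uptake index forwarded
#'   to [detect_end_of_uptake()] for `method = "ss"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            fitting = fit_control(),
                            hct_fixed = 0.41,
                            end_override = NULL) {
  stopifnot(inherits(detection, "detection_config"),
            inherits(fitting, "fit_control"))
  if (!is.finite(hct_fixed) || hct_fixed <= 0 || hct_fixed >= 1) {
    stop("`hct_fixed` must be a fraction in (0, 1)", call. = FALSE)
  }
  structure(list(detection = detection, fitting = fitting,
                 hct_fixed = hct_fixed, end_override = end_override),
            class = "pipeline_config")
}

#' Estimate a subject's GFR from raw DCE-MRI curves
#'
#' Runs the full subject-specific pipeline: baseline enhancement of both
#' curves, blood-to-plasma correction of the aorta (subject hematocrit or
#' the fixed literature value), postaortic rise detection, AIF fitting,
#' end-of-uptake selection (for `method = "ss"`) or a fixed 90/110 s
#' window, and the bounded kidney-model fit. Provenance (indices, the
#' hematocrit used, detection mode, AIF fit) is recorded on the result.
#'
#' @param subject A `subject_record` (see [simulate_subject()] and
#'   [read_cohort_metadata()]).
#' @param method Kidney model/window: `"ss"` (subject-specific end of
#'   uptake), `"fixed90"`, `"fixed110"` (fixed windows after the postaortic
#'   rise) or `"inflow_outflow"` (full acquisition).
#' @param hct_mode `"subject"` (measured hematocrit) or `"fixed41"`
#'   (literature value from `config$hct_fixed`).
#' @param config A [pipeline_config()].
#' @return A `fit_result` with `gfr_ml_min` and provenance.
#' @export
estimate_subject_gfr <- function(subject, method = kidney_fit_methods,
                                 hct_mode = c("subject", "fixed41"),
                                 config = pipeline_config()) {
  stopifnot(inherits(subject, "subject_record"),
            inherits(config, "pipeline_config"))
  method <- match.arg(method)
  hct_mode <- match.arg(hct_mode)
  hct_used <- if (hct_mode == "subject") subject$hct else config$hct_fixed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  aorta_enh <- stage("enhancement_curve(aorta)",
                     enhancement_curve(subject$aorta_curve))
  plasma <- stage("plasma_correct", plasma_correct(aorta_enh, hct_used))
  rise <- stage("detect_postaortic_rise",
                detect_postaortic_rise(plasma, config$detection))
  aif_fit <- stage("fit_aif", fit_aif(plasma, rise, config$fitting))
  kidney_enh <- stage("enhancement_curve(kidney)",
                      enhancement_curve(subject$kidney_curve))

  n <- length(kidney_enh$values)
  dt <- curve_dt(kidney_enh)
  detection <- NULL
  end_index <- switch(
    method,
    ss = {
      detection <- stage("detect_end_of_uptake",
                         detect_end_of_uptake(kidney_enh, rise,
                                              config$detection,
                                              config$end_override))
      detection$end_of_uptake_index
    },
    fixed90 = rise + as.integer(round(90 / dt)),
    fixed110 = rise + as.integer(round(110 / dt)),
    inflow_outflow = n
  )
  if (end_index > n) {
    stop(sprintf("[fit window] %s window extends past the acquisition (%d > %d)",
                 method, end_index, n), call. = FALSE)
  }
  fit <- stage("fit_kidney_model",
               fit_kidney_model(kidney_enh, aif_fit$params, method,
                                rise_index = rise, end_index = end_index,
                                volume = subject$parenchymal_volume,
                                control = config$fitting))
  fit$hct_mode <- hct_mode
  fit$provenance <- list(
    subject_id = subject$subject_id,
    rise_index = rise,
    end_index = end_index,
    hct_used = hct_used,
    detection_mode = if (is.null(detection)) NA_character_ else detection$mode,
    uptake_interval = if (is.null(detection)) (end_index - rise) * dt
                      else detection$uptake_interval,
    aif_fit = aif_fit
  )
  fit
}

#' Fit a cohort of subjects across methods and hematocrit modes
#'
#' Convenience driver used by the command-line interface and the cohort
#' summaries: runs [estimate_subject_gfr()] for every subject x method x
#' hct_mode combination and collects one row per fit.
#'
#' @param cohort List of `subject_record`s.
#' @param methods Character vector of kidney-model methods.
#' @param hct_modes Character vector of hematocrit modes.
#' @param config A [pipeline_config()].
#' @param keep_going If `TRUE`, subject-level failures are recorded as `NA`
#'   rows with a warning instead of aborting.
#' @return A data.frame with one row per fit: identifiers, fitted
#'   parameters, `gfr_ml_min`, fit quality, window provenance and subject
#'   covariates.
#' @export
fit_cohort <- function(cohort, methods = "ss", hct_modes = "subject",
                       config = pipeline_config(), keep_going = FALSE) {
  rows <- list()
  for (subject in cohort) {
    for (method in methods) {
      for (hm in hct_modes) {
        res <- if (keep_going) {
          tryCatch(estimate_subject_gfr(subject, method, hm, config),
                   error = function(e) {
                     warning(sprintf("subject %s (%s/%s) failed: %s",
                                     subject$subject_id, method, hm,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
        } else {
          estimate_subject_gfr(subject, method, hm, config)
        }
        rows[[length(rows) + 1L]] <- cohort_fit_row(subject, method, hm, res)
      }
    }
  }
  do.call(rbind, rows)
}

cohort_fit_row <- function(subject, method, hm, res) {
  if (is.null(res)) {
    return(data.frame(
      subject_id = subject$subject_id, method = method, hct_mode = hm,
      gfr_ml_min = NA_real_, gfr_v = NA_real_, v_p = NA_real_,
      delay = NA_real_, t_disp = NA_real_, t_tub = NA_real_,
      rpf_v = NA_real_, r_squared = NA_real_, aif_r_squared = NA_real_,
      rise_index = NA_integer_, end_index = NA_integer_,
      uptake_interval = NA_real_, detection_mode = NA_character_,
      hct_used = NA_real_, volume_ml = subject$parenchymal_volume,
      reference_gfr = subject$reference_gfr %||% NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  p <- res$params
  data.frame(
    subject_id = subject$subject_id, method = method, hct_mode = hm,
    gfr_ml_min = res$gfr_ml_min, gfr_v = p$gfr_v, v_p = p$v_p,
    delay = p$delay, t_disp = p$t_disp, t_tub = p$t_tub,
    rpf_v = rpf_from_params(p), r_squared = res$r_squared,
    aif_r_squared = res$provenance$aif_fit$r_squared,
    rise_index = res$provenance$rise_index,
    end_index = res$provenance$end_index,
    uptake_interval = res$provenance$uptake_interval,
    detection_mode = res$provenance$detection_mode,
    hct_used = res$provenance$hct_used,
    volume_ml = subject$parenchymal_volume,
    reference_gfr = subject$reference_gfr %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
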