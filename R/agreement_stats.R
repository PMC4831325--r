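#' Linear regression of MR-GFR on reference GFR
#'
#' Ordinary least squares of the MR-based estimates on the reference
#' measurements, with the two-sided t-test p-value for slope != 0.
#'
#' @param ref Reference GFR values (mL/min), length >= 3, non-degenerate.
#' @param mr MR-GFR values (mL/min), same length.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(ref, mr) {
  check_paired(ref, mr)
  if (stats::var(ref) <= 0) {
    stop("degenerate reference values: zero variance", call. = FALSE)
  }
  fit <- stats::lm(mr ~ ref)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["ref", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = unname(co["ref", "Pr(>|t|)"]),
       n = length(ref))
}

#' Bland-Altman comparison of two GFR methods
#'
#' Mean difference (bias) of MR minus reference and limits of agreement at
#' bias +/- 2 SD of the differences (SD with the n-1 denominator).
#'
#' @inheritParams linear_regression
#' @return A list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(ref, mr) {
  check_paired(ref, mr)
  d <- mr - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 2 * s, loa_high = bias + 2 * s,
       sd_diff = s, n = length(d))
}

check_paired <- function(ref, mr) {
  if (!is.numeric(ref) || !is.numeric(mr) || length(ref) != length(mr)) {
    stop("`ref` and `mr` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(ref) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (any(!is.finite(ref)) || any(!is.finite(mr))) {
    stop("`ref` and `mr` must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Method-agreement statistics
#'
#' Combines [linear_regression()] and [bland_altman()] into one record.
#'
#' @inheritParams linear_regression
#' @return An object of class `agreement_stats`.
#' @export
agreement_stats <- function(ref, mr) {
  lr <- linear_regression(ref, mr)
  ba <- bland_altman(ref, mr)
  structure(c(lr, ba[c("bias", "loa_low", "loa_high", "sd_diff")]),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_stats> n=%d slope=%.3f intercept=%.1f R^2=%.3f ",
           "p=%.3g | bias=%.1f LoA=[%.1f, %.1f] mL/min\n"),
    x$n, x$slope, x$intercept, x$r_squared, x$p_value,
    x$bias, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' Cohort summary table of GFR estimates
#'
#' Summarizes per-subject fit results per method x hematocrit-mode cell:
#' range, mean +/- SD of the GFR estimates, and agreement statistics
#' against the reference GFR. The first row summarizes the reference
#' measurements themselves.
#'
#' @param results Data.frame of fits as returned by [fit_cohort()] (needs
#'   columns `subject_id`, `method`, `hct_mode`, `gfr_ml_min`).
#' @param ref Named numeric vector of reference GFR values (names are
#'   subject ids), or `NULL` to take the `reference_gfr` column of
#'   `results`.
#' @return A data.frame with one row per cell (plus the reference row) and
#'   columns `method`, `hct_mode`, `n`, `gfr_min`, `gfr_max`, `gfr_mean`,
#'   `gfr_sd`, `slope`, `intercept`, `r_squared`, `p_value`, `bias`,
#'   `loa_low`, `loa_high`.
#' @export
summarize_cohort <- function(results, ref = NULL) {
  needed <- c("subject_id", "method", "hct_mode", "gfr_ml_min")
  if (!is.data.frame(results) || !all(needed %in% names(results))) {
    stop("`results` must be a fit_cohort() data.frame", call. = FALSE)
  }
  if (is.null(ref)) {
    if (!"reference_gfr" %in% names(results)) {
      stop("no reference GFR available", call. = FALSE)
    }
    ref_tab <- unique(results[, c("subject_id", "reference_gfr")])
    ref <- stats::setNames(ref_tab$reference_gfr, ref_tab$subject_id)
  }
  methods <- unique(results$method)
  modes <- unique(results$hct_mode)
  cells <- expand.grid(method = methods, hct_mode = modes,
                       stringsAsFactors = FALSE)
  missing_cells <- character(0)
  rows <- list()
  have_ref <- !all(is.na(ref))
  ref_vals <- ref[!is.na(ref)]
  rows[[1L]] <- data.frame(
    method = "reference", hct_mode = "-", n = length(ref_vals),
    gfr_min = min(ref_vals), gfr_max = max(ref_vals),
    gfr_mean = mean(ref_vals), gfr_sd = stats::sd(ref_vals),
    slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
    p_value = NA_real_, bias = NA_real_, loa_low = NA_real_,
    loa_high = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cells))) {
    sub <- results[results$method == cells$method[i] &
                     results$hct_mode == cells$hct_mode[i] &
                     !is.na(results$gfr_ml_min), , drop = FALSE]
    if (nrow(sub) == 0L) {
      missing_cells <- c(missing_cells,
                         paste0(cells$method[i], "/", cells$hct_mode[i]))
      next
    }
    g <- sub$gfr_ml_min
    agr <- rep(NA_real_, 7)
    if (have_ref && nrow(sub) >= 3L) {
      r <- unname(ref[as.character(sub$subject_id)])
      ok <- is.finite(r)
      if (sum(ok) >= 3L) {
        a <- agreement_stats(r[ok], g[ok])
        agr <- c(a$slope, a$intercept, a$r_squared, a$p_value,
                 a$bias, a$loa_low, a$loa_high)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      method = cells$method[i], hct_mode = cells$hct_mode[i], n = nrow(sub),
      gfr_min = min(g), gfr_max = max(g), gfr_mean = mean(g),
      gfr_sd = if (nrow(sub) > 1L) stats::sd(g) else 0,
      slope = agr[1L], intercept = agr[2L], r_squared = agr[3L],
      p_value = agr[4L], bias = agr[5L], loa_low = agr[6L],
      loa_high = agr[7L], stringsAsFactors = FALSE
    )
  }
  if (length(missing_cells) > 0L) {
    stop("empty summary cell(s): ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plain-text cohort summary report
#'
#' Formats a [summarize_cohort()] table as a fixed-width text report with
#' GFR ranges, mean +/- SD and agreement statistics per model and
#' hematocrit mode.
#'
#' @param summary Data.frame from [summarize_cohort()].
#' @return A character vector of report lines (invisibly printable with
#'   `cat(..., sep = "\n")`).
#' @export
format_cohort_summary <- function(summary) {
  hdr <- sprintf("%-16s %-8s %3s  %-15s %-15s %-28s %s",
                 "model", "Hct", "n", "range (mL/min)", "mean +/- SD",
                 "regression vs reference", "Bland-Altman bias [LoA]")
  lines <- c(hdr, strrep("-", nchar(hdr)))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    reg <- if (is.na(r$slope)) "-" else
      sprintf("slope %.2f, R^2 %.3f, p %.2g", r$slope, r$r_squared, r$p_value)
    ba <- if (is.na(r$bias)) "-" else
      sprintf("%.1f [%.1f, %.1f]", r$bias, r$loa_low, r$loa_high)
    lines <- c(lines, sprintf(
      "%-16s %-8s %3d  %6.1f-%-8.1f %6.1f +/- %-6.1f %-28s %s",
      r$method, r$hct_mode, r$n, r$gfr_min, r$gfr_max, r$gfr_mean, r$gfr_sd,
      reg, ba
    ))
  }
  lines
}
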