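#' Write a subject's curve pair to a delimited text file
#'
#' CSV with header `time_s,aorta_signal,kidney_signal`; times in seconds.
#'
#' @param aorta,kidney [ts_curve()]s sharing the same time grid.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curves <- function(aorta, kidney, path) {
  stopifnot(inherits(aorta, "ts_curve"), inherits(kidney, "ts_curve"))
  if (!isTRUE(all.equal(aorta$times, kidney$times))) {
    stop("aorta and kidney curves must share the same time grid",
         call. = FALSE)
  }
  df <- data.frame(time_s = aorta$times, aorta_signal = aorta$values,
                   kidney_signal = kidney$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a subject's curve pair from a delimited text file
#'
#' Parses a CSV with columns `time_s`, `aorta_signal`, `kidney_signal`,
#' validating numeric cells and uniform, increasing sampling; parse errors
#' report the offending line number (header is line 1).
#'
#' @param path File path.
#' @param n_precontrast Number of leading precontrast samples (from the
#'   cohort metadata).
#' @return A list with `ts_curve`s `aorta` and `kidney`.
#' @export
read_curves <- function(path, n_precontrast) {
  if (!file.exists(path)) stop("curve file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "aorta_signal", "kidney_signal")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in needed) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, col, bad[1L] + 1L), call. = FALSE)
    }
    df[[col]] <- v
  }
  d <- diff(df$time_s)
  if (any(d <= 0)) {
    stop(sprintf("%s: time column not strictly increasing at line %d",
                 path, which(d <= 0)[1L] + 2L), call. = FALSE)
  }
  if (any(abs(d - d[1L]) > 1e-9 * max(abs(d[1L]), 1))) {
    stop(sprintf("%s: non-uniform sampling at line %d", path,
                 which(abs(d - d[1L]) > 1e-9 * max(abs(d[1L]), 1))[1L] + 2L),
         call. = FALSE)
  }
  list(
    aorta = ts_curve(df$time_s, df$aorta_signal, n_precontrast),
    kidney = ts_curve(df$time_s, df$kidney_signal, n_precontrast)
  )
}

#' Read and validate cohort metadata
#'
#' Parses a CSV with columns `subject_id`, `hct_fraction`, `volume_ml`,
#' `n_precontrast`, optional `ref_gfr_ml_min` and `curve_file`. Hematocrit
#' must be a fraction in (0, 1) — percent values are rejected — and
#' volumes must be positive; violations name the subject. A missing
#' reference column yields valid records with a warning that agreement
#' statistics are disabled.
#'
#' @param path Metadata CSV path.
#' @return A data.frame of validated subject stubs.
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "hct_fraction", "volume_ml", "n_precontrast")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    id <- df$subject_id[i]
    h <- df$hct_fraction[i]
    v <- df$volume_ml[i]
    if (!is.finite(h) || h <= 0 || h >= 1) {
      stop(sprintf(
        "subject %s: hct_fraction %.4g outside (0, 1); hematocrit must be a fraction, not percent",
        id, h), call. = FALSE)
    }
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("subject %s: volume_ml must be > 0", id), call. = FALSE)
    }
  }
  if (!"ref_gfr_ml_min" %in% names(df)) {
    warning("no ref_gfr_ml_min column: agreement statistics disabled",
            call. = FALSE)
    df$ref_gfr_ml_min <- NA_real_
  }
  df
}

#' Write a simulated cohort to a directory
#'
#' Writes one curve CSV per subject, a `metadata.csv`, a
#' `ground_truth.csv` (simulated cohorts only) and a `manifest.json`
#' carrying the seed, the full configuration and its MD5 hash for
#' provenance.
#'
#' @param cohort List of `subject_record`s from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The [cohort_config()] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  truth <- list()
  for (s in cohort) {
    f <- paste0(s$subject_id, ".csv")
    write_curves(s$aorta_curve, s$kidney_curve, file.path(dir, f))
    meta[[length(meta) + 1L]] <- data.frame(
      subject_id = s$subject_id, hct_fraction = s$hct,
      volume_ml = s$parenchymal_volume,
      n_precontrast = s$aorta_curve$n_precontrast,
      ref_gfr_ml_min = s$reference_gfr %||% NA_real_, curve_file = f,
      stringsAsFactors = FALSE
    )
    if (!is.null(s$ground_truth)) {
      gt <- s$ground_truth
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = s$subject_id, gfr_v = gt$kidney$gfr_v,
        v_p = gt$kidney$v_p, delay = gt$kidney$delay,
        t_disp = gt$kidney$t_disp, t_tub = gt$kidney$t_tub,
        gfr_ml_min = gt$gfr_ml_min,
        end_of_uptake_s = gt$end_of_uptake_time,
        a1 = gt$aif$a1, b1 = gt$aif$b1, c1 = gt$aif$c1, t1 = gt$aif$t1,
        a2 = gt$aif$a2, b2 = gt$aif$b2, c2 = gt$aif$c2, t2 = gt$aif$t2,
        stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(do.call(rbind, meta), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  if (length(truth) > 0L) {
    utils::write.csv(do.call(rbind, truth),
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  manifest <- list(
    package = "gfr2c",
    version = as.character(utils::packageVersion("gfr2c")),
    n_subjects = length(cohort),
    seed = if (is.null(config)) NA else config$seed,
    config = if (is.null(config)) NULL else unclass(config)
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  manifest$config_md5 <- unname(tools::md5sum(mf))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory back into subject records
#'
#' Counterpart of [write_cohort()]: reads `metadata.csv`, the per-subject
#' curve files and, if present, `ground_truth.csv`.
#'
#' @param dir Cohort directory.
#' @return A list of `subject_record`s.
#' @export
read_cohort <- function(dir) {
  meta <- read_cohort_metadata(file.path(dir, "metadata.csv"))
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) {
    utils::read.csv(gt_path, stringsAsFactors = FALSE)
  } else NULL
  lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    curves <- read_curves(file.path(dir, row$curve_file), row$n_precontrast)
    truth <- NULL
    if (!is.null(gt)) {
      g <- gt[gt$subject_id == row$subject_id, ]
      if (nrow(g) == 1L) {
        truth <- list(
          aif = aif_model(g$a1, g$b1, g$c1, g$t1, g$a2, g$b2, g$c2, g$t2),
          kidney = kidney_params(g$v_p, g$gfr_v, g$delay, g$t_disp, g$t_tub),
          end_of_uptake_time = g$end_of_uptake_s,
          gfr_ml_min = g$gfr_ml_min
        )
      }
    }
    structure(
      list(subject_id = row$subject_id, aorta_curve = curves$aorta,
           kidney_curve = curves$kidney, hct = row$hct_fraction,
           parenchymal_volume = row$volume_ml,
           reference_gfr = row$ref_gfr_ml_min, ground_truth = truth),
      class = "subject_record"
    )
  })
}

#' Write cohort fit results to a delimited text file
#'
#' One row per subject x method x hct_mode, with a `# seed=` / `# md5=`
#' provenance comment header.
#'
#' @param results Data.frame from [fit_cohort()].
#' @param path Output CSV path.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NA) {
  tmp <- tempfile()
  utils::write.csv(results, tmp, row.names = FALSE)
  md5 <- unname(tools::md5sum(tmp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gfr2c results; seed=%s; md5=%s", seed, md5), con)
  writeLines(readLines(tmp), con)
  unlink(tmp)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Results CSV path.
#' @return The results data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
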