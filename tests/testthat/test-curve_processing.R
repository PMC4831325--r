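test_that("enhancement subtracts the precontrast baseline", {
  tm <- acq_times(4)
  flat <- enhancement_curve(ts_curve(tm, rep(7, 4), n_precontrast = 2))
  expect_equal(flat$values, rep(0, 4))
  crv <- enhancement_curve(ts_curve(tm, c(10, 10, 12, 14), n_precontrast = 2))
  expect_equal(crv$values, c(0, 0, 2, 4))
  expect_equal(crv$baseline_mean, 10)
  noisy <- enhancement_curve(ts_curve(acq_times(), rnorm(135, 50, 2),
                                      n_precontrast = 10))
  expect_equal(mean(noisy$values[1:10]), 0)
  expect_error(enhancement_curve(ts_curve(tm, 1:4)), "precontrast")
})

test_that("postaortic rise is the sample before the sustained increase", {
  # baseline of 12 alternating +/-1 samples (SD about 1), step of 100 at
  # sample 13
  v <- c(rep(c(1, -1), 6), rep(100, 10))
  crv <- enhancement_curve(ts_curve(acq_times(22), v, n_precontrast = 12))
  cfg <- detection_config(rise_sigma_k = 3, persistence = 2)
  expect_identical(detect_postaortic_rise(crv, cfg), 12L)
  # all-zero curve: no rise
  zero <- enhancement_curve(ts_curve(acq_times(20), rep(5, 20),
                                     n_precontrast = 5))
  expect_error(detect_postaortic_rise(zero), "no aortic rise")
  # missing baseline metadata
  expect_error(detect_postaortic_rise(ts_curve(acq_times(20), 1:20)),
               "baseline")
})

test_that("detected rise time matches the simulated AIF onset", {
  set.seed(3)
  sub <- simulate_subject(quiet_config(), "s")
  plasma <- plasma_correct(enhancement_curve(sub$aorta_curve), sub$hct)
  rise <- detect_postaortic_rise(plasma)
  t1 <- sub$ground_truth$aif$t1
  expect_lte(abs(plasma$times[rise] - t1), 1.7)
})

test_that("moving-average smoothing preserves length and reduces variance", {
  tm <- acq_times(3)
  crv <- ts_curve(tm, c(0, 3, 0))
  expect_equal(smooth_curve(crv, 1)$values, c(0, 3, 0))
  expect_equal(smooth_curve(crv, 3)$values, c(1.5, 1, 1.5))
  expect_error(smooth_curve(crv, 2), "odd")
  set.seed(11)
  noise <- ts_curve(acq_times(200), rnorm(200))
  expect_lt(var(smooth_curve(noise, 5)$values), var(noise$values))
})

test_that("end-of-uptake picks the peak before outflow or the plateau start", {
  cfg <- detection_config(smoothing_window = 1)
  # triangle: rises to sample 51, falls after
  tri <- ts_curve(acq_times(80), c(rep(0, 2), 1:49, 48:20), 2)
  det <- detect_end_of_uptake(enhancement_curve(tri), 2, cfg)
  expect_identical(det$end_of_uptake_index, 51L)
  expect_identical(det$mode, "outflow_defined")
  expect_equal(det$uptake_interval, (51 - 2) * 1.7)
  # ramp that flattens at sample 41 and stays constant
  ramp <- ts_curve(acq_times(61), c(0:40, rep(40, 20)), 1)
  det2 <- detect_end_of_uptake(enhancement_curve(ramp), 1, cfg)
  expect_identical(det2$end_of_uptake_index, 41L)
  expect_identical(det2$mode, "plateau")
  # truncated mid-uptake: pure ramp has neither outflow nor plateau
  mono <- ts_curve(acq_times(50), c(0, 0, seq_len(48)), 2)
  expect_error(detect_end_of_uptake(enhancement_curve(mono), 2, cfg),
               "truncated|filtration")
  # manual override
  det3 <- detect_end_of_uptake(enhancement_curve(tri), 2, cfg,
                               override_index = 40)
  expect_identical(det3$end_of_uptake_index, 40L)
  expect_identical(det3$mode, "manual")
})

test_that("detection is deterministic and shift-invariant", {
  set.seed(21)
  sub <- simulate_subject(cohort_config(n_subjects = 1), "s")
  enh <- enhancement_curve(sub$kidney_curve)
  d1 <- detect_end_of_uptake(enh, 13)
  d2 <- detect_end_of_uptake(enh, 13)
  expect_identical(d1, d2)
  shifted <- ts_curve(enh$times, enh$values + 25, enh$n_precontrast,
                      enh$baseline_mean, enh$baseline_sd)
  d3 <- detect_end_of_uptake(shifted, 13)
  expect_identical(d1$end_of_uptake_index, d3$end_of_uptake_index)
  expect_identical(d1$mode, d3$mode)
})

test_that("noise-free cohort detections land on the true filtration peak", {
  cfg <- quiet_config(50)
  cohort <- simulate_cohort(cfg)
  n_in_band <- 0L
  for (sub in cohort) {
    plasma <- plasma_correct(enhancement_curve(sub$aorta_curve), sub$hct)
    rise <- detect_postaortic_rise(plasma)
    det <- detect_end_of_uptake(enhancement_curve(sub$kidney_curve), rise)
    expect_identical(det$mode, "outflow_defined")
    expect_lte(abs(det$end_of_uptake_index -
                     sub$ground_truth$end_of_uptake_index), 2L)
    if (det$uptake_interval >= 64 && det$uptake_interval <= 141) {
      n_in_band <- n_in_band + 1L
    }
  }
  expect_gte(n_in_band / length(cohort), 0.95)
})
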