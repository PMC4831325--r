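test_that("hematocrit follows the CBC formula and rejects bad inputs", {
  expect_equal(hct_from_cbc(5.0, 82), 41.0)
  expect_equal(hct_from_cbc(4.0, 75), 30.0)
  expect_error(hct_from_cbc(0, 80), "positive")
  expect_error(hct_from_cbc(5, -1), "positive")
})

test_that("plasma correction scales by 1/(1 - Hct) and validates hct", {
  tm <- c(0, 1)
  expect_equal(plasma_correct(ts_curve(tm, c(1, 1)), 0)$values, c(1, 1))
  expect_equal(plasma_correct(ts_curve(tm, c(0.59, 0.59)), 0.41)$values,
               c(1, 1))
  crv <- ts_curve(acq_times(20), rnorm(20, 10, 2))
  a <- plasma_correct(crv, 0.41)$values
  b <- plasma_correct(crv, 0.30)$values
  expect_equal(b / a, rep(0.59 / 0.70, 20), tolerance = 1e-12)
  expect_identical(plasma_correct(crv, 0.3)$times, crv$times)
  expect_error(plasma_correct(crv, 1), "fraction")
  expect_error(plasma_correct(crv, -0.1), "fraction")
})

test_that("two-gamma AIF evaluates lobes with onset and superposition", {
  aif <- demo_aif()
  tm <- acq_times()
  v <- eval_aif(aif, tm)$values
  expect_true(all(v[tm < aif$t1] == 0))
  # b = 1 single lobe peaks at t1 + c with height a*c*exp(-1)
  single <- aif_model(a1 = 2, b1 = 1, c1 = 6.8, t1 = 17)
  peak_t <- 17 + 6.8
  grid <- seq(0, 60, by = 0.85)   # contains peak_t exactly
  pv <- eval_aif(single, grid)$values
  expect_equal(grid[which.max(pv)], peak_t)
  expect_equal(max(pv), 2 * 6.8 * exp(-1), tolerance = 1e-12)
  # superposition of the two lobes
  lobe1 <- aif_model(aif$a1, aif$b1, aif$c1, aif$t1)
  lobe2 <- aif_model(aif$a2, aif$b2, aif$c2, aif$t2)
  expect_equal(v, eval_aif(lobe1, tm)$values + eval_aif(lobe2, tm)$values,
               tolerance = 1e-12)
  # onset convention: b = 0 gives a boxcar-decay lobe with value a at onset
  box <- aif_model(a1 = 3, b1 = 0, c1 = 10, t1 = 1.7)
  expect_equal(eval_aif(box, c(0, 1.7, 3.4))$values[2], 3)
  expect_error(aif_model(1, 1, 1, 10, t2 = 5), "t2")
  expect_error(aif_model(1, 1, -1, 0), "decay")
})

test_that("plasma compartment solves the dispersion ODE", {
  tm <- acq_times()
  # zero input -> zero response
  none <- aif_model(a1 = 0, b1 = 1, c1 = 10, t1 = 0)
  expect_true(all(plasma_compartment_response(none, 0, 5, tm)$values == 0))
  # unit step input: closed form 1 - exp(-t/t_disp)
  step_in <- aif_model(a1 = 1, b1 = 0, c1 = 1e12, t1 = 0)
  for (td in c(1, 4, 15)) {
    p <- plasma_compartment_response(step_in, 0, td, tm)$values
    expect_lt(max(abs(p - (1 - exp(-tm / td)))), 1e-6)
  }
  expect_error(plasma_compartment_response(demo_aif(), 0, 0, tm), "t_disp")
  expect_error(plasma_compartment_response(demo_aif(), -1, 2, tm), "delay")
})

test_that("convolution matches brute-force ODE integration (oracle)", {
  tm <- acq_times()
  set.seed(421)
  for (i in 1:20) {
    aif <- aif_model(runif(1, 5, 50), runif(1, 1, 4), runif(1, 3, 10),
                     runif(1, 15, 25), runif(1, 1, 5), runif(1, 0.5, 2),
                     runif(1, 30, 90), runif(1, 35, 50))
    delay <- runif(1, 0, 5)
    td <- runif(1, 1, 15)
    p <- plasma_compartment_response(aif, delay, td, tm)$values
    sol <- deSolve::ode(
      y = 0, times = tm, parms = NULL, method = "lsoda",
      rtol = 1e-11, atol = 1e-12,
      func = function(t, y, parms) {
        list((eval_aif(aif, c(t - delay - 1, t - delay))$values[2] - y) / td)
      }
    )
    expect_lt(rel_dev(p, sol[, 2]), 1e-6)
  }
})

test_that("uptake model combines vascular and accumulation terms", {
  tm <- acq_times()
  aif <- demo_aif()
  p <- plasma_compartment_response(aif, 1.5, 4, tm)$values
  # gfr_v = 0: purely vascular
  vasc <- forward_uptake(kidney_params(0.2, 0, 1.5, 4), aif, tm)$values
  expect_equal(vasc, 0.2 * p, tolerance = 1e-12)
  # v_p = 0: accumulation matches an independent trapezoid of P
  acc <- forward_uptake(kidney_params(0, 0.4, 1.5, 4), aif, tm)$values
  trapz <- c(0, cumsum((p[-1] + p[-length(p)]) / 2)) * 1.7 * 0.4 / 60
  expect_true(all(diff(acc) >= -1e-12))
  expect_lt(rel_dev(acc, trapz), 2e-3)
  # linearity in AIF amplitude
  aif2 <- aif_model(2 * aif$a1, aif$b1, aif$c1, aif$t1,
                    2 * aif$a2, aif$b2, aif$c2, aif$t2)
  up1 <- forward_uptake(demo_kidney(), aif, tm)$values
  up2 <- forward_uptake(demo_kidney(), aif2, tm)$values
  expect_lt(rel_dev(up2, 2 * up1), 1e-10)
})

test_that("inflow-outflow model nests the uptake model", {
  tm <- acq_times()
  aif <- demo_aif()
  up <- forward_uptake(demo_kidney(), aif, tm)$values
  # no-outflow limit
  io_inf <- forward_inflow_outflow(demo_kidney(1e9), aif, tm)$values
  expect_lt(rel_dev(io_inf, up), 1e-5)
  # gfr_v = 0: identical vascular-only curve
  v1 <- forward_inflow_outflow(kidney_params(0.2, 0, 1.5, 4, 300),
                               aif, tm)$values
  v2 <- forward_uptake(kidney_params(0.2, 0, 1.5, 4), aif, tm)$values
  expect_equal(v1, v2, tolerance = 1e-12)
  # outflow can only remove tracer
  io <- forward_inflow_outflow(demo_kidney(300), aif, tm)$values
  expect_true(all(io <= up + 1e-12))
  expect_error(forward_inflow_outflow(demo_kidney(NA), aif, tm), "t_tub")
})

test_that("scalar conversions are dimensionally consistent", {
  expect_equal(gfr_from_gfrv(0, 241), 0)
  expect_equal(gfr_from_gfrv(0.40, 241), 96.4)
  expect_equal(gfr_from_gfrv(0.30, 200), 60)
  expect_error(gfr_from_gfrv(-0.1, 241), ">= 0")
  expect_equal(rpf_from_params(demo_kidney()), 60 * 0.2 / 4)
})
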