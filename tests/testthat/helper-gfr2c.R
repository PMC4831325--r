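# shared fixtures, built in code

acq_times <- function(n = 135L, dt = 1.7) (seq_len(n) - 1L) * dt

# a plasma AIF with both lobes clearly expressed
demo_aif <- function() {
  aif_model(a1 = 2, b1 = 3, c1 = 5, t1 = 20.4,
            a2 = 0.5, b2 = 1.2, c2 = 40, t2 = 42)
}

demo_kidney <- function(t_tub = NA_real_) {
  kidney_params(v_p = 0.2, gfr_v = 0.4, delay = 1.5, t_disp = 4,
                t_tub = t_tub)
}

# maximum deviation relative to the scale of the reference curve
rel_dev <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# a small noise-free cohort configuration for recovery-style tests
quiet_config <- function(n = 5L, seed = 20160413L, ...) {
  cohort_config(n_subjects = n, seed = seed, noise_sd = 0,
                reference_noise_sd = 0, ...)
}
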