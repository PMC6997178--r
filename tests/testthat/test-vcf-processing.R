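# Baseline correction, dF/F, and F-V / G-V extraction.

test_that("baseline correction removes the fitted trend", {
  t <- seq(0, 6, by = 0.01)
  # constant trace -> identically zero
  bc <- baseline_correct(rep(2.5, length(t)), t, fit_window = 2, holding_s = 2)
  expect_lt(max(abs(bc$corrected)), 1e-12)
  expect_equal(bc$f0, 2.5, tolerance = 1e-12)
  # linear drift, linear model: exact removal
  tr <- 3 + 0.2 * t
  bc <- baseline_correct(tr, t, fit_window = 2, holding_s = 2)
  expect_lt(max(abs(bc$corrected)), 1e-9)
  # pure exponential bleach, exponential model: residual < 1% of amplitude
  tr <- 5 * exp(-t / 4)
  bc <- baseline_correct(tr, t, fit_window = 2, holding_s = 2,
                         model = "exponential")
  expect_lt(sqrt(mean(bc$corrected^2)), 0.01 * 5)
  # fit window longer than holding period is rejected
  expect_error(baseline_correct(tr, t, fit_window = 3, holding_s = 2),
               "holding")
})

test_that("dF/F is the corrected trace over F0", {
  expect_equal(compute_dff(rep(0, 5), 2), rep(0, 5))
  expect_equal(compute_dff(2, 2), 1.0)
  expect_error(compute_dff(1, 0), "positive")
  expect_error(compute_dff(1, -3), "positive")
})

test_that("plateau dF/F matches the forward signal model", {
  s <- default_scheme()
  proto <- voltage_protocol(test_mV = c(-60, 0, 60), dt = 0.002)
  rec <- simulate_vcf_recording(s, NULL, proto, bleach_tau = Inf,
                                noise_sd = 0, seed = 1)
  sw <- rec[rec$sweep_id == 3, ]
  bc <- baseline_correct(sw$fluorescence, sw$time_s, fit_window = 2,
                         holding_s = 2, model = "linear")
  dff <- compute_dff(bc$corrected, bc$f0)
  pulse_end <- proto$holding_s + proto$test_s
  plateau <- mean(dff[sw$time_s >= pulse_end - 0.1 & sw$time_s < pulse_end])
  occ_end <- drop(steady_state_occupancy(s, v = 60))
  occ_hold <- drop(steady_state_occupancy(s, v = proto$holding_mV))
  m_end <- s$f1_amp * (occ_end["p_i"] + occ_end["p_a"]) +
    s$f2_amp * occ_end["p_a"]
  m_hold <- s$f1_amp * (occ_hold["p_i"] + occ_hold["p_a"]) +
    s$f2_amp * occ_hold["p_a"]
  # F0 is the fitted baseline level, which includes the resting modulation
  expected <- (m_end - m_hold) / (1 + m_hold)
  expect_equal(plateau, unname(expected), tolerance = 0.02)
})

test_that("F-V extraction normalises to the maximum and preserves shape", {
  s <- default_scheme()
  rec <- simulate_vcf_recording(s, NULL, voltage_protocol(), noise_sd = 0)
  # exponential baseline: the simulated bleach is mono-exponential, and the
  # default linear model leaves a small curvature residual
  fv <- extract_fv(rec, baseline_model = "exponential")
  expect_equal(max(fv$value), 1.0)
  expect_false(attr(fv, "degenerate"))
  # monotone saturating truth -> monotone curve above the resting baseline
  rising <- fv$value[fv$voltage_mV >= -80]
  expect_true(all(diff(rising) > -1e-9))
  # analytic steady-state F-V (same -80 mV reference) matches closely
  occ <- steady_state_occupancy(s, v = fv$voltage_mV)
  occ0 <- drop(steady_state_occupancy(s, v = -80))
  f <- s$f1_amp * (occ[, "p_i"] + occ[, "p_a"]) + s$f2_amp * occ[, "p_a"]
  f0 <- s$f1_amp * (occ0["p_i"] + occ0["p_a"]) + s$f2_amp * occ0["p_a"]
  expected <- (f - f0) / max(f - f0)
  expect_equal(fv$value, unname(expected), tolerance = 0.02)
  expect_error(extract_fv(rec[rec$sweep_id == 1, , drop = FALSE]))
})

test_that("G-V extraction tracks the open probability at the pulse end", {
  s <- default_scheme()
  rec <- simulate_vcf_recording(s, NULL, voltage_protocol(), noise_sd = 0)
  gv <- extract_gv(rec)
  expect_equal(max(gv$value), 1.0)
  occ <- steady_state_occupancy(s, v = gv$voltage_mV)
  g <- s$g_io * occ[, "p_i"] + s$g_ao * occ[, "p_a"]
  expect_equal(gv$value, unname(g / max(g)), tolerance = 0.03)
  # with g_AO = 0 the curve tracks P_I
  mod <- construct_modifier(g_ao_scale = 0)
  rec2 <- simulate_vcf_recording(s, mod, voltage_protocol(), noise_sd = 0)
  gv2 <- extract_gv(rec2)
  occ2 <- steady_state_occupancy(s, mod, gv2$voltage_mV)
  expect_equal(gv2$value, unname(occ2[, "p_i"] / max(occ2[, "p_i"])),
               tolerance = 0.05)
  # tail window outside the tail step is rejected
  expect_error(extract_gv(rec, settle_s = 0.4, window_s = 0.2), "tail")
})

test_that("degenerate (no-signal) normalisation is flagged, not silent", {
  s <- default_scheme()
  mod <- construct_modifier(g_io_scale = 0, g_ao_scale = 0)
  rec <- simulate_vcf_recording(s, mod, voltage_protocol(),
                                noise_sd = c(current = 0.05, fluorescence = 0),
                                seed = 9)
  expect_warning(gv <- extract_gv(rec), "degenerate")
  expect_true(attr(gv, "degenerate"))
})

test_that("curve extraction is idempotent and curves round-trip as text", {
  s <- default_scheme()
  rec <- simulate_vcf_recording(s, NULL, voltage_protocol(),
                                noise_sd = c(current = 0.2,
                                             fluorescence = 0.002),
                                seed = 5)
  fv1 <- extract_fv(rec); fv2 <- extract_fv(rec)
  gv1 <- extract_gv(rec); gv2 <- extract_gv(rec)
  expect_identical(fv1, fv2)
  expect_identical(gv1, gv2)
  path <- tempfile(fileext = ".tsv")
  write_xy_curve(gv1, path)
  expect_equal(read_xy_curve(path)$value, gv1$value, tolerance = 1e-12)
})

test_that("extracted curves match analytic curves within noise on replicates", {
  s <- default_scheme()
  occ <- steady_state_occupancy(s, v = voltage_protocol()$test_mV)
  g_true <- s$g_io * occ[, "p_i"] + s$g_ao * occ[, "p_a"]
  g_true <- unname(g_true / max(g_true))
  errs <- sapply(1:5, function(r) {
    rec <- simulate_vcf_recording(s, NULL, voltage_protocol(),
                                  noise_sd = c(current = 0.3,
                                               fluorescence = 0.002),
                                  seed = 100 + r)
    max(abs(extract_gv(rec)$value - g_true))
  })
  # tail mean over ~4 samples with sd 0.3 on tail currents of ~40 units,
  # normalised: allow a generous 3x band
  expect_lt(max(errs), 0.05)
})
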