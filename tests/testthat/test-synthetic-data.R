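test_that("gamma moment matching solves the closed-form system", {
  g <- match_gamma_moments(2, 1, 1)
  expect_equal(g$shape, 4)
  expect_equal(g$scale, 0.5)
  expect_equal(g$shift, 0)
  # matched distribution reproduces the requested moments analytically
  for (tgt in list(c(0.895, 0.419, 1.37), c(5, 2, 0.5))) {
    g <- match_gamma_moments(tgt[1], tgt[2], tgt[3])
    expect_equal(g$shift + g$shape * g$scale, tgt[1])
    expect_equal(sqrt(g$shape) * g$scale, tgt[2])
    expect_equal(2 / sqrt(g$shape), tgt[3])
  }
  expect_error(match_gamma_moments(1, 0.1, 0), class = "protospike_error")
})

test_that("zero-skew specs fall back to a symmetric amplitude law", {
  spec <- test_spec(amp_skew = 0, amp_min = 0, amp_max = 2)
  x <- sample_amplitudes(spec, 1e5, seed = 11)
  expect_lt(abs(sample_skewness(x)), 0.05)
  expect_equal(mean(x), spec$amp_mean, tolerance = 0.02)
})

test_that("built-in amplitude draws hit the calibration means within 2%", {
  for (spec in builtin_conditions()) {
    x <- sample_amplitudes(spec, 1e5, seed = 7)
    expect_equal(mean(x), spec$amp_mean, tolerance = 0.02,
                 label = paste(spec$label, "amplitude mean"))
    expect_true(all(x >= spec$amp_min & x <= spec$amp_max))
    # clipping at the published sample extremes removes tail mass, so the
    # sampled SD sits below target but within ~15%
    expect_lt(sd(x), spec$amp_sd * 1.005)
    expect_gt(sd(x), spec$amp_sd * 0.85)
  }
})

test_that("built-in ISI draws hit the calibration means within 2% and stay in range", {
  for (spec in builtin_conditions()) {
    x <- sample_isis(spec, 1e5, seed = 7, on_infeasible = "quiet")
    expect_equal(mean(x), spec$isi_mean, tolerance = 0.02,
                 label = paste(spec$label, "ISI mean"))
    expect_true(all(x >= spec$isi_min & x <= spec$isi_max))
  }
})

test_that("truncated-normal solver matches a numerical-integration oracle", {
  # feasible targets: solver's (mu, sigma) must reproduce the target
  # moments under independent numerical integration
  cases <- list(c(1000, 200, 595.24, 1952.38),
                c(60, 15, 20, 120),
                c(0.9, 0.3, 0.2, 2.0))
  for (cs in cases) {
    m <- match_truncnorm_moments(cs[1], cs[2], cs[3], cs[4])
    expect_true(m$feasible)
    or <- truncnorm_moments_numint(m$mu, m$sigma, cs[3], cs[4])
    expect_equal(unname(or["mean"]), cs[1], tolerance = 1e-3 / cs[1])
    expect_equal(unname(or["sd"]), cs[2], tolerance = 1e-3)
  }
  # untruncated limit: plain normal
  m <- match_truncnorm_moments(5, 2, -Inf, Inf)
  expect_equal(m$mu, 5)
  expect_equal(m$sigma, 2)
})

test_that("infeasible ISI moment targets are reported explicitly", {
  # an SD target beyond the uniform-limit bound (width/sqrt(12)) of the
  # truncation support cannot be attained
  spec <- test_spec(isi_mean = 60, isi_sd = 40, isi_min = 20, isi_max = 120)
  expect_warning(sample_isis(spec, 10, seed = 1),
                 class = "protospike_warning_infeasible_moments")
  expect_error(sample_isis(spec, 10, seed = 1, on_infeasible = "error"),
               class = "infeasible_moments")
  x <- sample_isis(spec, 1e4, seed = 1, on_infeasible = "quiet")
  fit <- attr(x, "moment_fit")
  expect_false(fit$feasible)
  # the mean is still matched exactly
  expect_equal(fit$attained_mean, 60, tolerance = 1e-6)
  expect_equal(mean(x), 60, tolerance = 0.02)
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- test_spec()
  a <- generate_voltage_trace(spec, 50, seed = 123)
  b <- generate_voltage_trace(spec, 50, seed = 123)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$events$times, b$events$times)
  c <- generate_voltage_trace(spec, 50, seed = 124)
  expect_false(identical(a$trace$values, c$trace$values))
})

test_that("render_trace places pulses of the requested height on a clean baseline", {
  spec <- test_spec(noise_sd = 0, drift_amplitude = 0)
  # no events: all-zero trace
  tr <- render_trace(spike_events(numeric(0), numeric(0)), 100, spec)
  expect_true(all(tr$values == 0))
  # single event: sampled peak equals the amplitude within 2%
  tr <- render_trace(spike_events(100, 1.0), 400, spec)
  expect_equal(max(tr$values), 1.0, tolerance = 0.02)
  # baseline is exactly zero before the pulse onset
  expect_true(all(tr$values[trace_times(tr) < 100] == 0))
  # event times must precede the duration
  expect_error(render_trace(spike_events(500, 1), 400, spec),
               class = "render_invalid")
})

test_that("current traces show the published condition ordering and relaxation", {
  # zero spike rate, zero noise: constant baseline
  tr <- generate_current_trace("control", 100, seed = 1, spike_rate = 0,
                               noise_sd = 0)
  expect_true(all(tr$values == tr$values[1]))
  expect_identical(tr$unit, "uA")
  # solvation at 25 mg/mL depresses the mean current below control;
  # vapour exposure raises it
  ctl <- generate_current_trace("control", 3600, seed = 5)
  low <- generate_current_trace("25 mg/mL", 3600, seed = 5)
  vap <- generate_current_trace("0.5 cm2", 3600, seed = 5)
  expect_lt(mean(low$values), mean(ctl$values))
  expect_gt(mean(vap$values), mean(ctl$values))
  # relaxation constant recovered from a single noiseless transient
  tau <- 0.5
  tr <- generate_current_trace("control", 60, seed = 4, dt = 0.02,
                               spike_rate = 1 / 60, relax_tau = tau,
                               noise_sd = 0)
  v <- tr$values - min(tr$values)
  ipk <- which.max(v)
  idx <- ipk:(ipk + 25)  # first half second of the decay
  fit <- stats::lm(log(v[idx]) ~ trace_times(tr)[idx])
  expect_equal(-1 / unname(coef(fit)[2]), tau, tolerance = 0.1)
  expect_error(generate_current_trace("control", 5), class = "sample_invalid")
})
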