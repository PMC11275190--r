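test_that("a flat trace yields no spikes", {
  tr <- trace(rep(0, 1000), dt = 1, unit = "mV")
  ev <- detect_spikes(tr, threshold = 0.1, min_prominence = 0.05)
  expect_length(ev$times, 0)
})

test_that("peaks within the refractory window merge, keeping the larger", {
  v <- rep(0, 200)
  v[101] <- 0.5
  v[111] <- 0.8  # 10 s later
  tr <- trace(v, dt = 1, unit = "mV")
  ev <- detect_spikes(tr, threshold = 0.1, min_prominence = 0.1,
                      refractory = 30)
  expect_length(ev$times, 1)
  expect_equal(ev$amplitudes, 0.8)
  # outside the refractory window both survive
  ev2 <- detect_spikes(tr, threshold = 0.1, min_prominence = 0.1,
                       refractory = 5)
  expect_length(ev2$times, 2)
  expect_error(detect_spikes(tr, threshold = -1), class = "detect_invalid")
})

test_that("rendered spikes are recovered with their amplitudes", {
  spec <- test_spec(noise_sd = 0, drift_amplitude = 0)
  amps <- c(0.8, 1.2, 0.5, 1.6, 1.0)
  ev_in <- spike_events(c(300, 650, 1000, 1350, 1700), amps)
  tr <- render_trace(ev_in, 2100, spec)
  ev <- detect_spikes(tr, threshold = 0.1, min_prominence = 0.1)
  expect_length(ev$times, 5)
  expect_equal(ev$amplitudes, amps, tolerance = 0.05)
})

test_that("moment summaries use the stated estimator conventions", {
  # symmetric three-point train
  ev <- spike_events(c(0, 60, 120), c(1, 2, 3))
  s <- summarize_spikes(ev, "sym")
  expect_equal(s$amplitude$Mean, 2)
  expect_equal(s$amplitude$StdDev, 1)       # sample (n-1) SD
  expect_equal(s$amplitude$Skewness, 0)
  # hand-computed moment oracle for [1,1,1,5]:
  # m2 = 3, m3 = 6, m4 = 21 => g1 = 6/3^1.5, kurt = 21/9
  ev <- spike_events(c(0, 60, 120, 180), c(1, 1, 1, 5))
  s <- summarize_spikes(ev, "asym")
  expect_equal(s$amplitude$Skewness, 6 / 3^1.5)
  expect_equal(s$amplitude$Kurtosis, 21 / 9)
  # ISI stats come from successive peak-time differences
  expect_equal(s$isi$Mean, 60)
  expect_equal(s$sem_isi, 0)
  expect_error(summarize_spikes(spike_events(c(0, 60), c(1, 1))),
               class = "insufficient_spikes")
})

test_that("amplitude statistics are scale-equivariant under MAD thresholds", {
  spec <- test_spec()
  gen <- generate_voltage_trace(spec, 60, seed = 17)
  fit <- detrend_trace(gen$trace)
  s1 <- summarize_spikes(detect_spikes(fit$residual), "x1")
  scaled <- fit$residual
  scaled$values <- scaled$values * 3
  s3 <- summarize_spikes(detect_spikes(scaled), "x3")
  for (col in c("Mean", "StdDev", "Max", "Min"))
    expect_equal(s3$amplitude[[col]], 3 * s1$amplitude[[col]],
                 tolerance = 1e-9)
  expect_equal(s3$amplitude$Skewness, s1$amplitude$Skewness,
               tolerance = 1e-9)
  expect_equal(s3$amplitude$Kurtosis, s1$amplitude$Kurtosis,
               tolerance = 1e-9)
})

test_that("the full pipeline recovers the vapour-condition calibration means", {
  # the remaining built-in conditions (control and 25 mg/mL are exercised
  # in the acceptance suite)
  specs <- builtin_conditions()[c("0.5 cm2", "1 cm2", "3 cm2")]
  for (spec in specs) {
    r <- recover_condition(spec, n_spikes = 500, seed = 2024)
    expect_equal(r$summary$amplitude$Mean, spec$amp_mean, tolerance = 0.05,
                 label = paste(spec$label, "amplitude mean"))
    expect_equal(r$summary$isi$Mean, spec$isi_mean, tolerance = 0.05,
                 label = paste(spec$label, "ISI mean"))
  }
})
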