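test_that("WAK cycle-mean flow equals frequency times stroke volume exactly", {
  w <- synthesize_waveform("WAK", frequency = 110, stroke_volume = 0.8)
  m <- time_mean(w)
  expect_equal(m[["Q_b_in"]], 88, tolerance = 1e-12)
  expect_equal(m[["Q_d_in"]], 88, tolerance = 1e-12)
  # zero stroke volume: identically zero flow
  w0 <- synthesize_waveform("WAK", frequency = 110, stroke_volume = 0)
  expect_equal(max(abs(w0$series$Q_b_in)), 0)
})

test_that("WAK channels are counter-phased", {
  w <- synthesize_waveform("WAK")
  pb <- w$series$P_b_in - mean(w$series$P_b_in)
  pd <- w$series$P_d_in - mean(w$series$P_d_in)
  expect_lt(sum(pb * pd) / sqrt(sum(pb^2) * sum(pd^2)), 0)
  # counter-phasing maximizes the instantaneous trans-membrane pressure:
  # the cycle peak of (P_b - P_d) exceeds that of an in-phase variant
  # with the identical per-channel excursions (whose TMP stays at the
  # mean separation), at the same cycle-mean TMP
  pd_inphase <- 2 * mean(w$series$P_d_in) - w$series$P_d_in
  expect_gt(
    max(w$series$P_b_in - w$series$P_d_in),
    max(w$series$P_b_in - pd_inphase)
  )
  expect_equal(mean(w$series$P_b_in - w$series$P_d_in),
    mean(w$series$P_b_in - pd_inphase), tolerance = 1e-10)
})

test_that("peak-flow sharpening preserves the cycle mean", {
  w <- synthesize_waveform("WAK", frequency = 110, stroke_volume = 0.8,
    peak_flow = 350)
  m <- time_mean(w)
  expect_equal(m[["Q_b_in"]], 88, tolerance = 1e-12)
  expect_equal(max(w$series$Q_b_in), 350, tolerance = 0.01)
})

test_that("roller waveform is quasi-steady (low ripple)", {
  w <- synthesize_waveform("roller_centrifugal", frequency = 13,
    stroke_volume = 8, ripple = 0.05)
  q <- w$series$Q_b_in
  expect_equal(time_mean(w)[["Q_b_in"]], 104, tolerance = 1e-12)
  expect_lt((max(q) - min(q)) / mean(q), 0.2)
})

test_that("time averaging uses complete cycles only", {
  w <- synthesize_waveform("WAK", frequency = 60, stroke_volume = 1,
    pressure_means = list(P_b_in = 50, P_b_out = 45, P_d_in = -20, P_d_out = -25),
    pressure_amplitude = 30, n_cycles = 3)
  # sinusoidal pressure with mean 50 over integer cycles
  expect_equal(time_mean(w)[["P_b_in"]], 50, tolerance = 1e-10)
  # truncate to 2.5 cycles: warning, average over 2
  w$time <- w$time[1:500]
  w$series <- w$series[1:500, ]
  expect_warning(m <- time_mean(w), "complete cycle")
  expect_equal(m[["P_b_in"]], 50, tolerance = 1e-10)
})

test_that("quasi-steadiness verdict follows the lumen Womersley number", {
  qs <- quasi_steady_check(m60, saline, urea_properties(), frequency = 2)
  expect_equal(round(qs$alpha[["blood_momentum"]], 1), 0.4)
  expect_true(qs$quasi_steady)
  qs0 <- quasi_steady_check(m60, saline, urea_properties(), frequency = 0)
  expect_equal(unname(qs0$alpha["blood_momentum"]), 0)
  qs200 <- quasi_steady_check(m60, saline, urea_properties(), frequency = 200)
  expect_gt(qs200$alpha[["blood_momentum"]], 1)
  expect_false(qs200$quasi_steady)
})
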