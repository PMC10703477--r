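test_that("set_time_base imposes i/fs and is idempotent", {
  s <- signal_trace("x", c(0, 1, 3, 7, 8), 1:5)
  s2 <- set_time_base(s, 100)
  expect_equal(s2$times, c(0, 0.01, 0.02, 0.03, 0.04))
  expect_identical(s2$values, s$values)
  expect_equal(set_time_base(s2, 100)$times, s2$times)
  expect_error(set_time_base(s, 0), class = "validation_error")
})

test_that("resampling spans the same window and preserves endpoints", {
  t <- seq(0, 1, by = 0.01)            # 101 samples at 100 Hz
  s <- signal_trace("r", t, sin(2 * pi * 3 * t))
  down <- resample_signal(s, 50)
  expect_length(down$values, 51L)
  expect_equal(down$times[51L], 1)
  expect_equal(down$values[c(1L, 51L)], s$values[c(1L, 101L)])
  same <- resample_signal(s, 100)
  expect_equal(same$values, s$values, tolerance = 1e-12)
  const <- resample_signal(signal_trace("c", t, rep(4, 101)), 37, "cubic")
  expect_equal(const$values, rep(4, length(const$values)), tolerance = 1e-9)
  nonuni <- signal_trace("n", c(0, 1, 3, 6, 10, 11, 12, 13), 1:8)
  expect_error(resample_signal(nonuni, 10), class = "contract_error")
})

test_that("butterworth attenuates the stopband and passes the passband", {
  t <- seq(0, 10, by = 1e-3)
  tone30 <- signal_trace("t30", t, sin(2 * pi * 30 * t))
  filtered <- butterworth(tone30, "stop", c(29, 31), order = 4)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(filtered$values), 0.1 * rms(tone30$values))
  tone5 <- signal_trace("t5", t, sin(2 * pi * 5 * t))
  lp <- butterworth(tone5, "low", 100)
  core <- seq(500, length(t) - 500)    # exclude edges
  expect_lt(rms(lp$values[core] - tone5$values[core]), 0.01 * rms(tone5$values))
  expect_error(butterworth(tone5, "low", 600), class = "validation_error")
  expect_error(butterworth(tone5, "band", c(31, 29)), class = "validation_error")
})

test_that("zero-phase filtering leaves a tone's phase untouched", {
  t <- seq(0, 2, by = 1e-3)
  s <- signal_trace("tone", t, sin(2 * pi * 10 * t))
  f <- butterworth(s, "low", 50, zero_phase = TRUE)
  cc <- cross_correlation(s$values, f$values, max_lag = 50)
  expect_identical(cc$peak_lag, 0L)
  # single-pass filtering, in contrast, delays the signal
  f1 <- butterworth(s, "low", 20, zero_phase = FALSE, order = 4)
  cc1 <- cross_correlation(s$values, f1$values, max_lag = 50)
  expect_gt(cc1$peak_lag, 0L)
})

test_that("rectification variants follow their definitions", {
  s <- signal_trace("r", 0:2, c(-1, 2, -3))
  expect_equal(rectify(s, "half_wave")$values, c(0, 2, 0))
  expect_equal(rectify(s, "absolute")$values, c(1, 2, 3))
  expect_equal(rectify(s, "square_root")$values, rectify(s, "absolute")$values)
  s2 <- signal_trace("m", 0:2, c(1, 2, 3))
  expect_equal(rectify(s2, "mean")$values, c(-1, 0, 1))
})

test_that("envelopes recover amplitudes of stationary tones", {
  t <- seq(0, 2, by = 1e-3)
  s <- signal_trace("tone", t, sin(2 * pi * 5 * t))
  h <- envelope(s, "hilbert")
  margin <- seq(0.05 * length(t), 0.95 * length(t))
  expect_lt(max(abs(h$values[margin] - 1)), 0.01)
  # moving RMS of a long sine sits at A/sqrt(2)
  amp <- 3
  s2 <- signal_trace("a", t, amp * sin(2 * pi * 50 * t))
  r <- envelope(s2, "moving_rms", w = 201)
  expect_lt(max(abs(r$values[margin] - amp / sqrt(2))), 0.01 * amp)
  expect_equal(envelope(signal_trace("rms3", 0:2, c(0, 3, 0)),
                        "moving_rms", w = 3)$values[2L], sqrt(3))
  cst <- signal_trace("c", 0:9, rep(-2, 10))
  expect_equal(envelope(cst, "hilbert")$values, rep(2, 10), tolerance = 1e-9)
  expect_equal(envelope(cst, "moving_mean", w = 3)$values, rep(-2, 10))
  expect_error(envelope(s, "moving_mean", w = 4), class = "validation_error")
})

test_that("lowpass envelope checks the rectification history", {
  t <- seq(0, 1, by = 1e-3)
  s <- signal_trace("emg", t, sin(2 * pi * 40 * t))
  expect_error(envelope(s, "lowpass", fc = 5), class = "contract_error")
  expect_silent(envelope(rectify(s, "absolute"), "lowpass", fc = 5))
  expect_silent(envelope(s, "lowpass", fc = 5, force = TRUE))
})

test_that("the periodogram satisfies Parseval and finds single tones", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  s <- signal_trace("tone", t, sin(2 * pi * 25 * t))
  sp <- power_spectrum(s)
  expect_equal(sum(sp$power), mean(s$values^2), tolerance = 1e-6)
  expect_equal(peak_frequency(sp), 25, tolerance = 0.1)
  # Parseval holds for arbitrary signals, odd and even lengths
  set.seed(11)
  for (n in c(256L, 257L)) {
    r <- signal_trace("r", seq_len(n) - 1L, rnorm(n) + 2)
    spr <- power_spectrum(r)
    expect_equal(sum(spr$power), mean(r$values^2), tolerance = 1e-6)
  }
  expect_error(power_spectrum(signal_trace("s", 0:3, 1:4)),
               class = "validation_error")
})

test_that("the three-tone mixture shows and loses its component peaks", {
  mx <- gen_sine_mixture()$signals$mixture
  sp <- power_spectrum(mx)
  bin <- function(sp, f) sp$power[which.min(abs(sp$frequencies - f))]
  floor_power <- stats::median(sp$power)
  for (f in c(25, 30, 35)) expect_gt(bin(sp, f), 1e6 * floor_power)
  filt <- butterworth(butterworth(mx, "stop", c(29, 31)), "stop", c(34, 36))
  spf <- power_spectrum(filt)
  expect_equal(peak_frequency(spf), 25, tolerance = 0.1)
  expect_lt(bin(spf, 30), 0.01 * bin(spf, 25))
  expect_lt(bin(spf, 35), 0.01 * bin(spf, 25))
})

test_that("spectrogram layout and content track the window parameters", {
  t <- (0:1023) / 1000
  s <- signal_trace("tone", t, sin(2 * pi * 25 * t))
  sg <- spectrogram(s, 256, 0.5)
  expect_identical(ncol(sg$power), 7L)            # floor((n-w)/hop)+1
  expect_identical(nrow(sg$power), 129L)
  peaks <- apply(sg$power[-1L, ], 2L, which.max)
  expect_true(all(abs(sg$frequencies[-1L][peaks] - 25) <= 1000 / 256))
  # frequency switch shows up at the right end
  v <- c(sin(2 * pi * 10 * t[1:512]), sin(2 * pi * 40 * t[513:1024]))
  sw <- spectrogram(signal_trace("sw", t, v), 256, 0, "hann")
  pk <- apply(sw$power[-1L, ], 2L, function(col)
    sw$frequencies[-1L][which.max(col)])
  expect_lt(pk[1L], 20); expect_gt(pk[4L], 30)
  expect_error(spectrogram(s, 2048), class = "validation_error")
})

test_that("area under the curve integrates trapezoidally", {
  s <- signal_trace("c", seq(0, 2, by = 0.1), rep(1, 21))
  expect_equal(area_under_curve(s, 0, 2), 2, tolerance = 1e-12)
  tri <- signal_trace("tri", c(0, 1, 2), c(0, 1, 0))
  expect_equal(area_under_curve(tri, 0, 2), 1)
  t <- seq(0, 1, by = 1e-3)
  sine <- signal_trace("s", t, sin(2 * pi * t))
  expect_lt(abs(area_under_curve(sine, 0, 1)), 1e-6)
  expect_equal(area_under_curve(s, 0.05, 0.15), 0.1)  # interpolated bounds
  expect_error(area_under_curve(s, 1, 0.5), class = "validation_error")
  expect_error(area_under_curve(s, 0, 5), class = "validation_error")
})
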