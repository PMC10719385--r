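# Filtering, envelope and resampling against analytic oracles.

fs <- 2343.8
tt <- (0:(5 * fs)) / fs

# steady-state amplitude of a filtered tone, away from the edges
tone_amp <- function(y) {
  n <- length(y)
  max(abs(y[round(n * 0.3):round(n * 0.7)]))
}

test_that("band-pass preserves mid-band tones and rejects DC", {
  x <- sin(2 * pi * 60 * tt)
  expect_equal(tone_amp(bandpass_filter(x, fs)[1, ]), 1, tolerance = 0.02)
  # DC offset must not change the output
  y0 <- bandpass_filter(x, fs)
  y5 <- bandpass_filter(x + 5, fs)
  expect_lt(max(abs(y5 - y0)), 1e-6 * sqrt(mean(x^2)))
})

test_that("stop-band attenuation matches the analytic Butterworth response", {
  # forward-backward squares the order-4 band-pass magnitude response
  f <- 10
  x <- sin(2 * pi * f * tt)
  got <- tone_amp(bandpass_filter(x, fs)[1, ])
  f0sq <- 25 * 100
  q <- (f^2 - f0sq) / (f * (100 - 25))
  expected <- (1 / (1 + q^8))  # |H|^2 with |H|^2 = 1/(1+q^(2n)), n = 4
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("band-stop notches 50 Hz and passes neighbours", {
  expect_lt(tone_amp(bandstop_filter(sin(2 * pi * 50 * tt), fs)[1, ]), 0.01)
  expect_equal(tone_amp(bandstop_filter(sin(2 * pi * 75 * tt), fs)[1, ]), 1,
               tolerance = 0.02)
  # mixture: 80 Hz survives, 50 Hz dies (FFT-coefficient oracle on the
  # steady-state middle section, away from edge transients)
  n <- 32768L
  t2 <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 50 * t2) + sin(2 * pi * 80 * t2)
  y <- bandstop_filter(x, fs)[1, ]
  mid <- 8193:24576
  w <- mmgdecode:::hann_window(length(mid))
  amp_at <- function(sig, f) {
    z <- abs(stats::fft(sig[mid] * w))
    2 * z[round(f * length(mid) / fs) + 1] / sum(w)
  }
  expect_equal(amp_at(y, 80), amp_at(x, 80), tolerance = 0.02)
  expect_lt(amp_at(y, 50), 0.01)
})

test_that("zero-phase property: filtering commutes with time reversal", {
  set.seed(5)
  x <- stats::rnorm(20000)
  y1 <- bandpass_filter(x, fs)[1, ]
  y2 <- rev(bandpass_filter(rev(x), fs)[1, ])
  expect_lt(max(abs(y1 - y2)) / max(abs(y1)), 1e-8)
  # no phase shift: cross-correlation of a band-limited tone peaks at lag 0
  tone <- sin(2 * pi * 60 * tt)
  yf <- bandpass_filter(tone, fs)[1, ]
  cc <- stats::ccf(yf, tone, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("Hilbert envelope recovers amplitude and modulation", {
  expect_equal(mean(hilbert_envelope(3 * sin(2 * pi * 40 * tt))[1, 2000:9000]),
               3, tolerance = 0.02)
  expect_equal(hilbert_envelope(matrix(0, 1, 100)), matrix(0, 1, 100))
  am <- (1 + 0.5 * sin(2 * pi * 2 * tt)) * sin(2 * pi * 60 * tt)
  env <- hilbert_envelope(am)[1, ]
  want <- 1 + 0.5 * sin(2 * pi * 2 * tt)
  mid <- 2000:9000
  expect_lt(max(abs(env[mid] - want[mid])) / max(want), 0.03)
})

test_that("resampling produces the documented length and waveform", {
  x <- matrix(sin(2 * pi * 5 * (0:11718) / fs), 1)
  r <- resample_signal(x, fs, 200)
  expect_identical(ncol(r), 1000L)  # 5 s at 2343.8 Hz -> 1000 samples
  want <- sin(2 * pi * 5 * (0:999) / 200)
  expect_lt(sqrt(mean((r[1, ] - want)^2)), 0.01)
  # constants survive exactly (up to filter ripple)
  rc <- resample_signal(matrix(2.5, 1, 11719), fs, 200)
  expect_equal(as.numeric(rc), rep(2.5, 1000), tolerance = 1e-3)
  expect_error(resample_signal(x, 200, 500), "upsampling")
})

test_that("preprocessing pipeline: notch logic, stationarity, metadata", {
  ch <- channel_table("EMG", 2L)
  mk_rec <- function(data) structure(
    list(data = data, fs = fs, channels = ch, session_id = 7L),
    class = "recording")
  # pure 50 Hz input -> virtually no envelope
  x50 <- rbind(sin(2 * pi * 50 * tt), sin(2 * pi * 50 * tt))
  env <- preprocess_recording(mk_rec(x50))
  expect_lt(max(env$data[, 200:800]), 0.02)
  expect_identical(env$fs, 200)
  expect_identical(env$channels, ch)
  expect_identical(env$session_id, 7L)
  expect_true(all(env$data >= 0))
  # white-noise input -> stationary envelope
  set.seed(8)
  xn <- matrix(stats::rnorm(2 * length(tt)), 2)
  envn <- preprocess_recording(mk_rec(xn))$data
  m1 <- mean(envn[, 1:500]); m2 <- mean(envn[, 501:1000])
  expect_lt(abs(m1 - m2) / m1, 0.10)
})

test_that("channels are processed independently", {
  set.seed(6)
  x <- matrix(stats::rnorm(2 * 8000), 2)
  joint <- bandpass_filter(x, fs)
  solo <- bandpass_filter(x[2, ], fs)
  expect_equal(joint[2, ], solo[1, ])
})

test_that("filter edge validation", {
  x <- stats::rnorm(1000)
  expect_error(bandpass_filter(x, fs, low = 0, high = 100), "band edges")
  expect_error(bandpass_filter(x, fs, low = 25, high = 2000), "band edges")
  expect_error(bandpass_filter(c(x, NA), fs), "finite")
})
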