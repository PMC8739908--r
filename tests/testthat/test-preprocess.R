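test_that("wavelet centre frequencies: db4 is 0.7 to one decimal, haar ~1", {
  expect_equal(round(wavelet_center_frequency("db4"), 1), 0.7)
  expect_lt(abs(wavelet_center_frequency("haar") - 1.0), 0.02)
  expect_identical(wavelet_center_frequency("db4"),
                   wavelet_center_frequency("db4"))
  expect_error(wavelet_center_frequency("nosuch"), "unknown wavelet")
})

test_that("pseudofrequency follows R_c * fs / 2^a", {
  expect_equal(round(pseudofrequency(0.7, 360, 9), 1), 0.5)
  expect_equal(pseudofrequency(0.7, 360, 9), 0.7 * 360 / 512)
  expect_equal(pseudofrequency(0.7, 360, 0), 252)
  a <- 0:11
  expect_equal(pseudofrequency(0.7, 500, a + 1),
               pseudofrequency(0.7, 500, a) / 2)
})

test_that("baseline scale selection reaches the drift band", {
  expect_equal(select_baseline_scale(0.7, 360, 0.5), 9)
  expect_equal(select_baseline_scale(0.7, 720, 0.5), 10)
  # direct evaluation oracle: smallest a with rounded pseudofrequency <= 0.5
  oracle <- function(rc, fs) {
    for (a in 1:20) if (round(rc * fs / 2^a, 1) <= 0.5) return(a)
  }
  for (fs in c(128, 250, 260, 360, 500, 720, 1000))
    expect_equal(select_baseline_scale(0.7, fs, 0.5), oracle(0.7, fs))
  # drift target above the first-scale pseudofrequency
  expect_equal(select_baseline_scale(0.7, 360, 200), 1)
})

test_that("DWT decompose-reconstruct is a perfect-reconstruction pair", {
  set.seed(1)
  x <- rnorm(2^12)
  for (w in c("haar", "db2", "db4", "sym4")) {
    d <- dwt(x, w, 6)
    expect_lt(max(abs(idwt(d) - x)) / max(abs(x)), 1e-8)
  }
  d9 <- dwt(x, "db4", 9)
  expect_lt(max(abs(idwt(d9) - x)) / max(abs(x)), 1e-8)
  expect_error(dwt(rnorm(100), "db4", 5), "divisible")
})

test_that("baseline removal suppresses drift and preserves cardiac content", {
  fs <- 360
  n <- 7200
  tt <- (0:(n - 1)) / fs
  drift <- sin(2 * pi * 0.3 * tt)
  out <- remove_baseline_dwt(ecg_record(drift, fs))
  expect_lt(sqrt(mean(out$samples^2) / mean(drift^2)), 0.10)

  zero <- remove_baseline_dwt(ecg_record(rep(0, n), fs), fs = fs)
  expect_equal(zero$samples, rep(0, n))

  sim <- generate_ecg(clean_config(duration_s = 20))
  x <- sim$record$samples
  noisy <- x + sin(2 * pi * 0.3 * tt)
  cleaned <- remove_baseline_dwt(ecg_record(noisy, fs))$samples
  expect_lt(sqrt(mean((cleaned - x)^2)), sqrt(mean((noisy - x)^2)))

  expect_error(remove_baseline_dwt(ecg_record(rnorm(100), fs)),
               "too short")
})

test_that("baseline removal is linear", {
  fs <- 360
  set.seed(4)
  x <- rnorm(4000); y <- rnorm(4000)
  f <- function(v) remove_baseline_dwt(ecg_record(v, fs))$samples
  expect_lt(max(abs(f(x + y) - (f(x) + f(y)))), 1e-10)
})

test_that("bandpass attenuates out-of-band tones and passes in-band ones", {
  fs <- 360
  tone <- function(f0) sin(2 * pi * f0 * (0:(20 * fs - 1)) / fs)
  gain <- function(f0, spec) {
    y <- bandpass_filter(tone(f0), spec, fs = fs)
    mid <- (5 * fs):(15 * fs)
    sqrt(mean(y[mid]^2) / mean(tone(f0)[mid]^2))
  }
  expect_lt(20 * log10(gain(60, bandpass_spec())), -20)
  expect_lt(abs(20 * log10(gain(10, bandpass_spec()))), 1)
  dc <- bandpass_filter(rep(1, 4000), bandpass_spec(), fs = fs)
  expect_lt(abs(mean(dc)), 0.01)
  # classification chain: 60 Hz is also strongly attenuated
  expect_lt(20 * log10(gain(60, bandpass_spec(0.5, 35,
                                              "butter_fir_combo"))), -20)
})

test_that("filtering is zero-phase: a symmetric pulse stays symmetric", {
  pulse <- exp(-((1:999) - 500)^2 / 50)
  y <- bandpass_filter(pulse, bandpass_spec(), fs = 360)
  expect_equal(which.max(y), 500)
  expect_lt(max(abs(y - rev(y))), 1e-6)
})

test_that("resampling preserves duration and spectral content", {
  fs <- 360
  rec <- ecg_record(sin(2 * pi * 5 * (0:(10 * fs - 1)) / fs), fs)
  rs <- resample_record(rec, 260)
  expect_equal(rs$fs, 260)
  expect_lte(abs(length(rs$samples) - 2600), 1)
  # dominant frequency unchanged
  spec <- Mod(stats::fft(rs$samples))[1:1300]
  f_peak <- (which.max(spec[-1])) * 260 / length(rs$samples)
  expect_lt(abs(f_peak - 5), 0.2)
  expect_identical(resample_record(rec, fs), rec)
})

test_that("beat segmentation yields odd-length centred windows", {
  expect_length(segment_beats(ecg_record(rnorm(1000), 260),
                              c(500))[[1]], 65)
  expect_length(segment_beats(ecg_record(rnorm(1000), 360),
                              c(500))[[1]], 91)
  # boundary beats are dropped with a warning
  expect_warning(
    segs <- segment_beats(ecg_record(rnorm(1000), 360), c(10, 500)),
    "dropped")
  expect_length(segs, 1)
  expect_equal(attr(segs, "dropped"), 1L)
  expect_length(segment_beats(ecg_record(rnorm(1000), 360),
                              numeric(0)), 0)
  # centring: the peak sample sits mid-window
  x <- numeric(1000); x[500] <- 1
  s <- segment_beats(ecg_record(x, 360), 500)[[1]]
  expect_equal(which.max(s), 46)
})

test_that("segment normalisation maps exactly onto [-1, 1]", {
  expect_equal(normalize_segment(c(0, 5, 10)), c(-1, 0, 1))
  v <- c(-1, 0.3, 1, -0.2)
  expect_equal(normalize_segment(v), v)
  set.seed(2)
  for (i in 1:5) {
    z <- normalize_segment(rnorm(50))
    expect_equal(min(z), -1)
    expect_equal(max(z), 1)
  }
  expect_warning(out <- normalize_segment(rep(3, 10)), "constant")
  expect_equal(out, rep(0, 10), ignore_attr = TRUE)
})
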