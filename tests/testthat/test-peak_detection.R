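test_that("background subtraction matches the brute-force windowed median", {
  set.seed(21)
  fs <- 100
  x <- cumsum(rnorm(10000, 0, 0.3)) + 50  # wandering baseline
  half <- floor(5 * fs / 2)
  expect_equal(subtract_background(x, fs, window = 5),
               x - naive_rolling_median(x, half), tolerance = 0)
  # constant series maps to zero
  expect_equal(subtract_background(rep(7, 400), fs), rep(0, 400))
})

test_that("an isolated fast transient survives background subtraction", {
  fs <- 1000
  x <- rep(100, 10000)
  peak_idx <- 5000 + seq(-25, 25)  # 50 ms pulse on a 5 s window
  x[peak_idx] <- 100 + 40 * exp(-(seq(-25, 25))^2 / (2 * 10^2))
  bg <- subtract_background(x, fs, window = 5)
  expect_equal(max(bg), 40, tolerance = 0.01)
  expect_equal(which.max(bg), 5000)
})

test_that("noise estimation matches the brute-force windowed sd", {
  set.seed(22)
  fs <- 50
  x <- rnorm(10000, 0, 2) * (1 + 0.5 * sin(seq_len(10000) / 2000))
  half <- floor(60 * fs / 2)
  got <- estimate_noise(x, fs, window = 60)$sigma
  want <- naive_rolling_sd(x, half)
  expect_lt(max(abs(got - want) / want), 1e-9)
  expect_equal(estimate_noise(rep(0, 500), fs)$sigma, rep(0, 500))
})

test_that("windowed sigma tracks iid Gaussian noise within 5%", {
  set.seed(23)
  fs <- 100
  x <- rnorm(10 * 60 * fs, 0, 2.0)  # 10 min trace
  sigma <- estimate_noise(x, fs, window = 60)$sigma
  expect_gte(mean(abs(sigma - 2) / 2 < 0.05), 0.99)
})

test_that("peak-masked noise estimation is not inflated by frequent pulses", {
  set.seed(24)
  fs <- 500
  n <- 240 * fs
  x <- rnorm(n, 0, 1)
  # 50 pulses/min of 30-80 mV: a concentrated phantom suspension
  centers <- sample(fs:(n - fs), 200)
  for (ct in centers) {
    idx <- ct + seq(-100, 100)
    x[idx] <- x[idx] + runif(1, 30, 80) * exp(-seq(-100, 100)^2 / (2 * 25^2))
  }
  plain <- estimate_noise(x, fs, window = 60)$sigma
  masked <- estimate_noise(x, fs, window = 60, mask_peaks = TRUE)$sigma
  expect_gt(median(plain), 2)            # unmasked estimate blows up
  # sub-threshold pulse flanks bound the residual inflation
  expect_lt(abs(median(masked) - 1), 0.25)
})

test_that("snr_db implements 20 log10(amplitude/sigma)", {
  expect_equal(snr_db(5, 1), 20 * log10(5))
  expect_equal(snr_db(1, 1), 0)
  expect_equal(snr_db(10, 1), 20)
  expect_error(snr_db(-1, 1), "positive")
  expect_error(snr_db(1, 0), "positive")
})

test_that("an injected 10-sigma peak yields exactly one candidate at its time", {
  set.seed(25)
  fs <- 1000
  x <- rnorm(60 * fs)
  center <- 30 * fs
  x <- x + 10 * exp(-(seq_along(x) - center)^2 / (2 * 30^2))
  noise <- estimate_noise(x, fs)
  cand <- find_candidates(x, noise, fs)
  expect_identical(nrow(cand), 1L)
  # the regional maximum of pulse + noise jitters around the injected center
  expect_lt(abs(cand$time_s - (center - 1) / fs), 0.03)
  # and its value is the pulse height plus an extreme-value noise excess
  expect_gt(cand$amplitude_sigma, 9)
  expect_lt(cand$amplitude_sigma, 14)
  expect_gt(cand$width_s, 0)
})

test_that("a 4.9-sigma peak stays below the detection threshold", {
  fs <- 1000
  x <- numeric(20 * fs)
  x <- x + 4.9 * exp(-(seq_along(x) - 10 * fs)^2 / (2 * 30^2))
  cand <- find_candidates(x, rep(1, length(x)), fs)
  expect_identical(nrow(cand), 0L)
})

test_that("every emitted candidate meets the 13.9 dB SNR floor", {
  set.seed(26)
  fs <- 500
  x <- rnorm(120 * fs)
  for (ct in c(20, 47, 80, 100) * fs) {
    x[ct + seq(-60, 60)] <- x[ct + seq(-60, 60)] +
      runif(1, 5, 60) * exp(-seq(-60, 60)^2 / (2 * 15^2))
  }
  cand <- find_candidates(x, estimate_noise(x, fs), fs)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$snr_db >= 20 * log10(5) - 1e-9))
  expect_true(all(cand$amplitude_sigma >= 5))
})

test_that("candidate count is monotone in the detection threshold", {
  set.seed(27)
  fs <- 200
  x <- rnorm(120 * fs)
  for (ct in seq(10, 110, by = 5) * fs) {
    x[ct + seq(-40, 40)] <- x[ct + seq(-40, 40)] +
      runif(1, 3, 15) * exp(-seq(-40, 40)^2 / (2 * 10^2))
  }
  noise <- estimate_noise(x, fs)
  counts <- vapply(c(3, 4, 5, 6, 8), function(k) {
    nrow(find_candidates(x, noise, fs, k = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(find_candidates(x, noise, fs, k = 0), "positive")
})

test_that("plateau peaks are reported once, at the plateau midpoint", {
  fs <- 100
  x <- numeric(1000)
  x[500:509] <- 10  # 10-sample plateau
  cand <- find_candidates(x, rep(1, 1000), fs)
  expect_identical(nrow(cand), 1L)
  expect_equal(cand$time_s, (504 - 1) / fs)  # midpoint sample
})

test_that("noise ripple riding on a peak's flank is not a second candidate", {
  fs <- 1000
  x <- 50 * exp(-(seq_len(10000) - 5000)^2 / (2 * 50^2))
  x[5150] <- x[5150] + 3  # bump on the flank, still above threshold region
  cand <- find_candidates(x, rep(1, 10000), fs)
  expect_identical(nrow(cand), 1L)
})

test_that("FWHM is measured by linear interpolation at half maximum", {
  fs <- 1000
  sd_samp <- 40
  x <- 20 * exp(-(seq_len(8000) - 4000)^2 / (2 * sd_samp^2))
  cand <- find_candidates(x, rep(1, 8000), fs)
  expect_equal(cand$width_s, 2 * sqrt(2 * log(2)) * sd_samp / fs,
               tolerance = 0.01)
})

test_that("detect_peaks annotates candidates with channel, probe and color", {
  scan <- make_test_scan(n = 4000, fs = 200, seed = 30)
  scan$signal$p1_green[2000 + seq(-20, 20)] <-
    scan$signal$p1_green[2000 + seq(-20, 20)] +
    30 * exp(-seq(-20, 20)^2 / (2 * 6^2))
  cand <- detect_peaks(scan)
  expect_true(all(c("id", "channel", "probe", "color") %in% names(cand)))
  hit <- cand[cand$channel == "p1_green" & abs(cand$time_s - 10) < 0.1, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$probe, 1L)
  expect_identical(hit$color, "green")
})
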