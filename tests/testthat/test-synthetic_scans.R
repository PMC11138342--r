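test_that("identical config and seed give identical events and scans", {
  cfg <- preset_config("phantom_single", duration_s = 30)
  a <- simulate_scan(cfg, 5)
  b <- simulate_scan(cfg, 5)
  expect_identical(a$events, b$events)
  expect_identical(a$scan$signal, b$scan$signal)
  c <- simulate_scan(cfg, 6)
  expect_false(identical(a$events, c$events))
})

test_that("zero concentration yields zero events", {
  cfg <- preset_config("phantom_single", duration_s = 60,
                       concentration = c(green = 0, orange = 0),
                       artifact_rate_per_min = 0)
  expect_identical(nrow(sample_events(cfg, 3)), 0L)
})

test_that("event counts follow the concentration x flow x duration mean", {
  # 1000/mL at 25 uL/min for 60 min: Poisson mean 1500 per color
  cfg <- preset_config("phantom_single", duration_s = 3600)
  counts <- vapply(1:5, function(s) {
    ev <- sample_events(cfg, s)
    sum(ev$population == "green")
  }, numeric(1))
  expect_true(all(abs(counts - 1500) < 3 * sqrt(1500)))
})

test_that("rendered pulses appear on probe 2 with the delay the speed implies", {
  cfg <- sim_config(duration_s = 10, concentration = c(green = 0, orange = 0),
                    noise_sigma = 0, background_mV = 0, drift_amp_mV = 0,
                    speed_mean = 30)
  ev <- data.frame(time_s = 4, population = "green", n_green = 1L,
                   n_orange = 0L, amp_green_mV = 80, amp_orange_mV = 0,
                   direction = "forward", speed_mm_s = 30,
                   is_artifact = FALSE)
  scan <- render_scan(ev, cfg, seed = 1)
  t <- scan_times(scan)
  expect_equal(t[which.max(scan$signal$p1_green)], 4, tolerance = 1e-3)
  expect_equal(t[which.max(scan$signal$p2_green)], 4 + 3 / 30,
               tolerance = 1e-3)
  # FWHM = sensing_length / speed
  g <- scan$signal$p1_green
  above_half <- sum(g >= max(g) / 2) / scan$sampling_rate
  expect_equal(above_half, 1 / 30, tolerance = 0.1)
})

test_that("spectral bleed is rendered at the configured ratio", {
  cfg <- sim_config(duration_s = 10, noise_sigma = 0, background_mV = 0,
                    drift_amp_mV = 0, bleed_TR = c(green = 0.05, orange = 0.08))
  ev <- data.frame(time_s = 5, population = "green", n_green = 1L,
                   n_orange = 0L, amp_green_mV = 100, amp_orange_mV = 0,
                   direction = "forward", speed_mm_s = 8,
                   is_artifact = FALSE)
  scan <- render_scan(ev, cfg, seed = 1)
  expect_equal(max(scan$signal$p1_orange) / max(scan$signal$p1_green), 0.05,
               tolerance = 1e-9)
})

test_that("event-free noiseless traces equal the configured background", {
  cfg <- sim_config(duration_s = 5, concentration = c(green = 0, orange = 0),
                    noise_sigma = 0, background_mV = 20, drift_amp_mV = 2,
                    drift_period_s = 60)
  scan <- render_scan(sample_events(cfg, 1), cfg, seed = 1)
  t <- scan_times(scan)
  expect_equal(scan$signal$p1_green, 20 + 2 * sin(2 * pi * t / 60))
  expect_identical(scan$signal$p1_green, scan$signal$p2_orange)
})

test_that("traces clip at the PMT rail, above the saturation limit", {
  cfg <- sim_config(duration_s = 4, noise_sigma = 0, background_mV = 0,
                    drift_amp_mV = 0, pmt_rail_mV = 3000)
  ev <- data.frame(time_s = 2, population = "green", n_green = 60L,
                   n_orange = 0L, amp_green_mV = 60 * 100, amp_orange_mV = 0,
                   direction = "forward", speed_mm_s = 8,
                   is_artifact = FALSE)
  scan <- render_scan(ev, cfg, seed = 1)
  expect_equal(max(scan$signal$p1_green), 3000)
  expect_gt(max(scan$signal$p1_green), 1500)  # catchable by the curation rule
})

test_that("artifacts render simultaneously on all four channels", {
  cfg <- sim_config(duration_s = 10, concentration = c(green = 0, orange = 0),
                    noise_sigma = 0, background_mV = 0, drift_amp_mV = 0)
  ev <- data.frame(time_s = 5, population = "artifact", n_green = 0L,
                   n_orange = 0L, amp_green_mV = 50, amp_orange_mV = 50,
                   direction = "forward", speed_mm_s = 8, is_artifact = TRUE)
  scan <- render_scan(ev, cfg, seed = 1)
  peaks <- vapply(scan$signal, which.max, integer(1))
  expect_true(all(peaks == peaks[1]))
  expect_true(all(vapply(scan$signal, max, numeric(1)) == 50))
})

test_that("events too fast to span two samples are skipped with a warning", {
  cfg <- sim_config(duration_s = 2, sampling_rate = 100)
  ev <- data.frame(time_s = 1, population = "green", n_green = 1L,
                   n_orange = 0L, amp_green_mV = 50, amp_orange_mV = 0,
                   direction = "forward", speed_mm_s = 120,  # FWHM < 2 samples
                   is_artifact = FALSE)
  expect_warning(render_scan(ev, cfg, seed = 1), "skipped")
})

test_that("presets encode the phantom study conditions", {
  ps <- preset_config("phantom_single")
  expect_equal(ps$concentration[["green"]], 1000)
  expect_equal(ps$concentration[["orange"]], 1000)
  expect_equal(ps$flow_uL_min, 25)
  pc <- preset_config("phantom_cluster")
  # ~1000 clusters/mL per color, mean cluster ~10 cells => ~10^4 cells/mL
  expect_equal(pc$concentration[["green"]], 1000)
  mean_size <- 1 + pc$cluster_size_dist$lambda
  expect_equal(pc$concentration[["green"]] * mean_size, 1e4)
  iv <- preset_config("invivo_mm")
  expect_false(is.null(iv$rate_modulation))
  expect_error(preset_config("swim_phantom"), "arg")
})

test_that("mixed clusters contain at least one cell of each color", {
  cfg <- preset_config("phantom_cluster", duration_s = 600, twoFP_mixing = 1)
  ev <- sample_events(cfg, 9)
  mixed <- ev[ev$n_green > 0 & ev$n_orange > 0, ]
  expect_gt(nrow(mixed), 0)
  multi <- ev[ev$n_green + ev$n_orange >= 2 & !ev$is_artifact, ]
  expect_true(all(multi$n_green >= 1 & multi$n_orange >= 1))
})
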