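test_that("bleed_max_secondary evaluates the closed form", {
  expect_equal(bleed_max_secondary(10, 0), 10 * (0 + 5) / (10 - 5))  # = 10
  expect_equal(bleed_max_secondary(100, 0.045), 10)
  expect_error(bleed_max_secondary(5, 0.1), "exceed")
  expect_error(bleed_max_secondary(10, -0.1), "non-negative")
})

test_that("the threshold is monotone in TR and has the right asymptotes", {
  I <- c(5.01, 6, 10, 50, 1000)
  for (ipr in I) {
    trs <- seq(0, 0.5, by = 0.05)
    vals <- bleed_max_secondary(ipr, trs)
    expect_true(all(diff(vals) > 0))
  }
  # ratio tends to TR as I_pr grows
  expect_equal(bleed_max_secondary(1e7, 0.06) / 1e7, 0.06, tolerance = 1e-5)
  # and diverges toward the detection floor
  expect_gt(bleed_max_secondary(5 + 1e-9, 0.06), 1e9)
})

test_that("single-point calibration inverts the threshold exactly", {
  # oracle: numerically solve bleed_max_secondary(100, TR) = 10 for TR
  f <- function(tr) bleed_max_secondary(100, tr) - 10
  tr_oracle <- uniroot(f, c(0, 1), tol = 1e-14)$root
  cal <- estimate_bleed_ratio(100, 10, "green")
  expect_equal(cal$TR, (10 * 95 - 500) / 10000)  # closed form 0.045
  expect_equal(cal$TR, tr_oracle, tolerance = 1e-10)
})

test_that("Eq round trip holds to machine precision on random grids", {
  set.seed(41)
  I_pr <- runif(500, 5.001, 2000)
  I_sec <- runif(500, 0, I_pr)
  tr_i <- (I_sec * (I_pr - 5) - 5 * I_pr) / I_pr^2
  keep <- tr_i >= 0
  expect_gt(sum(keep), 50)
  back <- bleed_max_secondary(I_pr[keep],
                              vapply(which(keep), function(i) {
                                estimate_bleed_ratio(I_pr[i], I_sec[i])$TR
                              }, numeric(1)))
  expect_equal(back, I_sec[keep], tolerance = 1e-12)
})

test_that("TR is the max over per-point values, clamped at zero", {
  # two points: TR_i = 0.01 and 0.045
  i1 <- 100; s1 <- (0.01 * i1^2 + 5 * i1) / (i1 - 5)
  i2 <- 100; s2 <- (0.045 * i2^2 + 5 * i2) / (i2 - 5)
  cal <- estimate_bleed_ratio(c(i1, i2), c(s1, s2))
  expect_equal(cal$TR, 0.045)
  # a zero-secondary point alone clamps to zero
  expect_identical(estimate_bleed_ratio(100, 0)$TR, 0)
  # sub-threshold points are rejected with a warning
  expect_warning(cal2 <- estimate_bleed_ratio(c(4, 100), c(1, s2)),
                 "rejected")
  expect_equal(cal2$n, 1L)
  expect_error(suppressWarnings(estimate_bleed_ratio(4, 1)), "no usable")
})

test_that("classification splits at the bleed threshold", {
  calg <- estimate_bleed_ratio(100, 10, "green")       # TR = 0.045
  calo <- estimate_bleed_ratio(100, 12, "orange")
  tl <- rbind(
    data.frame(time_s = 1, I_pr = 100, I_sec = 9.9, primary_color = "green",
               amp_pri_mV = 100, amp_sec_mV = 9.9, amplitude_mV_max = 100,
               direction = "forward", speed_mm_s = 10, width_s = 0.1),
    data.frame(time_s = 2, I_pr = 100, I_sec = 10.1, primary_color = "green",
               amp_pri_mV = 100, amp_sec_mV = 10.1, amplitude_mV_max = 100,
               direction = "forward", speed_mm_s = 10, width_s = 0.1)
  )
  out <- classify_two_lambda(tl, calg, calo)
  expect_identical(out$classification, c("oneFP", "twoFP"))
})

test_that("any calibration set self-classifies with zero 2FP detections", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    I_pr <- runif(n, 6, 1500)
    I_sec <- runif(n, 0, 0.2 * I_pr)
    cal <- estimate_bleed_ratio(I_pr, I_sec, "green")
    tl <- data.frame(time_s = seq_len(n), I_pr = I_pr, I_sec = I_sec,
                     primary_color = "green", amp_pri_mV = I_pr,
                     amp_sec_mV = I_sec, amplitude_mV_max = I_pr,
                     direction = "forward", speed_mm_s = 10, width_s = 0.1)
    out <- classify_two_lambda(tl, cal, estimate_bleed_ratio(100, 0, "orange"))
    expect_identical(sum(out$classification == "twoFP"), 0L)
  }
})

test_that("saturated and near-threshold peaks are indeterminate", {
  calg <- estimate_bleed_ratio(100, 10, "green")
  calo <- estimate_bleed_ratio(100, 10, "orange")
  tl <- rbind(
    data.frame(time_s = 1, I_pr = 2000, I_sec = 500, primary_color = "green",
               amp_pri_mV = 2000, amp_sec_mV = 500, amplitude_mV_max = 2000,
               direction = "forward", speed_mm_s = 10, width_s = 0.1),
    data.frame(time_s = 2, I_pr = 4.5, I_sec = 4, primary_color = "orange",
               amp_pri_mV = 4.5, amp_sec_mV = 4, amplitude_mV_max = 10,
               direction = "forward", speed_mm_s = 10, width_s = 0.1)
  )
  out <- classify_two_lambda(tl, calg, calo)
  expect_identical(out$classification, c("indeterminate", "indeterminate"))
  expect_identical(out$saturated, c(TRUE, FALSE))
})

test_that("saturation flagging is strictly greater-than 1500 mV", {
  expect_identical(flag_saturation(c(1600, 1500, 100)),
                   c(TRUE, FALSE, FALSE))
})

test_that("coincident green and orange matches pair into one 2-lambda peak", {
  matched <- rbind(make_matched("green", 10.00, amplitude_mV = 120,
                                amplitude_sigma = 120),
                   make_matched("orange", 10.01, amplitude_mV = 40,
                                amplitude_sigma = 40),
                   make_matched("green", 50.0))
  tl <- find_two_lambda(matched, coincidence_window = 0.05)
  expect_identical(nrow(tl$two_lambda), 1L)
  expect_identical(tl$two_lambda$primary_color, "green")
  expect_equal(tl$two_lambda$I_pr, 120)
  expect_equal(tl$two_lambda$I_sec, 40)
  expect_identical(nrow(tl$singletons), 1L)
  expect_identical(tl$singletons$color, "green")
})

test_that("green and orange on different transits do not pair", {
  # same probe-1 time but inconsistent probe-2 delay (different transit)
  g <- make_matched("green", 10.0, delay_s = 0.1)
  o <- make_matched("orange", 10.0, delay_s = 0.5)
  tl <- find_two_lambda(rbind(g, o), coincidence_window = 0.05)
  expect_identical(nrow(tl$two_lambda), 0L)
  expect_identical(nrow(tl$singletons), 2L)
})

test_that("cluster sizing follows the 3-nuclei rule for 1FP detections", {
  calg <- estimate_bleed_ratio(1000, 50, "green")
  calo <- estimate_bleed_ratio(1000, 80, "orange")
  s <- rbind(make_matched("green", 1, amplitude_mV = 2.0 * 26),
             make_matched("green", 2, amplitude_mV = 3.4 * 26),
             make_matched("orange", 3, amplitude_mV = 0.4 * 26))
  recs <- build_detection_records(s, make_matched("green", 1)[0, ],
                                  ref_green = 26, ref_orange = 26,
                                  calib_green = calg, calib_orange = calo)
  expect_identical(recs$classification,
                   c("single_1FP", "cluster_1FP", "single_1FP"))
  expect_equal(recs$n_green, c(2, 3, 0))
  expect_equal(recs$n_orange, c(0, 0, 1))  # floored at 1 for detected color
})

test_that("every 2FP detection is a cluster and sizing is bleed-corrected", {
  calg <- estimate_bleed_ratio(1000, 10, "green")  # TR ~ 0
  calo <- estimate_bleed_ratio(1000, 10, "orange")
  tl <- data.frame(time_s = 5, I_pr = 100, I_sec = 60,
                   primary_color = "orange", amp_pri_mV = 2 * 26,
                   amp_sec_mV = 1.2 * 26, amplitude_mV_max = 60,
                   direction = "forward", speed_mm_s = 10, width_s = 0.1)
  tl <- classify_two_lambda(tl, calg, calo)
  expect_identical(tl$classification, "twoFP")
  recs <- build_detection_records(make_matched("green", 1)[0, ], tl,
                                  ref_green = 26, ref_orange = 26,
                                  calib_green = calg, calib_orange = calo)
  expect_identical(recs$classification, "cluster_2FP")
  expect_equal(recs$n_orange, 2)
  expect_gte(recs$n_green, 1)
  expect_error(
    build_detection_records(make_matched("green", 1), tl, ref_green = 0,
                            ref_orange = 26, calib_green = calg,
                            calib_orange = calo),
    "positive"
  )
})

test_that("reference amplitude is the median of calibration detections", {
  expect_equal(reference_amplitude(c(20, 26, 90)), 26)
  expect_error(reference_amplitude(numeric(0)), "no calibration")
})
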