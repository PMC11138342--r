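# Shared fixtures and brute-force oracles used across test files.

# naive O(n * w) rolling median with centered, edge-truncated windows
naive_rolling_median <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# naive rolling sample standard deviation, same window convention
naive_rolling_sd <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (length(w) < 2) NA_real_ else sd(w)
  }, numeric(1))
}

# a tiny valid scan with arbitrary signal content
make_test_scan <- function(n = 100, fs = 100, seed = 1) {
  set.seed(seed)
  difc_scan(
    data.frame(
      p1_green = rnorm(n, 10), p1_orange = rnorm(n, 12),
      p2_green = rnorm(n, 11), p2_orange = rnorm(n, 9)
    ),
    sampling_rate = fs, probe_separation = 3,
    metadata = list(scan_id = "t1", subject_id = "m1", scenario = "unit")
  )
}

# candidate table row in the detect_peaks() layout
make_candidate <- function(id, channel, time_s, amplitude_mV = 50,
                           amplitude_sigma = 50, width_s = 0.1) {
  chans <- difc_channels()
  i <- match(channel, chans$channel)
  data.frame(
    id = id, channel = channel, probe = chans$probe[i],
    color = chans$color[i], time_s = time_s,
    amplitude_mV = amplitude_mV, amplitude_sigma = amplitude_sigma,
    width_s = width_s, snr_db = 20 * log10(amplitude_sigma)
  )
}

# minimal matched-detection row in the match_across_probes() layout
make_matched <- function(color, time_p1, delay_s = 0.1,
                         amplitude_mV = 100, amplitude_sigma = 100,
                         width_s = 0.1, amplitude_mV_max = NULL) {
  if (is.null(amplitude_mV_max)) amplitude_mV_max <- amplitude_mV
  data.frame(
    color = color, time_s = time_p1, time_p1 = time_p1,
    time_p2 = time_p1 + delay_s, delay_s = delay_s,
    direction = if (delay_s > 0) "forward" else "reverse",
    speed_mm_s = 3 / abs(delay_s),
    amplitude_mV = amplitude_mV, amplitude_sigma = amplitude_sigma,
    width_s = width_s, amplitude_mV_max = amplitude_mV_max,
    match_score = 0
  )
}

# valid detection-record table
make_records <- function() {
  data.frame(
    time_s = c(1.5, 10.2, 33.7, 60),
    color = c("green", "orange", "green", "orange"),
    direction = c("forward", "forward", "reverse", "forward"),
    amplitude_mV = c(52.1, 260.4, 31.9, 1800.0),
    amplitude_sigma = c(52.1, 260.4, 31.9, 1800.0),
    width_s = c(0.11, 0.13, 0.09, 0.2),
    classification = c("single_1FP", "cluster_1FP", "single_1FP",
                       "indeterminate"),
    n_green = c(1, 0, 1, NA),
    n_orange = c(0, 5, 0, NA),
    flags = c("", "", "", "saturated")
  )
}
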