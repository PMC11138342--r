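#' Moving detection rate through a scan
#'
#' Counts detections per color in a moving window (default 2 min) stepped
#' densely through the scan (default every 1 s). Edge windows are truncated
#' at the scan boundaries and their counts normalized by the actual window
#' length, so rates stay in detections per minute everywhere.
#'
#' @param times_green,times_orange detection times in seconds.
#' @param duration_s scan duration in seconds.
#' @param window_min window length in minutes (default 2).
#' @param step_s window-center step in seconds (default 1).
#' @return data.frame of class `difc_rates` with columns `time_s` (window
#'   centers), `rate_green`, `rate_orange` (per minute); attributes
#'   `window_min`, `duration_s`.
#' @export
moving_rate <- function(times_green, times_orange, duration_s,
                        window_min = 2, step_s = 1) {
  if (window_min <= 0 || step_s <= 0 || duration_s <= 0) {
    stop("duration, window and step must be positive")
  }
  win_s <- window_min * 60
  if (win_s > duration_s) {
    warning("rate window longer than the scan; using one whole-scan window")
    centers <- duration_s / 2
    win_s <- duration_s
  } else {
    centers <- seq(0, duration_s, by = step_s)
  }
  half <- win_s / 2
  lo <- pmax(centers - half, 0)
  hi <- pmin(centers + half, duration_s)
  count_in <- function(times) {
    if (length(times) == 0) return(numeric(length(centers)))
    if (any(times < 0 | times > duration_s)) {
      stop("detection times outside [0, duration]")
    }
    ts <- sort(times)
    findInterval(hi, ts) - findInterval(lo, ts, left.open = TRUE)
  }
  mins <- (hi - lo) / 60
  out <- data.frame(
    time_s = centers,
    rate_green = count_in(times_green) / mins,
    rate_orange = count_in(times_orange) / mins
  )
  attr(out, "window_min") <- window_min
  attr(out, "duration_s") <- duration_s
  class(out) <- c("difc_rates", "data.frame")
  out
}

#' Pearson correlation of paired detection-rate series
#'
#' Correlates the green and orange moving rates of one scan. Because
#' overlapping windows stepped much faster than their length are serially
#' correlated, the two-sided p-value uses an effective sample size of
#' `duration / window` (the number of non-overlapping windows) rather than
#' the raw number of window centers.
#'
#' @param rates a `difc_rates` table from [moving_rate()].
#' @return list with `pcc`, `p_value` and `n_eff`. `pcc` is `NA` (with `NA`
#'   p-value) when either series has zero variance.
#' @export
correlate_rates <- function(rates) {
  g <- rates$rate_green
  o <- rates$rate_orange
  if (length(g) < 3) stop("need at least 3 rate samples")
  n_eff <- attr(rates, "duration_s") / (attr(rates, "window_min") * 60)
  if (sd(g) == 0 || sd(o) == 0) {
    return(list(pcc = NA_real_, p_value = NA_real_, n_eff = n_eff))
  }
  pcc <- cor(g, o)
  p <- NA_real_
  if (n_eff > 2 && abs(pcc) < 1) {
    tstat <- pcc * sqrt((n_eff - 2) / (1 - pcc^2))
    p <- 2 * pt(-abs(tstat), df = n_eff - 2)
  } else if (abs(pcc) == 1) {
    p <- 0
  }
  list(pcc = pcc, p_value = p, n_eff = n_eff)
}

#' Scan inclusion filter
#'
#' Scans are retained for rate-correlation analysis only when the overall
#' detection rate reaches the threshold (default at least 0.5 detections per
#' minute); sparser scans carry too little information about rate
#' fluctuation.
#'
#' @param rate_per_min overall detection rate (both colors), per minute.
#' @param threshold_per_min inclusion threshold (default 0.5).
#' @return TRUE iff `rate_per_min >= threshold_per_min`.
#' @export
include_scan <- function(rate_per_min, threshold_per_min = 0.5) {
  rate_per_min >= threshold_per_min
}

#' Peripheral-blood concentration from a detection rate
#'
#' Converts a detection rate into an apparent concentration by dividing by
#' the blood flow sampled under the probes (default 0.1 mL/min, the order of
#' flow carried by the large tail vessels DiFC targets). The estimate assumes
#' every cell passing through the sampled vessel is detected; in tissue it is
#' therefore a lower bound on the true concentration.
#'
#' @param rate_per_min detection rate, per minute.
#' @param sampled_flow_mL_per_min blood (or phantom) flow sampled, mL/min.
#' @return estimated concentration, cells/mL, with the detection-efficiency
#'   assumption recorded in the `"assumption"` attribute.
#' @export
estimate_concentration <- function(rate_per_min,
                                   sampled_flow_mL_per_min = 0.1) {
  if (sampled_flow_mL_per_min <= 0) stop("sampled flow must be positive")
  conc <- rate_per_min / sampled_flow_mL_per_min
  attr(conc, "assumption") <-
    "complete detection of cells within the sampled vessel"
  conc
}

#' Summarize a scan's detection records
#'
#' Computes per-classification counts, per-color detection rates and
#' concentration estimates, the cluster fraction, the moving-rate Pearson
#' correlation, and the inclusion flag.
#'
#' @param records detection-record table ([build_detection_records()]).
#' @param duration_s scan duration, seconds.
#' @param window_min moving-rate window, minutes.
#' @param include_threshold inclusion threshold, detections/min.
#' @param sampled_flow_mL_per_min sampled flow for concentration estimates.
#' @param step_s moving-rate step, seconds.
#' @return list of class `difc_summary`.
#' @export
summarize_scan <- function(records, duration_s, window_min = 2,
                           include_threshold = 0.5,
                           sampled_flow_mL_per_min = 0.1, step_s = 1) {
  counted <- records[records$classification != "indeterminate", ,
                     drop = FALSE]
  dur_min <- duration_s / 60
  counts <- table(factor(records$classification,
                         levels = .difc_classifications))
  tg <- counted$time_s[counted$n_green > 0 | counted$color == "green"]
  to <- counted$time_s[counted$n_orange > 0 | counted$color == "orange"]
  rate_green <- length(tg) / dur_min
  rate_orange <- length(to) / dur_min
  total_rate <- nrow(counted) / dur_min
  n_cluster <- sum(counted$classification %in%
                     c("cluster_1FP", "cluster_2FP"))
  rates <- moving_rate(tg, to, duration_s, window_min = window_min,
                       step_s = step_s)
  pcc <- correlate_rates(rates)
  structure(list(
    counts = counts,
    rate_per_min = c(green = rate_green, orange = rate_orange,
                     total = total_rate),
    concentration_per_mL = c(
      green = as.numeric(estimate_concentration(rate_green,
                                                sampled_flow_mL_per_min)),
      orange = as.numeric(estimate_concentration(rate_orange,
                                                 sampled_flow_mL_per_min))
    ),
    cluster_fraction = if (nrow(counted) > 0) n_cluster / nrow(counted)
                       else NA_real_,
    pcc = pcc$pcc,
    p_value = pcc$p_value,
    included = include_scan(total_rate, include_threshold),
    rates = rates,
    duration_s = duration_s
  ), class = "difc_summary")
}

#' @export
print.difc_summary <- function(x, ...) {
  cat("difc scan summary\n")
  cat(sprintf("  duration: %.1f min\n", x$duration_s / 60))
  cat("  counts:", paste(names(x$counts), as.integer(x$counts), sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  rates/min: green %.2f, orange %.2f, total %.2f\n",
              x$rate_per_min["green"], x$rate_per_min["orange"],
              x$rate_per_min["total"]))
  cat(sprintf("  est. concentration (cells/mL): green %.0f, orange %.0f\n",
              x$concentration_per_mL["green"],
              x$concentration_per_mL["orange"]))
  cat(sprintf("  cluster fraction: %.3f\n", x$cluster_fraction))
  cat(sprintf("  PCC: %.3f (p = %.3g, n_eff = %.1f)\n", x$pcc, x$p_value,
              attr(x$rates, "duration_s") /
                (attr(x$rates, "window_min") * 60)))
  cat(sprintf("  included (rate >= threshold): %s\n", x$included))
  invisible(x)
}
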