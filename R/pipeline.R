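#' Run the full two-color DiFC processing pipeline on a scan
#'
#' Per-channel background subtraction, noise estimation and 5-sigma peak
#' candidate detection; artifact removal and cross-probe directional
#' matching; 2-lambda coincidence pairing; bleed-threshold 1FP/2FP
#' classification; saturation flagging; amplitude-based cluster sizing; and
#' scan-level summary statistics.
#'
#' @param scan a `difc_scan`.
#' @param calib_green,calib_orange `bleed_calibration` objects (from
#'   [estimate_bleed_ratio()] or [calibrate_bleed_run()]).
#' @param ref_green,ref_orange per-cell reference amplitudes, mV.
#' @param bg_window,noise_window,k detection settings (see [detect_peaks()]).
#' @param params matching settings ([match_params()]).
#' @param coincidence_window 2-lambda pairing window, seconds (NULL = auto).
#' @param saturation_limit PMT saturation limit, mV.
#' @param window_min,include_threshold,sampled_flow_mL_per_min summary
#'   settings ([summarize_scan()]).
#' @param mask_peaks passed to [estimate_noise()].
#' @return list with `candidates`, `matched`, `unmatched`, `artifact_ids`,
#'   `two_lambda`, `singletons`, `records`, `summary`.
#' @export
difc_pipeline <- function(scan, calib_green, calib_orange,
                          ref_green, ref_orange,
                          bg_window = 5, noise_window = 60, k = 5,
                          params = match_params(),
                          coincidence_window = NULL,
                          saturation_limit = 1500,
                          window_min = 2, include_threshold = 0.5,
                          sampled_flow_mL_per_min = 0.1,
                          mask_peaks = FALSE) {
  candidates <- detect_peaks(scan, bg_window = bg_window,
                             noise_window = noise_window, k = k,
                             mask_peaks = mask_peaks)
  m <- match_detections(candidates,
                        probe_separation = scan$probe_separation,
                        params = params)
  tl <- find_two_lambda(m$matched, coincidence_window = coincidence_window)
  two_lambda <- classify_two_lambda(tl$two_lambda, calib_green, calib_orange,
                                    saturation_limit = saturation_limit)
  records <- build_detection_records(tl$singletons, two_lambda,
                                     ref_green = ref_green,
                                     ref_orange = ref_orange,
                                     calib_green = calib_green,
                                     calib_orange = calib_orange,
                                     saturation_limit = saturation_limit)
  summary <- summarize_scan(records, scan_duration(scan),
                            window_min = window_min,
                            include_threshold = include_threshold,
                            sampled_flow_mL_per_min = sampled_flow_mL_per_min)
  list(candidates = candidates, matched = m$matched,
       unmatched = m$unmatched, artifact_ids = m$artifact_ids,
       two_lambda = two_lambda, singletons = tl$singletons,
       records = records, summary = summary)
}

#' Calibrate the bleed ratio from a single-fluorophore scan
#'
#' Runs detection, matching and 2-lambda pairing on a scan known to contain
#' only one fluorophore, takes the coincident peaks whose primary color is
#' that fluorophore (excluding saturated ones, whose relative intensities are
#' unreliable), and feeds their primary/secondary amplitudes to
#' [estimate_bleed_ratio()].
#'
#' @param scan a `difc_scan` from a single-fluorophore run.
#' @param fluorophore "green" or "orange" - which fluorophore the run
#'   carried.
#' @param saturation_limit PMT saturation limit, mV.
#' @param bg_window,noise_window,k,params,coincidence_window
#'   detection/matching settings, as in [difc_pipeline()].
#' @param mask_peaks noise estimation with peak masking (default TRUE here:
#'   calibration runs use concentrated suspensions whose frequent bright
#'   pulses would otherwise inflate the noise estimate and starve the
#'   secondary channel of candidates).
#' @return a `bleed_calibration`.
#' @export
calibrate_bleed_run <- function(scan, fluorophore = c("green", "orange"),
                                saturation_limit = 1500,
                                bg_window = 5, noise_window = 60, k = 5,
                                params = match_params(),
                                coincidence_window = NULL,
                                mask_peaks = TRUE) {
  fluorophore <- match.arg(fluorophore)
  candidates <- detect_peaks(scan, bg_window = bg_window,
                             noise_window = noise_window, k = k,
                             mask_peaks = mask_peaks)
  m <- match_detections(candidates,
                        probe_separation = scan$probe_separation,
                        params = params)
  tl <- find_two_lambda(m$matched, coincidence_window = coincidence_window)
  pts <- tl$two_lambda
  pts <- pts[pts$primary_color == fluorophore &
               !flag_saturation(pts$amplitude_mV_max, saturation_limit), ,
             drop = FALSE]
  if (nrow(pts) == 0) {
    stop("no usable 2-lambda calibration points in this run; ",
         "need brighter cells or clusters")
  }
  estimate_bleed_ratio(pts$I_pr, pts$I_sec, fluorophore = fluorophore)
}
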