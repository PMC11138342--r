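#' Largest secondary amplitude attributable to spectral bleed
#'
#' A bright single-fluorophore (1FP) cell or cluster leaks some emission into
#' the other color's detection band, producing a coincident two-channel
#' ("2-lambda") peak. Given the primary peak amplitude `I_pr` (in local-noise
#' sigma units, so the detection floor is the constant 5) and the bleed ratio
#' `TR`, the largest secondary amplitude consistent with pure bleed is
#'
#'   max(I_sec) = I_pr * (TR * I_pr + 5) / (I_pr - 5)
#'
#' The threshold is deliberately conservative: it diverges as `I_pr`
#' approaches the 5-sigma detection floor (a dim primary peak tells little
#' about its bleed), and its ratio to `I_pr` tends to `TR` for very bright
#' peaks.
#'
#' @param I_pr primary peak amplitude in noise-sigma units; must exceed 5.
#' @param TR bleed ratio (dimensionless, >= 0) of the primary color's
#'   fluorophore.
#' @return maximum bleed-attributable secondary amplitude (sigma units).
#' @export
bleed_max_secondary <- function(I_pr, TR) {
  if (any(TR < 0)) stop("TR must be non-negative")
  if (any(I_pr <= 5)) {
    stop("I_pr must exceed the 5-sigma detection floor; classification at ",
         "or below it is indeterminate")
  }
  I_pr * (TR * I_pr + 5) / (I_pr - 5)
}

#' Calibrate the bleed ratio TR from single-fluorophore detections
#'
#' Calibration points are coincident two-channel peaks measured on
#' suspensions known to carry a single fluorophore (e.g. GFP-only phantom
#' runs), so every secondary peak is pure bleed plus noise. Each point gives
#'
#'   TR_i = (I_sec* * (I_pr* - 5) - 5 * I_pr*) / I_pr*^2
#'
#' (the inverse of [bleed_max_secondary()]), and TR is the largest TR_i,
#' clamped at 0. The max rule makes TR the smallest value for which zero
#' calibration points classify as two-fluorophore: a worst-case allowance for
#' the coincidence of signal noise and peak detection.
#'
#' @param I_pr primary (own-color) peak amplitudes, noise-sigma units.
#' @param I_sec secondary (opposite-channel) peak amplitudes, sigma units.
#' @param fluorophore which fluorophore the run carried ("green" or
#'   "orange").
#' @return object of class `bleed_calibration`: list with `fluorophore`,
#'   `TR`, `points` (data.frame of retained I_pr/I_sec/TR_i) and `n`.
#'   Points with `I_pr <= 5` are dropped with a warning.
#' @export
estimate_bleed_ratio <- function(I_pr, I_sec,
                                 fluorophore = c("green", "orange")) {
  fluorophore <- match.arg(fluorophore)
  if (length(I_pr) != length(I_sec)) stop("I_pr and I_sec lengths differ")
  ok <- I_pr > 5
  if (!all(ok)) {
    warning(sum(!ok), " calibration point(s) with I_pr <= 5 sigma rejected")
    I_pr <- I_pr[ok]
    I_sec <- I_sec[ok]
  }
  if (length(I_pr) == 0) {
    stop("no usable calibration points (all I_pr <= 5)")
  }
  tr_i <- (I_sec * (I_pr - 5) - 5 * I_pr) / I_pr^2
  structure(
    list(
      fluorophore = fluorophore,
      TR = max(0, max(tr_i)),
      points = data.frame(I_pr = I_pr, I_sec = I_sec, TR_i = tr_i),
      n = length(I_pr)
    ),
    class = "bleed_calibration"
  )
}

#' @export
print.bleed_calibration <- function(x, ...) {
  cat(sprintf("bleed_calibration: %s, TR = %.4g (%d points)\n",
              x$fluorophore, x$TR, x$n))
  invisible(x)
}

#' Pair coincident green and orange detections into 2-lambda peaks
#'
#' A multicellular cluster carrying both fluorophores - or a bright 1FP event
#' with spectral bleed - produces simultaneous peaks in the green and orange
#' channels of the same probes. Green and orange matched detections whose
#' peak times agree within the coincidence window on both probes are paired;
#' each detection joins at most one pair (closest pairs first). The larger
#' of the two coincident amplitudes is the primary peak.
#'
#' @param matched matched-detection table from [match_detections()] (both
#'   colors).
#' @param coincidence_window pairing window in seconds. Default: half the
#'   mean matched peak width, floored at 5 ms.
#' @return list with `two_lambda` (data.frame: `time_s`, `I_pr`, `I_sec`
#'   (sigma units), `primary_color`, `amp_pri_mV`, `amp_sec_mV`,
#'   `amplitude_mV_max`, `direction`, `speed_mm_s`, `width_s`) and
#'   `singletons` (matched rows without a partner).
#' @export
find_two_lambda <- function(matched, coincidence_window = NULL) {
  g <- matched[matched$color == "green", , drop = FALSE]
  o <- matched[matched$color == "orange", , drop = FALSE]
  if (is.null(coincidence_window)) {
    coincidence_window <- max(0.005, 0.5 * mean(matched$width_s))
    if (!is.finite(coincidence_window)) coincidence_window <- 0.005
  }
  empty <- data.frame(
    time_s = numeric(0), I_pr = numeric(0), I_sec = numeric(0),
    primary_color = character(0), amp_pri_mV = numeric(0),
    amp_sec_mV = numeric(0), amplitude_mV_max = numeric(0),
    direction = character(0), speed_mm_s = numeric(0), width_s = numeric(0)
  )
  if (nrow(g) == 0 || nrow(o) == 0) {
    return(list(two_lambda = empty, singletons = matched))
  }
  cand <- list()
  for (i in seq_len(nrow(g))) {
    d1 <- abs(g$time_p1[i] - o$time_p1)
    d2 <- abs(g$time_p2[i] - o$time_p2)
    j <- which(d1 <= coincidence_window & d2 <= coincidence_window)
    if (length(j) > 0) {
      cand[[length(cand) + 1L]] <- data.frame(i = i, j = j,
                                              d = d1[j] + d2[j])
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(two_lambda = empty, singletons = matched))
  }
  cand <- cand[order(cand$d), , drop = FALSE]
  used_g <- logical(nrow(g))
  used_o <- logical(nrow(o))
  take <- integer(0)
  for (r in seq_len(nrow(cand))) {
    if (!used_g[cand$i[r]] && !used_o[cand$j[r]]) {
      used_g[cand$i[r]] <- TRUE
      used_o[cand$j[r]] <- TRUE
      take <- c(take, r)
    }
  }
  sel <- cand[take, , drop = FALSE]
  gi <- sel$i; oj <- sel$j
  g_amp <- g$amplitude_sigma[gi]
  o_amp <- o$amplitude_sigma[oj]
  g_primary <- g_amp >= o_amp
  two_lambda <- data.frame(
    time_s = (g$time_s[gi] + o$time_s[oj]) / 2,
    I_pr = pmax(g_amp, o_amp),
    I_sec = pmin(g_amp, o_amp),
    primary_color = ifelse(g_primary, "green", "orange"),
    amp_pri_mV = ifelse(g_primary, g$amplitude_mV[gi], o$amplitude_mV[oj]),
    amp_sec_mV = ifelse(g_primary, o$amplitude_mV[oj], g$amplitude_mV[gi]),
    amplitude_mV_max = pmax(g$amplitude_mV_max[gi], o$amplitude_mV_max[oj]),
    direction = ifelse(g_primary, g$direction[gi], o$direction[oj]),
    speed_mm_s = ifelse(g_primary, g$speed_mm_s[gi], o$speed_mm_s[oj]),
    width_s = ifelse(g_primary, g$width_s[gi], o$width_s[oj])
  )
  ord <- order(two_lambda$time_s)
  two_lambda <- two_lambda[ord, , drop = FALSE]
  rownames(two_lambda) <- NULL
  singletons <- rbind(g[!used_g, , drop = FALSE], o[!used_o, , drop = FALSE])
  singletons <- singletons[order(singletons$time_s), , drop = FALSE]
  rownames(singletons) <- NULL
  list(two_lambda = two_lambda, singletons = singletons,
       coincidence_window = coincidence_window)
}

#' Flag detections that saturated a PMT
#'
#' Amplitudes above the PMT saturation limit (default 1500 mV) clip, so the
#' relative green/orange peak intensities are unreliable; such detections are
#' excluded from 1FP/2FP classification and cluster statistics. The limit is
#' exclusive: exactly 1500 mV is not flagged.
#'
#' @param amplitude_mV raw (pre-normalization) peak amplitude(s) in mV;
#'   for a multi-peak detection pass the maximum constituent amplitude.
#' @param limit saturation limit in mV (default 1500).
#' @return logical vector, TRUE where saturated.
#' @export
flag_saturation <- function(amplitude_mV, limit = 1500) {
  amplitude_mV > limit
}

#' Classify 2-lambda peaks as one- or two-fluorophore
#'
#' Each coincident peak is tested against the bleed threshold of the primary
#' color's calibration: if the measured secondary amplitude exceeds
#' [bleed_max_secondary()] at the primary amplitude, more secondary light was
#' seen than bleed can explain and the detection is a two-fluorophore (2FP)
#' cluster; otherwise it is a 1FP detection attributed to the primary color.
#' Saturated peaks and peaks with `I_pr <= 5` are `indeterminate`.
#'
#' @param two_lambda 2-lambda table from [find_two_lambda()].
#' @param calib_green,calib_orange `bleed_calibration` objects for GFP and
#'   tdTomato.
#' @param saturation_limit PMT saturation limit, mV (default 1500).
#' @return `two_lambda` with added columns `saturated` (logical) and
#'   `classification` ("oneFP", "twoFP" or "indeterminate").
#' @export
classify_two_lambda <- function(two_lambda, calib_green, calib_orange,
                                saturation_limit = 1500) {
  stopifnot(inherits(calib_green, "bleed_calibration"),
            inherits(calib_orange, "bleed_calibration"))
  n <- nrow(two_lambda)
  two_lambda$saturated <- flag_saturation(two_lambda$amplitude_mV_max,
                                          saturation_limit)
  cls <- character(n)
  for (r in seq_len(n)) {
    if (two_lambda$saturated[r] || two_lambda$I_pr[r] <= 5) {
      cls[r] <- "indeterminate"
      next
    }
    TR <- if (two_lambda$primary_color[r] == "green") {
      calib_green$TR
    } else {
      calib_orange$TR
    }
    thr <- bleed_max_secondary(two_lambda$I_pr[r], TR)
    # relative tolerance so the calibration point that set TR (for which
    # I_sec equals the threshold in exact arithmetic) never flips to 2FP
    # through floating-point round-off
    cls[r] <- if (two_lambda$I_sec[r] > thr * (1 + 1e-9)) "twoFP" else "oneFP"
  }
  two_lambda$classification <- cls
  two_lambda
}

#' Per-cell reference amplitude from single-cell calibration detections
#'
#' The median matched-peak amplitude of known single-cell runs, used as the
#' mV-per-cell scale for amplitude-based cluster sizing.
#'
#' @param amplitudes_mV matched single-cell detection amplitudes (mV).
#' @return scalar reference amplitude (mV per cell).
#' @export
reference_amplitude <- function(amplitudes_mV) {
  if (length(amplitudes_mV) == 0) stop("no calibration detections")
  median(amplitudes_mV)
}

#' Assemble final detection records with cluster sizing
#'
#' Combines single-color matched detections and classified 2-lambda peaks
#' into the pipeline's final record table. Cell counts are estimated from
#' peak amplitudes: `n = round(amplitude / ref)`, floored at 1 for any
#' detected color. Following the cluster definitions used for enumeration,
#' a 1FP detection is a cluster only when its amplitude is consistent with
#' three or more nuclei (excluding a single cell in mitosis), while every
#' 2FP detection is a cluster, since it must contain at least one cell of
#' each fluorophore. For 2FP detections the secondary amplitude is
#' bleed-corrected (`amp_sec - TR * amp_pri`) before sizing so bleed does not
#' inflate the minority-color count. Saturated/indeterminate peaks are kept,
#' flagged, with NA counts.
#'
#' @param singletons single-color matched detections ([find_two_lambda()]
#'   `singletons`).
#' @param two_lambda classified 2-lambda table ([classify_two_lambda()]).
#' @param ref_green,ref_orange per-cell reference amplitudes, mV (> 0).
#' @param calib_green,calib_orange `bleed_calibration` objects (for the
#'   bleed correction of 2FP sizing).
#' @param saturation_limit PMT saturation limit, mV.
#' @return detection-record data.frame (columns of [read_detections()]).
#' @export
build_detection_records <- function(singletons, two_lambda,
                                    ref_green, ref_orange,
                                    calib_green, calib_orange,
                                    saturation_limit = 1500) {
  if (ref_green <= 0 || ref_orange <= 0) {
    stop("reference amplitudes must be positive")
  }
  recs <- list()
  if (nrow(singletons) > 0) {
    ref <- ifelse(singletons$color == "green", ref_green, ref_orange)
    n_cells <- pmax(1, round(singletons$amplitude_mV / ref))
    sat <- flag_saturation(singletons$amplitude_mV_max, saturation_limit)
    recs$single <- data.frame(
      time_s = singletons$time_s,
      color = singletons$color,
      direction = singletons$direction,
      amplitude_mV = singletons$amplitude_mV,
      amplitude_sigma = singletons$amplitude_sigma,
      width_s = singletons$width_s,
      classification = ifelse(sat, "indeterminate",
                              ifelse(n_cells >= 3, "cluster_1FP",
                                     "single_1FP")),
      n_green = ifelse(sat, NA_real_,
                       ifelse(singletons$color == "green", n_cells, 0)),
      n_orange = ifelse(sat, NA_real_,
                        ifelse(singletons$color == "orange", n_cells, 0)),
      flags = ifelse(sat, "saturated", "")
    )
  }
  if (nrow(two_lambda) > 0) {
    tl <- two_lambda
    n <- nrow(tl)
    n_green <- rep(NA_real_, n)
    n_orange <- rep(NA_real_, n)
    classification <- character(n)
    for (r in seq_len(n)) {
      if (tl$classification[r] == "indeterminate") {
        classification[r] <- "indeterminate"
        next
      }
      pri_green <- tl$primary_color[r] == "green"
      ref_pri <- if (pri_green) ref_green else ref_orange
      ref_sec <- if (pri_green) ref_orange else ref_green
      TR <- if (pri_green) calib_green$TR else calib_orange$TR
      if (tl$classification[r] == "oneFP") {
        # all light attributed to the primary fluorophore
        n_pri <- max(1, round(tl$amp_pri_mV[r] / ref_pri))
        n_green[r] <- if (pri_green) n_pri else 0
        n_orange[r] <- if (pri_green) 0 else n_pri
        classification[r] <- if (n_pri >= 3) "cluster_1FP" else "single_1FP"
      } else {
        n_pri <- max(1, round(tl$amp_pri_mV[r] / ref_pri))
        sec_corr <- max(0, tl$amp_sec_mV[r] - TR * tl$amp_pri_mV[r])
        n_sec <- max(1, round(sec_corr / ref_sec))
        n_green[r] <- if (pri_green) n_pri else n_sec
        n_orange[r] <- if (pri_green) n_sec else n_pri
        classification[r] <- "cluster_2FP"
      }
    }
    recs$two_lambda <- data.frame(
      time_s = tl$time_s,
      color = tl$primary_color,
      direction = tl$direction,
      amplitude_mV = tl$amp_pri_mV,
      amplitude_sigma = tl$I_pr,
      width_s = tl$width_s,
      classification = classification,
      n_green = n_green,
      n_orange = n_orange,
      flags = ifelse(tl$saturated, "saturated", "")
    )
  }
  if (length(recs) == 0) {
    return(data.frame(
      time_s = numeric(0), color = character(0), direction = character(0),
      amplitude_mV = numeric(0), amplitude_sigma = numeric(0),
      width_s = numeric(0), classification = character(0),
      n_green = numeric(0), n_orange = numeric(0), flags = character(0)
    ))
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
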