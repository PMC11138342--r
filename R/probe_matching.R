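#' Matching parameters for cross-probe peak pairing
#'
#' A true cell transit produces similar peaks on both probes with a time
#' delay set by the flow speed and the probe separation. Candidate pairs are
#' accepted when the implied speed lies in a physiological band and the
#' amplitude and width ratios between probes stay within tolerance.
#'
#' @param speed_min,speed_max admissible flow speed band, mm/s. With the
#'   default 3 mm probe separation the defaults (5-150 mm/s) give an
#'   inter-probe delay window of 0.02-0.6 s.
#' @param amp_tol maximum cross-probe amplitude ratio (factor; default 2).
#' @param width_tol maximum cross-probe width ratio (factor; default 2).
#' @param artifact_window all-channel coincidence window (s) used by
#'   [flag_motion_artifacts()]; must be shorter than the minimum inter-probe
#'   delay so genuine transits are never self-flagged.
#' @return named list of parameters.
#' @export
match_params <- function(speed_min = 5, speed_max = 150, amp_tol = 2,
                         width_tol = 2, artifact_window = 0.010) {
  if (speed_min <= 0 || speed_max <= speed_min) {
    stop("need 0 < speed_min < speed_max")
  }
  if (amp_tol < 1 || width_tol < 1) stop("ratio tolerances must be >= 1")
  list(speed_min = speed_min, speed_max = speed_max, amp_tol = amp_tol,
       width_tol = width_tol, artifact_window = artifact_window)
}

#' Flag simultaneous peaks on all four channels
#'
#' Peaks that co-occur on all four channels within a short window cannot be a
#' directed cell transit (which reaches probe 2 only after the inter-probe
#' delay) and are treated as motion/instrument artifacts and removed before
#' matching.
#'
#' @param candidates candidate table from [detect_peaks()] (needs `id`,
#'   `channel`, `time_s`).
#' @param coincidence_window coincidence window in seconds (default 10 ms).
#' @return integer vector of flagged candidate `id`s.
#' @export
flag_motion_artifacts <- function(candidates, coincidence_window = 0.010) {
  if (nrow(candidates) == 0) return(integer(0))
  chans <- difc_channels()$channel
  times <- lapply(chans, function(ch) {
    sort(candidates$time_s[candidates$channel == ch])
  })
  names(times) <- chans
  flagged <- logical(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    t0 <- candidates$time_s[r]
    own <- candidates$channel[r]
    ok <- TRUE
    for (ch in setdiff(chans, own)) {
      tt <- times[[ch]]
      if (length(tt) == 0) { ok <- FALSE; break }
      idx <- findInterval(t0, tt)
      d <- Inf
      if (idx >= 1) d <- min(d, abs(t0 - tt[idx]))
      if (idx < length(tt)) d <- min(d, abs(tt[idx + 1] - t0))
      if (d > coincidence_window) { ok <- FALSE; break }
    }
    flagged[r] <- ok
  }
  candidates$id[flagged]
}

#' Match peak candidates across the two probes (one color)
#'
#' Pairs probe-1 and probe-2 candidates of the same color into directional
#' detections. A pair is feasible when the absolute delay falls inside the
#' window implied by the speed band, and the cross-probe amplitude and width
#' ratios are within tolerance. Feasible pairs are scored by
#' `|log2 amplitude ratio| + |log2 width ratio| + |delay - median delay| /
#' delay window` and assigned greedily in ascending score, each candidate
#' used at most once; ties break on earlier probe-1 time. Positive delay
#' (probe 1 then probe 2) is the forward (arterial) direction, negative is
#' reverse (venous). Unmatched candidates are returned separately and are
#' excluded from downstream counting.
#'
#' @param candidates_p1,candidates_p2 candidate tables for probe 1 and
#'   probe 2 of one color (rows of the [detect_peaks()] output).
#' @param probe_separation probe separation in mm (default 3).
#' @param params a [match_params()] list.
#' @return list with `matched` (data.frame: `color`, `time_s` = probe-1 peak
#'   time, `time_p1`, `time_p2`, `delay_s`, `direction`, `speed_mm_s`,
#'   `amplitude_mV`, `amplitude_sigma`, `width_s` (cross-probe means),
#'   `amplitude_mV_max`, `match_score`) and `unmatched` (leftover candidate
#'   rows).
#' @export
match_across_probes <- function(candidates_p1, candidates_p2,
                                probe_separation = 3,
                                params = match_params()) {
  dmin <- probe_separation / params$speed_max
  dmax <- probe_separation / params$speed_min
  if (dmin >= dmax) stop("invalid delay window (min >= max)")
  n1 <- nrow(candidates_p1)
  n2 <- nrow(candidates_p2)
  matched_cols <- data.frame(
    color = character(0), time_s = numeric(0), time_p1 = numeric(0),
    time_p2 = numeric(0), delay_s = numeric(0), direction = character(0),
    speed_mm_s = numeric(0), amplitude_mV = numeric(0),
    amplitude_sigma = numeric(0), width_s = numeric(0),
    amplitude_mV_max = numeric(0), match_score = numeric(0)
  )
  if (n1 == 0 || n2 == 0) {
    return(list(matched = matched_cols,
                unmatched = rbind(candidates_p1, candidates_p2)))
  }
  p2_ord <- order(candidates_p2$time_s)
  c2 <- candidates_p2[p2_ord, , drop = FALSE]
  t2 <- c2$time_s
  pairs <- vector("list", n1)
  for (i in seq_len(n1)) {
    t1 <- candidates_p1$time_s[i]
    lo <- findInterval(t1 - dmax, t2) + 1L
    hi <- findInterval(t1 + dmax, t2)
    if (hi < lo) next
    j <- lo:hi
    dt <- t2[j] - t1
    feas <- abs(dt) >= dmin & abs(dt) <= dmax
    if (!any(feas)) next
    j <- j[feas]; dt <- dt[feas]
    ar <- candidates_p1$amplitude_mV[i] / c2$amplitude_mV[j]
    wr <- candidates_p1$width_s[i] / c2$width_s[j]
    feas2 <- ar <= params$amp_tol & ar >= 1 / params$amp_tol &
      wr <= params$width_tol & wr >= 1 / params$width_tol
    if (!any(feas2)) next
    pairs[[i]] <- data.frame(i = i, j = j[feas2], delay = dt[feas2],
                             lar = abs(log2(ar[feas2])),
                             lwr = abs(log2(wr[feas2])))
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(matched = matched_cols,
                unmatched = rbind(candidates_p1, candidates_p2)))
  }
  med_delay <- median(abs(pairs$delay))
  pairs$score <- pairs$lar + pairs$lwr +
    abs(abs(pairs$delay) - med_delay) / (dmax - dmin)
  ord <- order(pairs$score, candidates_p1$time_s[pairs$i])
  used1 <- logical(n1)
  used2 <- logical(nrow(c2))
  take <- integer(0)
  for (r in ord) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE
      used2[j] <- TRUE
      take <- c(take, r)
    }
  }
  sel <- pairs[take, , drop = FALSE]
  i <- sel$i; j <- sel$j
  matched <- data.frame(
    color = candidates_p1$color[i],
    time_s = candidates_p1$time_s[i],
    time_p1 = candidates_p1$time_s[i],
    time_p2 = c2$time_s[j],
    delay_s = sel$delay,
    direction = ifelse(sel$delay > 0, "forward", "reverse"),
    speed_mm_s = probe_separation / abs(sel$delay),
    amplitude_mV = (candidates_p1$amplitude_mV[i] + c2$amplitude_mV[j]) / 2,
    amplitude_sigma = (candidates_p1$amplitude_sigma[i] +
                         c2$amplitude_sigma[j]) / 2,
    width_s = (candidates_p1$width_s[i] + c2$width_s[j]) / 2,
    amplitude_mV_max = pmax(candidates_p1$amplitude_mV[i],
                            c2$amplitude_mV[j]),
    match_score = sel$score
  )
  matched <- matched[order(matched$time_s), , drop = FALSE]
  rownames(matched) <- NULL
  unmatched <- rbind(candidates_p1[!used1, , drop = FALSE],
                     c2[!used2, , drop = FALSE])
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched = unmatched)
}

#' Full matching stage: artifacts out, then per-color cross-probe matching
#'
#' Removes all-channel simultaneous peaks ([flag_motion_artifacts()]), then
#' runs [match_across_probes()] separately for the green and orange detector
#' pairs, as matching is color-specific.
#'
#' @param candidates candidate table from [detect_peaks()].
#' @param probe_separation probe separation in mm.
#' @param params a [match_params()] list.
#' @return list with `matched` (both colors, time-ordered), `unmatched`
#'   candidate rows, and `artifact_ids` (flagged candidate ids).
#' @export
match_detections <- function(candidates, probe_separation = 3,
                             params = match_params()) {
  art <- flag_motion_artifacts(candidates, params$artifact_window)
  cand <- candidates[!(candidates$id %in% art), , drop = FALSE]
  out_m <- list()
  out_u <- list()
  for (col in .difc_colors) {
    res <- match_across_probes(
      cand[cand$color == col & cand$probe == 1L, , drop = FALSE],
      cand[cand$color == col & cand$probe == 2L, , drop = FALSE],
      probe_separation = probe_separation, params = params
    )
    out_m[[col]] <- res$matched
    out_u[[col]] <- res$unmatched
  }
  matched <- do.call(rbind, out_m)
  matched <- matched[order(matched$time_s), , drop = FALSE]
  rownames(matched) <- NULL
  unmatched <- do.call(rbind, out_u)
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched = unmatched, artifact_ids = art)
}
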