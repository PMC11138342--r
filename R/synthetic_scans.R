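#' Simulator configuration
#'
#' Generative parameters for synthetic two-color DiFC scans with known ground
#' truth. Defaults describe the optical flow phantom: cell suspensions at
#' 1000 cells/mL per color driven at 25 uL/min through tubing at fixed speed,
#' kHz-class sampling, 3 mm probe separation, ~1 mm sensing length (so a
#' transit's FWHM is `sensing_length / speed`).
#'
#' @param sampling_rate samples/s (default 2000).
#' @param duration_s scan length, seconds.
#' @param probe_separation mm (default 3).
#' @param flow_uL_min volumetric flow past the probes, uL/min (default 25,
#'   the phantom pump rate). Event rate per population =
#'   `concentration * flow * duration`.
#' @param concentration named vector `c(green=, orange=)` of cells (or
#'   clusters) per mL for the two populations.
#' @param speed_mean,speed_sd transit speed distribution, mm/s (truncated
#'   normal, floor 0.5 mm/s). Phantom default 8 mm/s (25 uL/min through
#'   0.254 mm ID tubing).
#' @param sensing_length optical sensing length, mm (default 1).
#' @param cell_amp_median,cell_amp_gsd per-cell peak brightness: log-normal
#'   median (mV, named by color) and geometric SD. Heterogeneous fluorophore
#'   expression makes brightness multiplicative, including the occasional
#'   very bright cell that triggers visible bleed.
#' @param bleed_TR named vector of true spectral bleed ratios: fraction of a
#'   fluorophore's signal leaking into the other color's channel.
#' @param noise_sigma additive Gaussian channel noise SD, mV (scalar or named
#'   per channel).
#' @param background_mV,drift_amp_mV,drift_period_s baseline autofluorescence
#'   level and slow sinusoidal drift.
#' @param cluster_size_dist distribution of cells per arriving event: either
#'   `list(type = "single")` (all size 1), `list(type = "pois1", lambda =)`
#'   (1 + Poisson), or `list(type = "geom1", prob =)` (1 + geometric).
#' @param twoFP_mixing probability that a cluster of >= 2 cells is mixed
#'   (contains both fluorophores; composition binomial(size, 1/2)
#'   conditioned on >= 1 of each).
#' @param direction_forward probability an event flows probe 1 -> probe 2.
#' @param artifact_rate_per_min rate of motion artifacts (simultaneous
#'   pulses on all four channels).
#' @param saturation_limit PMT linearity limit, mV (default 1500): above it
#'   measured relative intensities are unreliable and detections are flagged
#'   for exclusion downstream.
#' @param pmt_rail_mV hard clipping level of the detector chain, mV (default
#'   3000). The rail sits above the linearity limit so that saturated peaks
#'   still register amplitudes above `saturation_limit` and can be caught by
#'   the "greater than 1500 mV" curation rule; clipping exactly at the
#'   linearity limit would make railed peaks measure just under it and evade
#'   the rule.
#' @param rate_modulation NULL for homogeneous Poisson arrivals, or
#'   `list(sd =, cor_time_s =, shared =)` for a log-Gaussian (AR(1) in 1 s
#'   steps) modulation of the arrival intensity with the given log-SD and
#'   correlation time; `shared` in \[0, 1\] is the fraction of modulation
#'   variance common to both populations (1 = blood-flow-like shared
#'   fluctuation, 0 = independent shedding).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 2000,
                       duration_s = 600,
                       probe_separation = 3,
                       flow_uL_min = 25,
                       concentration = c(green = 1000, orange = 1000),
                       speed_mean = 8,
                       speed_sd = 0.5,
                       sensing_length = 1,
                       cell_amp_median = c(green = 50, orange = 50),
                       cell_amp_gsd = 1.8,
                       bleed_TR = c(green = 0.05, orange = 0.08),
                       noise_sigma = 1,
                       background_mV = 20,
                       drift_amp_mV = 2,
                       drift_period_s = 60,
                       cluster_size_dist = list(type = "single"),
                       twoFP_mixing = 0,
                       direction_forward = 1,
                       artifact_rate_per_min = 0,
                       saturation_limit = 1500,
                       pmt_rail_mV = 3000,
                       rate_modulation = NULL) {
  chans <- difc_channels()$channel
  if (length(noise_sigma) == 1) {
    noise_sigma <- stats::setNames(rep(noise_sigma, 4), chans)
  }
  stopifnot(
    sampling_rate > 0, duration_s >= 0, probe_separation > 0,
    flow_uL_min >= 0, all(concentration >= 0), speed_mean > 0,
    sensing_length > 0, all(cell_amp_median > 0), cell_amp_gsd >= 1,
    all(bleed_TR >= 0), all(noise_sigma >= 0),
    twoFP_mixing >= 0, twoFP_mixing <= 1,
    direction_forward >= 0, direction_forward <= 1,
    artifact_rate_per_min >= 0, saturation_limit > 0,
    pmt_rail_mV >= saturation_limit
  )
  structure(as.list(environment()), class = "sim_config")
}

#' Preset simulator scenarios
#'
#' * `phantom_single`: multiple-myeloma-like single-cell suspensions,
#'   1000 cells/mL per color at 25 uL/min (expected arrival rate 25
#'   events/min per color), fixed tube speed, all forward; per-cell median
#'   brightness 26 mV over 1 mV noise (peak SNR around 28 dB). Bleed is
#'   usually sub-threshold, so coincident two-channel peaks come only from
#'   the bright tail of the brightness distribution.
#' * `phantom_cluster`: cultured breast-cancer-like cluster suspensions,
#'   10000 cells/mL organized in ~1000 clusters/mL per color (mean ~10
#'   cells/cluster, 1 + Poisson(9) sizes), brighter per cell (50 mV median,
#'   peak SNR around 34 dB); unmixed by default (single-fluorophore cluster
#'   runs; set `twoFP_mixing` for co-culture).
#' @param scenario one of `"phantom_single"`, `"phantom_cluster"`,
#'   `"invivo_mm"`.
#' @param ... overrides passed to [sim_config()] (e.g.
#'   `concentration = c(green = 1000, orange = 0)` for a single-fluorophore
#'   run).
#' @details
#' `invivo_mm`: two multiple-myeloma-like CTC populations in a mouse tail
#' vessel sampling ~100 uL/min, ~20 cells/mL each (detection rates of a few
#' per minute), mostly single cells with occasional clusters, both flow
#' directions, slowly fluctuating shedding intensity (log-SD 0.7,
#' ~5 min correlation, independent between populations by default) to
#' exercise the rate-correlation analysis, and rare motion artifacts.
#' @return a `sim_config`.
#' @export
preset_config <- function(scenario = c("phantom_single", "phantom_cluster",
                                       "invivo_mm"), ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    phantom_single = list(
      cell_amp_median = c(green = 26, orange = 26)
    ),
    phantom_cluster = list(
      concentration = c(green = 1000, orange = 1000),
      cluster_size_dist = list(type = "pois1", lambda = 9)
    ),
    invivo_mm = list(
      duration_s = 3600,
      flow_uL_min = 100,
      concentration = c(green = 20, orange = 20),
      cell_amp_median = c(green = 26, orange = 26),
      speed_mean = 30,
      speed_sd = 5,
      cluster_size_dist = list(type = "geom1", prob = 0.6),
      twoFP_mixing = 0.1,
      direction_forward = 0.8,
      artifact_rate_per_min = 0.1,
      rate_modulation = list(sd = 0.7, cor_time_s = 300, shared = 0)
    )
  )
  args <- utils::modifyList(base, list(...))
  cfg <- do.call(sim_config, args)
  cfg$scenario <- scenario
  cfg
}

.draw_cluster_sizes <- function(n, dist) {
  if (n == 0) return(integer(0))
  switch(dist$type,
    single = rep(1L, n),
    pois1 = 1L + rpois(n, dist$lambda),
    geom1 = 1L + rgeom(n, dist$prob),
    stop("unknown cluster size distribution: ", dist$type)
  )
}

# AR(1) log-Gaussian intensity modulation on a 1 s grid, mean-corrected so
# E[exp(g)] = 1 and the base rate is preserved in expectation.
.modulation <- function(n_bins, sd, cor_time_s) {
  a <- exp(-1 / cor_time_s)
  g <- numeric(n_bins)
  g[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n_bins - 1, 0, sd * sqrt(1 - a^2))
  for (t in seq_len(n_bins - 1)) g[t + 1] <- a * g[t] + innov[t]
  exp(g - sd^2 / 2)
}

.sample_population_times <- function(base_rate_per_s, duration_s, lam_mult) {
  if (base_rate_per_s <= 0 || duration_s <= 0) return(numeric(0))
  if (is.null(lam_mult)) {
    n <- rpois(1, base_rate_per_s * duration_s)
    return(sort(runif(n, 0, duration_s)))
  }
  # inhomogeneous Poisson via per-bin sampling on the 1 s modulation grid
  n_bins <- length(lam_mult)
  bin_w <- duration_s / n_bins
  counts <- rpois(n_bins, base_rate_per_s * bin_w * lam_mult)
  t0 <- (which(counts > 0) - 1) * bin_w
  times <- unlist(mapply(function(s, k) s + runif(k, 0, bin_w),
                         t0, counts[counts > 0], SIMPLIFY = FALSE))
  if (is.null(times)) return(numeric(0))
  sort(times)
}

#' Sample ground-truth events for a synthetic scan
#'
#' Event arrivals per population follow a (possibly intensity-modulated)
#' Poisson process with mean `concentration * flow * duration`. Each event
#' is a cell or cluster: its size is drawn from the configured cluster-size
#' distribution, mixed clusters draw a binomial green/orange composition,
#' per-cell brightnesses are log-normal, and direction and speed are drawn
#' per event. Motion artifacts are added as a separate Poisson stream.
#' Identical `(config, seed)` give identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return data.frame of events: `time_s` (arrival at probe 1), `population`
#'   ("green", "orange" or "artifact"), `n_green`, `n_orange` (cell counts),
#'   `amp_green_mV`, `amp_orange_mV` (summed per-color true pulse
#'   amplitudes, before bleed/noise), `direction`, `speed_mm_s`,
#'   `is_artifact`.
#' @export
sample_events <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    flow_mL_min <- config$flow_uL_min / 1000
    dur_min <- config$duration_s / 60
    mods <- list(green = NULL, orange = NULL)
    if (!is.null(config$rate_modulation) && config$duration_s >= 2) {
      rm <- config$rate_modulation
      n_bins <- max(2L, as.integer(ceiling(config$duration_s)))
      shared <- .modulation(n_bins, rm$sd, rm$cor_time_s)
      for (pop in .difc_colors) {
        own <- .modulation(n_bins, rm$sd, rm$cor_time_s)
        # variance-preserving mix of shared and independent log-modulation
        g_sh <- log(shared) + rm$sd^2 / 2
        g_own <- log(own) + rm$sd^2 / 2
        g <- sqrt(rm$shared) * g_sh + sqrt(1 - rm$shared) * g_own
        mods[[pop]] <- exp(g - rm$sd^2 / 2)
      }
    }
    ev <- list()
    for (pop in .difc_colors) {
      rate_per_s <- config$concentration[[pop]] * flow_mL_min / 60
      times <- .sample_population_times(rate_per_s, config$duration_s,
                                        mods[[pop]])
      n <- length(times)
      if (n == 0) next
      sizes <- .draw_cluster_sizes(n, config$cluster_size_dist)
      mixed <- sizes >= 2 & runif(n) < config$twoFP_mixing
      n_own <- sizes
      n_other <- integer(n)
      if (any(mixed)) {
        k <- rbinom(sum(mixed), sizes[mixed] - 2L, 0.5) + 1L
        n_own[mixed] <- k
        n_other[mixed] <- sizes[mixed] - k
      }
      n_green <- if (pop == "green") n_own else n_other
      n_orange <- if (pop == "orange") n_own else n_other
      amp_for <- function(counts, color) {
        vapply(counts, function(m) {
          if (m == 0) return(0)
          sum(rlnorm(m, meanlog = log(config$cell_amp_median[[color]]),
                     sdlog = log(config$cell_amp_gsd)))
        }, numeric(1))
      }
      ev[[pop]] <- data.frame(
        time_s = times,
        population = pop,
        n_green = n_green,
        n_orange = n_orange,
        amp_green_mV = amp_for(n_green, "green"),
        amp_orange_mV = amp_for(n_orange, "orange"),
        direction = ifelse(runif(n) < config$direction_forward,
                           "forward", "reverse"),
        speed_mm_s = pmax(0.5, rnorm(n, config$speed_mean, config$speed_sd)),
        is_artifact = FALSE
      )
    }
    n_art <- rpois(1, config$artifact_rate_per_min * dur_min)
    if (n_art > 0) {
      amp <- rlnorm(n_art, meanlog = log(100), sdlog = log(2))
      ev$artifact <- data.frame(
        time_s = sort(runif(n_art, 0, config$duration_s)),
        population = "artifact",
        n_green = 0L, n_orange = 0L,
        amp_green_mV = amp, amp_orange_mV = amp,
        direction = "forward",
        speed_mm_s = config$speed_mean,
        is_artifact = TRUE
      )
    }
    if (length(ev) == 0) {
      return(data.frame(
        time_s = numeric(0), population = character(0),
        n_green = integer(0), n_orange = integer(0),
        amp_green_mV = numeric(0), amp_orange_mV = numeric(0),
        direction = character(0), speed_mm_s = numeric(0),
        is_artifact = logical(0)
      ))
    }
    out <- do.call(rbind, ev)
    out <- out[order(out$time_s), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# add a Gaussian pulse (FWHM fwhm_s, height amp) centered at t0 into x,
# evaluated within +/- 5 SD of the center
.add_pulse <- function(x, t0, amp, fwhm_s, sampling_rate) {
  sd_t <- fwhm_s / (2 * sqrt(2 * log(2)))
  lo <- max(1L, as.integer(floor((t0 - 5 * sd_t) * sampling_rate)) + 1L)
  hi <- min(length(x), as.integer(ceiling((t0 + 5 * sd_t) * sampling_rate)) + 1L)
  if (hi < lo) return(x)
  idx <- lo:hi
  tt <- (idx - 1) / sampling_rate
  x[idx] <- x[idx] + amp * exp(-(tt - t0)^2 / (2 * sd_t^2))
  x
}

#' Render ground-truth events into a four-channel scan
#'
#' Each non-artifact event contributes, on both probes of every expressed
#' color, a Gaussian pulse with FWHM = `sensing_length / speed`; the probe-2
#' pulse is delayed by `probe_separation / speed` (forward) or advanced
#' (reverse). The green channel receives the event's summed green amplitude
#' plus `bleed_TR["orange"]` times its orange amplitude, and symmetrically
#' for the orange channel. Artifacts are rendered as simultaneous pulses on
#' all four channels. A drifting sinusoidal background and i.i.d. Gaussian
#' noise are added per channel, and the trace is clipped at the PMT
#' saturation limit. Events whose transit spans fewer than 2 samples are
#' skipped with a warning.
#'
#' @param events event table from [sample_events()].
#' @param config the same [sim_config()].
#' @param seed RNG seed for the noise (use a different seed from
#'   [sample_events()] if independence matters; [simulate_scan()] handles
#'   this).
#' @return a `difc_scan`.
#' @export
render_scan <- function(events, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$sampling_rate * config$duration_s)
  chans <- difc_channels()
  withr::with_seed(seed, {
    sig <- list()
    tvec <- (seq_len(n) - 1) / config$sampling_rate
    drift <- config$background_mV +
      config$drift_amp_mV * sin(2 * pi * tvec / config$drift_period_s)
    for (i in seq_len(nrow(chans))) {
      ch <- chans$channel[i]
      sig[[ch]] <- drift + rnorm(n, 0, config$noise_sigma[[ch]])
    }
    if (nrow(events) > 0) {
      fwhm <- config$sensing_length / events$speed_mm_s
      too_fast <- fwhm * config$sampling_rate < 2
      if (any(too_fast)) {
        warning(sum(too_fast),
                " event(s) faster than 2 samples per transit skipped")
      }
      TRg <- config$bleed_TR[["green"]]
      TRo <- config$bleed_TR[["orange"]]
      for (e in which(!too_fast)) {
        t1 <- events$time_s[e]
        if (events$is_artifact[e]) {
          for (ch in chans$channel) {
            sig[[ch]] <- .add_pulse(sig[[ch]], t1, events$amp_green_mV[e],
                                    fwhm[e], config$sampling_rate)
          }
          next
        }
        delay <- config$probe_separation / events$speed_mm_s[e]
        t2 <- if (events$direction[e] == "forward") t1 + delay else t1 - delay
        amp_g <- events$amp_green_mV[e] + TRo * events$amp_orange_mV[e]
        amp_o <- events$amp_orange_mV[e] + TRg * events$amp_green_mV[e]
        if (amp_g > 0) {
          sig$p1_green <- .add_pulse(sig$p1_green, t1, amp_g, fwhm[e],
                                     config$sampling_rate)
          sig$p2_green <- .add_pulse(sig$p2_green, t2, amp_g, fwhm[e],
                                     config$sampling_rate)
        }
        if (amp_o > 0) {
          sig$p1_orange <- .add_pulse(sig$p1_orange, t1, amp_o, fwhm[e],
                                      config$sampling_rate)
          sig$p2_orange <- .add_pulse(sig$p2_orange, t2, amp_o, fwhm[e],
                                      config$sampling_rate)
        }
      }
    }
    for (ch in chans$channel) {
      sig[[ch]] <- pmin(sig[[ch]], config$pmt_rail_mV)
    }
    difc_scan(
      as.data.frame(sig),
      sampling_rate = config$sampling_rate,
      probe_separation = config$probe_separation,
      metadata = list(scenario = if (!is.null(config$scenario))
        config$scenario else "custom", seed = seed)
    )
  })
}

#' Simulate a complete scan with ground truth
#'
#' Convenience wrapper: [sample_events()] with `seed`, then [render_scan()]
#' with a derived seed, returning both the scan and the true event list.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; determinism is per `(config, seed)`.
#' @return list with `scan` (a `difc_scan`) and `events` (ground truth).
#' @export
simulate_scan <- function(config, seed) {
  events <- sample_events(config, seed)
  scan <- render_scan(events, config, seed = (seed + 777L) %% .Machine$integer.max)
  list(scan = scan, events = events)
}
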