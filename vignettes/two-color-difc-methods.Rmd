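---
title: "Two-color DiFC signal processing: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-color DiFC signal processing: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difc)
```

## The measurement and its signal model

Diffuse in vivo flow cytometry (DiFC) counts fluorescently labeled cells
flowing through a large blood vessel by collecting diffusely scattered
laser-excited fluorescence through fiber probes resting on the skin. A
two-color instrument uses two probes, separated by a few millimeters along
the vessel, each feeding a green (GFP) and an orange (tdTomato) detection
band: four photomultiplier channels in total (P1-G, P1-O, P2-G, P2-O).

A cell transit appears as a transient, roughly unimodal peak riding on a
slowly varying autofluorescence background. The processing chain assumes:

* uniform sampling (time is sample index over `sampling_rate`);
* background variation much slower than a transit, so a moving-median over a
  window much longer than a peak removes it without attenuating peaks;
* locally stationary noise, so a moving standard deviation tracks the
  detection floor;
* a transit crosses both probes with delay `probe_separation / speed`,
  producing similar peaks on both probes of the expressed color(s).

## Pipeline stages and their tunable parameters

**Background subtraction** (`subtract_background`): moving median, window
5 s (default), centered, truncated at the trace edges. A 5 s window is two
orders of magnitude longer than a typical transit (tens of ms), so peak
height is preserved to within a percent.

**Noise estimation** (`estimate_noise`): moving standard deviation of the
background-subtracted trace, window 60 s, centered and truncated. By default
all samples enter the window. At high event rates (concentrated phantom
suspensions, tens of detections per minute) the pulses themselves inflate
this estimate several-fold and would starve detection; the `mask_peaks`
option computes a robust first-pass scale (1.4826 times the moving median
absolute deviation, consistent for Gaussian noise) and excludes samples
above 3 of those sigmas from the standard deviation. Residual inflation from
sub-threshold pulse flanks is bounded by that 3-sigma band and measured at
about 10% under a 50-events/min torture load. For traces shorter than the
full noise window the windowed robust scale degenerates to the global median
absolute deviation, which is then used directly.

**Candidate detection** (`find_candidates`, `detect_peaks`): a candidate is
a transient maximum at least `k = 5` local sigmas high — equivalently SNR at
least `20*log10(5) = 13.98 dB`. One candidate is emitted per contiguous
above-threshold region (the maximum; plateau midpoints when the top value
repeats), so noise ripple riding on a peak's flanks cannot spawn duplicates.
Regions closer than half the wider peak's FWHM are merged into the taller
one: one cell, one continuous transit peak. Width is FWHM by linear
interpolation between samples. The local sigma is floored at 1e-6 mV so
synthetic noiseless traces do not divide by zero.

**Cross-probe matching** (`match_across_probes`, `match_detections`):
candidates of one color are paired across probes when the implied speed lies
in 5-150 mm/s (delay 0.02-0.6 s at 3 mm separation) and cross-probe
amplitude and width ratios are within a factor of 2 — wide enough for
probe-to-probe sensitivity differences, tight enough to reject chance noise
coincidences. Feasible pairs are scored by
`|log2 amp ratio| + |log2 width ratio| + |delay - median feasible delay| /
delay window` and assigned greedily, each candidate at most once, ties to
the earlier probe-1 time. Positive delay is forward (arterial) flow.
Candidates co-occurring on **all four** channels within 10 ms (shorter than
any physical inter-probe delay) are motion/instrument artifacts and are
removed before matching; unmatched candidates are discarded from counting.

**Two-fluorophore classification** (`find_two_lambda`,
`estimate_bleed_ratio`, `classify_two_lambda`): green and orange matched
detections whose peak times agree on both probes within a coincidence window
(half the mean matched width, floored at 5 ms) form a 2-lambda peak; the
larger amplitude is the primary peak `I_pr`, the smaller the secondary
`I_sec`. With amplitudes in local-noise-sigma units — the reading under
which the constant 5 in the equations coincides with the 5-sigma detection
floor — the largest secondary amplitude attributable to spectral bleed is

$$\max(I_{sec}) = I_{pr}\,\frac{T_R I_{pr} + 5}{I_{pr} - 5},$$

and calibration points $(I^*_{pr}, I^*_{sec})$ from known single-fluorophore
runs each give

$$T_{R,i} = \frac{I^*_{sec}(I^*_{pr} - 5) - 5 I^*_{pr}}{(I^*_{pr})^2},$$

with $T_R = \max(0, \max_i T_{R,i})$. These two forms are exact mutual
inverses, which the classification logic requires: the max rule makes $T_R$
the smallest value for which zero calibration points classify as
two-fluorophore — a worst-case allowance for noise coinciding with peak
detection. The threshold diverges as $I_{pr} \to 5^+$ (classification is
maximally conservative near the detection floor; at or below it the peak is
`indeterminate`) and $\max(I_{sec})/I_{pr} \to T_R$ for bright peaks. A
relative tolerance of 1e-9 in the comparison keeps the argmax calibration
point — equal to its own threshold in exact arithmetic — from flipping to
2FP by round-off.

Because each per-point estimate expands as
$T_{R,i} \approx T_R^{true} - (5 + 5T_R^{true} - \varepsilon)/I_{pr}$
(with $\varepsilon$ the secondary-amplitude measurement noise in sigmas),
the max-rule estimate converges to the true spectral ratio from below as
calibration sets gain bright points, with worst-case deviation about
$(5 + 5T_R + 3)/\max(I_{pr})$. Calibration should therefore use the
brightest available unsaturated detections — cluster suspensions, in
practice.

**Saturation curation** (`flag_saturation`): detections whose raw amplitude
exceeds 1500 mV saturate a PMT and misreport relative intensities; they are
flagged and excluded from classification, calibration and cluster
statistics (the limit is exclusive: exactly 1500 mV passes). Automated
flags replace manual curation for reproducibility.

**Cluster sizing** (`build_detection_records`): cell counts are
`round(amplitude / per-cell reference)`, floored at 1 per detected color;
the reference is the median single-cell calibration amplitude
(`reference_amplitude`). A 1FP detection is a cluster only at 3+ nuclei
(excluding a single cell in mitosis); every 2FP detection is a cluster. For
2FP peaks the secondary amplitude is bleed-corrected
(`amp_sec - TR * amp_pri`) before sizing so bleed does not inflate the
minority-color count. With log-normal per-cell brightness, sizing by
amplitude unavoidably mislabels the bright tail of single cells (roughly
the mass above 2.5 times the median — about 6% at geometric SD 1.8) as
small clusters; this is a property of amplitude-based sizing itself, not of
the implementation.

**Scan analysis** (`moving_rate`, `correlate_rates`, `summarize_scan`):
detection rates per color in 2-min moving windows stepped every 1 s
(near-continuous), truncated and renormalized at scan edges. The Pearson
correlation between the two colors' rate series distinguishes shared
drivers (blood flow under anesthesia) from independent ones (shedding).
Overlapping windows are serially correlated, so the p-value uses
`n_eff = duration / window` degrees of freedom rather than the number of
window centers, which would overstate significance by orders of magnitude.
Scans below 0.5 detections/min overall are excluded from correlation
summaries. Concentration estimates divide rate by the sampled flow
(default 0.1 mL/min, the order carried by the large tail vessels DiFC
targets; 0.025 mL/min for the phantom pump) and assume complete detection —
in tissue they are lower bounds.

## The synthetic-scan generator

`sim_config()` / `preset_config()` / `simulate_scan()` generate four-channel
scans with known ground truth. Events arrive as a Poisson process with mean
`concentration x flow x duration`; each event is a cell or cluster with
log-normal per-cell brightness (multiplicative expression heterogeneity,
including the rare very bright cells that trigger visible bleed), linear
amplitude additivity within clusters (the assumption underlying
amplitude-based sizing), a Gaussian transit pulse of FWHM
`sensing_length / speed` on both probes with the direction-signed delay,
spectral bleed at the configured true ratios, a drifting sinusoidal
background, white Gaussian channel noise, and optional all-channel motion
artifacts. Traces clip at a PMT rail of 3000 mV, deliberately above the
1500 mV linearity limit: clipping exactly at the limit would make railed
peaks measure just under it and evade the "greater than 1500 mV" curation
rule that exists to catch them.

Presets encode the three study conditions. `phantom_single`: 1000 cells/mL
per color at 25 uL/min (25 events/min/color expected), tube speed 8 mm/s
(25 uL/min through 0.254 mm ID tubing), per-cell median 26 mV over 1 mV
noise — peak SNR near 28 dB, the multiple-myeloma phantom operating point.
`phantom_cluster`: 10^4 cells/mL organized as ~10^3 clusters/mL per color
(1 + Poisson(9) cells), 50 mV median per cell (SNR near 34 dB,
breast-cancer-like). `invivo_mm`: two populations at ~2 detections/min each
in a 100 uL/min vessel, 26 mV cells, mostly singles with geometric cluster
sizes (~16% at 3+ cells), 10% of multi-cell clusters mixed, 80% forward
flow, rare artifacts, and a log-Gaussian AR(1) modulation of the shedding
intensity (log-SD 0.7, 5 min correlation) whose `shared` fraction is the
knob that makes the rate-correlation analysis testable: `shared = 1` mimics
a common cardiovascular driver, `shared = 0` independent shedding. True
bleed ratios default to 0.05 (green) and 0.08 (orange), slightly below the
conservative calibrated thresholds a real instrument reports.

What the generator does **not** emulate: depth- and wavelength-dependent
optical sensitivity (amplitude distributions absorb those effects),
non-Gaussian or correlated detector noise, pulse-shape asymmetry from
non-uniform sensing profiles, probe-to-probe gain mismatch, and real motion
artifacts' spectral structure. Passing tests therefore demonstrate the
correctness of the algorithms under the stated signal model, not instrument
performance on animals.

## Numerical choices

* Rolling medians use the Turlach running-median algorithm for the interior
  and exact truncated-window recomputation at the edges (sorted-insertion,
  quadratic in the half-window, so user-facing windows recompute only the
  5 s background edges); rolling standard deviations use centered cumulative
  sums after global mean-centering, agreeing with direct two-pass
  computation to ~1e-12 relative.
* Windows are specified in seconds and converted with
  `half = floor(window * rate / 2)`, so results are sampling-rate-robust.
* Degenerate inputs: empty traces error; constant traces background-subtract
  to zero; noiseless traces are handled by the 1e-6 mV sigma floor;
  events too fast to span two samples are skipped with a warning.
* Determinism: all generators run under `withr::with_seed`; identical
  `(config, seed)` give byte-identical scans.
* Serialization writes 17 significant digits, round-tripping IEEE doubles
  exactly.

## Validation problem sizes

The shipped tests validate: rolling statistics against brute-force oracles
on 10^4-sample traces (exact); false-alarm suppression on 6 h of
noise-only 4-channel traces at 1 kHz (zero matched directional detections);
the calibration zero-false-positive property on simulated single-fluorophore
cluster runs (240 s at 2 kHz); phantom parameter recovery (rate,
concentration, speed, bleed ratio) on 600 s scans; end-to-end recovery of
at least 95% of isolated transits with amplitude at least 8 sigma —
isolated meaning no same-color event within 0.3 s, since co-transiting
same-color events merge into one peak for any threshold detector — and the
shared-vs-independent shedding contrast on 20 seeded event-level
simulations per arm. These sizes keep the full suite within tens of minutes
on one CPU while leaving Monte-Carlo margins wide relative to the asserted
tolerances.

## Known limitations

* The bleed threshold handles one fluorophore pair; no spectral unmixing or
  more than two colors.
* Coincident arrivals of different-color cells within one transit time are
  classified as 2FP by construction — the known failure mode of coincidence
  gating, growing with event rate (at 25+25 events/min about 1-2% of
  detections).
* Amplitude-based sizing inherits the brightness distribution's spread; per
  -cell counts are order-of-magnitude estimates, and the 3-nuclei cluster
  rule mislabels the bright single-cell tail.
* The concentration estimator assumes complete detection in the sampled
  vessel; in vivo it is a lower bound with an unknown efficiency factor.
* The matching stage resolves conflicts greedily; a globally optimal
  assignment could differ in dense scans.
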