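# difc

Signal processing for **two-color diffuse in vivo flow cytometry (DiFC)**.

DiFC counts rare fluorescent circulating tumor cells (CTCs) and CTC clusters
(CTCCs) non-invasively, by shining a 488 nm laser into a large blood vessel
(e.g. a mouse tail artery) through two fiber probes placed a few millimeters
apart and watching for transient fluorescence peaks as labeled cells transit
the sensing volume. A two-color instrument splits each probe's light into a
green (GFP) and an orange (tdTomato) detection band, producing four channels
(P1-G, P1-O, P2-G, P2-O), so two cell populations — or mixed two-fluorophore
clusters — can be monitored in the same animal.

This package implements the full processing chain from raw four-channel mV
traces to classified, sized detection records and scan-level statistics:

1. **Background subtraction** — moving 5 s median, removing the tissue
   autofluorescence baseline.
2. **Noise-adaptive detection** — moving 1 min standard deviation; peak
   candidates are transient maxima with amplitude at least 5 times the local
   noise, i.e. SNR at least 20·log10(5) = 13.9 dB.
3. **Cross-probe matching** — candidates must appear on both probes with a
   physiological time delay (forward/arterial or reverse/venous), similar
   amplitude and width; unmatched peaks and all-channel-simultaneous
   (motion-artifact) peaks are discarded. This yields direction and speed
   per detection and suppresses false alarms to essentially zero.
4. **Two-fluorophore classification** — coincident green+orange ("2λ")
   peaks on the same transit are either genuine two-fluorophore (2FP)
   clusters or bright single-fluorophore (1FP) events with spectral bleed.
   With amplitudes in local-noise-sigma units, the largest secondary
   amplitude attributable to bleed at primary amplitude `I_pr` is

       max(I_sec) = I_pr (TR·I_pr + 5) / (I_pr − 5)

   where the bleed ratio `TR` is calibrated from known single-fluorophore
   runs as the maximum over points of

       TR_i = [I_sec*(I_pr* − 5) − 5·I_pr*] / I_pr*²

   so that zero calibration detections classify as 2FP. A 2λ peak whose
   secondary amplitude exceeds the threshold is a 2FP cluster.
5. **Cluster sizing and curation** — cell counts from peak amplitude over a
   per-cell reference; 1FP detections sized at 3+ nuclei are clusters, every
   2FP detection is a cluster; detections above 1500 mV (PMT saturation) are
   flagged and excluded.
6. **Scan analysis** — 2-min moving detection rates per color, Pearson
   correlation between the two populations' rates (with overlap-corrected
   degrees of freedom), a ≥0.5 detections/min scan-inclusion filter, and
   flow-normalized peripheral-blood concentration estimates.

A **synthetic scan simulator** (`sim_config()`, `preset_config()`,
`simulate_scan()`) generates four-channel scans with known ground truth —
Poisson cell arrivals, log-normal per-cell brightness, configurable spectral
bleed, drifting background, noise, motion artifacts, and optionally
shared-vs-independent fluctuating shedding rates — so every stage is testable
without instrument data.

## Worked example

```r
library(difc)

# calibrate the bleed ratios on single-fluorophore cluster suspensions
cal_g <- calibrate_bleed_run(simulate_scan(
  preset_config("phantom_cluster", duration_s = 240,
                concentration = c(green = 1000, orange = 0)), 7)$scan, "green")
cal_o <- calibrate_bleed_run(simulate_scan(
  preset_config("phantom_cluster", duration_s = 240,
                concentration = c(green = 0, orange = 1000)), 8)$scan, "orange")
cal_g
#> bleed_calibration: green, TR = 0.04713 (87 points)
cal_o
#> bleed_calibration: orange, TR = 0.07746 (82 points)

# process a phantom scan: 1000 cells/mL per color at 25 uL/min
sim <- simulate_scan(preset_config("phantom_single", duration_s = 600), 42)
res <- difc_pipeline(sim$scan, cal_g, cal_o, ref_green = 26, ref_orange = 26,
                     sampled_flow_mL_per_min = 0.025, mask_peaks = TRUE)
res$summary
#> difc scan summary
#>   duration: 10.0 min
#>   counts: single_1FP=450, cluster_1FP=29, cluster_2FP=4, indeterminate=0
#>   rates/min: green 27.10, orange 21.60, total 48.30
#>   est. concentration (cells/mL): green 1084, orange 864
#>   cluster fraction: 0.068
#>   PCC: 0.269 (p = 0.661, n_eff = 5.0)
#>   included (rate >= threshold): TRUE
```

The detection rates (27.1 and 21.6 per minute) recover the realized Poisson
event rates of this simulation (27.1 and 21.9 per minute; nominal 25), and
dividing by the 0.025 mL/min phantom flow recovers the nominal 1000 cells/mL
suspension concentration. The calibrated bleed ratios sit just below the
simulator's true spectral bleed (0.05 green, 0.08 orange), as expected for
the conservative max-rule estimator, and the four 2FP records come from
coincident green+orange arrivals in the same sensing volume — the known
failure mode of coincidence classification at high event rates.

A thin command-line front end over the same functions is included at
`inst/cli/difc.R` with subcommands `simulate`, `detect`, `match`,
`calibrate-bleed`, `classify` and `analyze`.

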