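# neurovasc

Quantitative analysis of neurovascular dysfunction from three data
streams, packaged for reuse and validated end-to-end on synthetic data
with known ground truth:

* **Bolus tracking.** Two-photon line scans of a fluorescent dextran
  bolus are modeled per vessel with the gamma-variate curve
  `F(t) = b + A((t-t0)/(αβ))^α exp(α-(t-t0)/β)`; the time-to-peak
  (TTP, peak at `t0 + αβ`) is measured from the injection trigger, and
  cerebrovascular reactivity is the percent TTP shortening under
  hypercapnia, `100(TTP_normo − TTP_hyper)/TTP_normo`.
* **Network flow change.** Hypercapnic vs normocapnic TTPs across a
  microvascular network are fit with orthogonal (Deming, λ = 1)
  regression; a slope `s < 1` signals compressed transit-time
  dispersion and the flow change is `100(1/s − 1)` percent, with a
  hierarchical (animal, then vessel) bootstrap CI.
* **Theta–gamma coupling.** 20 kHz local field potentials are low-pass
  filtered at 500 Hz, decimated to 1 kHz, and scanned over a grid of
  four 1 Hz theta bins (4–8 Hz) × 27 4 Hz gamma bins (30–138 Hz). Each
  cell gets the Canolty modulation index
  `MI = |n⁻¹ Σ a_t e^{iφ_t}|`, a z-score against 50 circular-shift
  surrogates of the envelope, and a Bonferroni-corrected significance
  flag.
* **Morphometry.** Pixel-ratio measures on labeled masks: mural-cell
  coverage (desmin/lectin pixels), detachment (instances with no
  neighbour within a Chebyshev radius), plaque load (8-connected
  components ≥ 100 µm² as percent of ROI), and vascular amyloid load
  (percent of vessel surface).

Because the study's raw imaging and electrophysiology data are not
deposited, the package includes seeded generators
(`generate_bolus_cohort()`, `generate_pac_signal()`,
`generate_mask_scene()`) that emulate each data type with configurable
ground truth; the test suite recovers what the generators put in.

## Worked example

Simulate a 147-vessel control-like cohort whose true hypercapnic flow
increase is 74%, fit nothing by hand, and recover it:

```r
library(neurovasc)

cfg <- bolus_cohort_config(flow_change_true = 74, seed = 1)
co  <- generate_bolus_cohort(cfg, traces = FALSE)
network_flow_change(co$truth, n_boot = 2000, seed = 2)
#> Deming regression (lambda = 1, n = 147)
#>   slope = 0.575004, intercept = 1.02785e-16
#>   flow change = 73.9% [69.3, 78.3]
```

The slope 0.575 of hypercapnic on normocapnic TTP deviations means the
transit-time dispersion contracted by that factor, i.e. network flow
rose by `100(1/0.575 − 1) ≈ 73.9%`; the bracket is the 95% hierarchical
bootstrap interval, which covers the generative truth of 74%.

The full analysis chain lives in `analysis/` as numbered drivers
(simulate cohorts → fit traces → flow/reactivity inference → coupling →
morphometry), each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_fit_bolus.R
Rscript analysis/03_flow_inference.R
Rscript analysis/04_pac_comodulogram.R
Rscript analysis/05_morphometry.R
```

`03_flow_inference.R` prints, among other rows, the pooled flow change
of both simulated cohorts — in the committed run, 76.3% [73.3, 79.3]
for the cohort generated at a true 74% and −5.6% [−6.5, −4.7] at a true
−5.3% — plus the arteriolar reactivity-vs-amyloid regression for one
33-vessel cohort generated at slope −0.29 with R² ≈ 0.26 noise (a
single realization, so its estimate carries the corresponding SE; the
acceptance script averages 100 such cohorts).
`04_pac_comodulogram.R` reports where the control cohort's comodulogram
peaks (the theta bin containing 6 Hz × the gamma bin containing 80 Hz,
Bonferroni-significant) and the cohort contrast in electrode-level
mean z.

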