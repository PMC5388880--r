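---
title: "Models and methods behind neurovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurovasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neurovasc` implements the quantitative chain used to characterize
cerebrovascular and neuronal-network dysfunction in a rodent model of
amyloidosis: bolus-transit modeling of two-photon line scans, a
dispersion-based estimator of the network flow response to hypercapnia,
theta–gamma phase–amplitude coupling (PAC) analysis of cortical local
field potentials, and pixel-ratio morphometry of immunofluorescence
masks. Because the raw animal data are not public, the package ships
seeded generators that emulate each data type with fully known ground
truth; every estimator is validated by recovering what the generator put
in. This vignette explains the models, the defaults, and the design
choices that were genuinely open.

## Bolus transit and the gamma-variate model

A fluorescent dextran bolus injected at the start of a line scan passes
through each vessel as a skewed transient. The package models a trace as

$$F(t) = b + A\,\Big(\tfrac{t-t_0}{\alpha\beta}\Big)^{\alpha}
  \exp\!\Big(\alpha - \tfrac{t-t_0}{\beta}\Big), \qquad t > t_0,$$

the classic gamma-variate bolus curve, parameterized so `amplitude` $A$
is the peak height above baseline $b$ and the analytic peak — the
time-to-peak (TTP), measured from the injection trigger at $t = 0$ —
is $t_0 + \alpha\beta$. Fitting is bounded nonlinear least squares
(Levenberg–Marquardt, with an L-BFGS-B fallback on the raw sum of
squares). Initialization is data-driven: baseline from the pre-rise
median, onset where a 5-sample moving average first exceeds baseline
plus three pre-rise SDs, shape fixed at 2, scale from the smoothed peak
location. The smoothing is used only to pick starting values, never in
the fit itself. Bounds ($t_0 \in [0, t_{peak}]$, $\alpha \in (0.1, 20]$,
$\beta \in (0.01, T]$) exclude degenerate spikes. Flat traces — no rise
above baseline + 3 SD — return a non-converged result rather than an
error, mirroring vessels that cannot be analyzed. A recirculation
(second-pass) truncation at the first post-peak local minimum is
available but off by default; whether the original analysis needed one
is not knowable from a fit contract alone, and the simulated traces
contain a single passage.

Reactivity of a vessel is the percent TTP shortening under hypercapnia,
$100\,(TTP_{normo} - TTP_{hyper})/TTP_{normo}$; vessels under 10 µm
apparent diameter are classified capillaries (strict inequality at
10 µm).

## Dispersion-based flow inference

Hypercapnia raises cerebral blood flow; transit times shorten and — the
key observation — their *dispersion* contracts. Regressing hypercapnic
on normocapnic TTPs across a vascular network with orthogonal (Deming,
$\lambda = 1$) regression measures that contraction: a slope $s < 1$
means compressed dispersion, and the network flow change is
$100\,(1/s - 1)$ percent. The closed-form Deming estimator is

$$\hat s = \frac{s_{yy} - \lambda s_{xx} +
  \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}},$$

with $\lambda$ exposed but defaulting to 1 (errors of the same scale in
both capnia states, as both TTPs come from the same fitting pipeline).
Degenerate clouds ($s_{xy} = 0$) are an error, not an arbitrary axis.

Two design points deserve emphasis:

* **Centering.** The Deming slope is invariant to a common translation,
  so centering the scatter is cosmetic for a single vessel population.
  When several vessel types with different mean TTPs are pooled,
  however, the between-type mean structure scales with reactivity
  (roughly $1 - R/100 \approx 0.85$), not with the dispersion factor
  $1/k$; a pooled fit on globally centered data mixes the two and
  understates the flow change whenever type means differ. The default
  `center = "by_type"` removes each type's own mean first, so the pooled
  slope measures the within-network dispersion compression; per-type
  fits are identical under both settings, and `center = "global"`
  reproduces the plain pooled regression.
* **Uncertainty.** The original analysis used linear mixed models with
  animal as a random effect; here the confidence interval comes from a
  hierarchical case-resampling bootstrap (resample animals with
  replacement, then vessels within each sampled animal; percentile
  interval; 2000 draws by default), which respects between-animal
  variation with in-package computation only. With a single animal the
  bootstrap falls back to vessel resampling.

The arteriole-level relation between reactivity and vascular amyloid
load is ordinary least squares of reactivity (%) on load (% of vessel
surface), reporting slope, SE, $R^2$, and the two-sided $p$ for a zero
slope; animal clustering is deliberately not modeled there.

## The bolus cohort generator

For vessel $i$ of type $v$ (arteriole/capillary/venule):

$$TTP_{normo,i} = \mu_v + \delta_i, \qquad
  TTP_{hyper,i} = (1 - R_v/100)\,\mu_v + \delta_i/k + \varepsilon_i,
  \qquad k = 1 + F/100,$$

with $\delta_i$ a zero-mean between-vessel deviation (truncated at
±3 SD so that every realized curve fits the scan window with the
required $3\beta$ margin; the truncation shrinks the SD by about 1.3%,
well inside the 10% tolerance of the dispersion-convergence property)
and $\varepsilon_i$ a small TTP measurement noise (default 0.05 s,
matching the empirical TTP error of the fitting stage at 5% trace
noise). The Deming slope of the generated deviations is $1/k$ by
construction, so the flow estimator targets $F$ exactly. Traces are
rendered on a 50 Hz line grid over 13 s with onset at half the TTP,
shape 3, and additive white fluorescence noise (SD 5 a.u. against a
100 a.u. peak); line-scan noise is not characterized in the source
material, and white Gaussian is the simplest adequate model for
recovery testing. Defaults place arteriolar bolus arrival (3 s) before
venular (5 s), with capillaries between, and allocate vessels to 9
animals for the hierarchical bootstrap. Mean per-vessel reactivity
equals $R_v$ only up to a second-order term in $\delta$ whenever
$F \neq 0$ — the dispersion term $\delta_i/k$ shifts individual
ratios — which is why reactivity recovery is asserted at cohort-CI
rather than exact precision.

## Phase–amplitude coupling

Raw 20 kHz LFPs are low-pass filtered at 500 Hz (zero-phase windowed-
sinc FIR, unit DC gain) and decimated to 1 kHz. For a band, the
instantaneous phase/amplitude is the angle/modulus of the analytic
signal (FFT Hilbert) of the zero-phase band-passed trace; the first and
last filter-length samples are excluded from all coupling estimates.
Zero-phase filtering is one FFT pass with the symmetric kernel
$h * \mathrm{rev}(h)$, exactly equivalent to forward–backward
application.

The coupling statistic is the Canolty composite-vector modulation
index, $MI = |n^{-1}\sum_t a_t e^{i\phi_t}|$: 1-homogeneous in
amplitude, bounded by the mean envelope, and analytically $A_\gamma m/2$
for an envelope $A_\gamma(1 + m\cos\phi)$. The null is built from 50
circular time-shifts of the envelope (offsets uniform in
$[0.1n, 0.9n]$), which preserve its spectrum and autocorrelation; the
shifted MIs are computed for all offsets at once through the circular
cross-correlation theorem, exactly matching the per-shift computation.
Cells are scored as $z = (MI - \bar{MI}_{surr})/sd(MI_{surr})$.

**Significance.** With 50 surrogates the Bonferroni-corrected tail
($0.05/108 \approx 4.6\times10^{-4}$) cannot be resolved empirically,
so a parametric tail model supplies the threshold. The default
moment-matches a gamma distribution to the surrogate MIs: the null MI
is the modulus of a near-Gaussian resultant (Rayleigh-like,
right-skewed), and a Gaussian tail there is anti-conservative by
roughly a factor six at these quantiles, while the gamma tail is mildly
conservative — null calibration runs show a family-wise error well
under the nominal 5%. `correction = "normal"` retains the plain
Gaussian quantile.

**Band grid and filters.** The default grid is four 1 Hz theta bins
spanning 4–8 Hz and 27 contiguous 4 Hz gamma bins from 30 Hz (a 4 Hz
binning of 30–140 Hz leaves a 2 Hz remainder; 134–138 is the last full
bin, and edges are configurable). Phase-band filters are
transition-matched to the bin width: phase is amplitude-invariant, so a
1 Hz theta bin whose filter passes the neighbouring carrier at high
gain would simply phase-lock to it and every theta bin would report the
same coupling. Amplitude-band filters use the conventional three cycles
of the band's low edge; their wide skirts are what allows a 4 Hz gamma
bin to pass the modulation sidebands sitting $f_\theta$ away from the
carrier, without which no coupling would be measurable at all.

**Peak semantics.** The comodulogram's peak is the maximum of the raw
MI map, the quantity such maps display. The surrogate z-score cannot
localize: it is invariant to amplitude scaling, so every cell whose
filter passes any part of the modulated complex attains essentially the
same z, and the max-z cell degenerates to a coin toss among the bins
straddling carrier and sidebands. Raw MI weights cells by actual band
amplitude and pins the peak to the carrier bin; z remains the
significance statistic. `comodulogram_peak(statistic = "z")` exposes
the alternative.

## The LFP generator

$$x(t) = A_\theta \cos\phi_\theta(t) +
  A_\gamma\,[1 + m\cos(\phi_\theta(t) - \phi_c)]\cos\phi_\gamma(t) +
  \text{pink} + \text{white},$$

with $m \in [0,1]$ the ground-truth coupling depth and analytic clean
MI $A_\gamma m/2$. Two departures from a textbook two-tone signal make
the generator behave like electrophysiology rather than a bench
function generator, and both are essential for the surrogate machinery
to be testable at all:

* **Theta phase decoherence.** A strictly periodic carrier is invariant
  under circular shift — the surrogate MI then *equals* the observed MI
  and no coupling is ever detectable against its own null. Real theta
  wanders; the generator gives the theta instantaneous frequency an
  Ornstein–Uhlenbeck jitter (SD 0.3 Hz, correlation time 1 s), which
  decoheres the phase over seconds while keeping it inside its 1 Hz
  bin. Setting `freq_jitter_sd = 0` restores the strictly periodic
  carrier (useful for analytic checks).
* **Gamma band spread.** A spectral-line gamma places its modulation
  sidebands exactly at the edges of the neighbouring 4 Hz analysis
  bins, making peak localization an artifact of filter roll-off. Real
  gamma is band-spread; an OU jitter on the gamma frequency (SD 1.5 Hz,
  correlation time 0.3 s) gives the carrier a few-Hz linewidth centred
  in its bin.

Pink noise is white noise shaped to a $1/f$ power spectrum (DC bin
zeroed, exponent configurable) — the conventional meaning of $1/f$
noise — plus white measurement noise. Defaults: $A_\theta = 1$,
$A_\gamma = 0.5$, pink SD 0.5, white SD 0.2, 120 s at 20 kHz (the
generators used in tests run at 1 kHz directly, which is spectrally
identical below 500 Hz and avoids pointless decimation work).

What the generator does *not* emulate: burst-like gamma packets,
non-sinusoidal theta waveform asymmetry (a known source of spurious
PAC), cross-regional coupling, volume conduction, and electrode
artifacts. Passing tests therefore show that the estimator chain is
correct and calibrated on its stated model, not that it is robust to
every pathology of real recordings.

## Morphometry

All measures are plain pixel ratios on labeled masks, computed exactly:
coverage (signal-positive over reference-positive pixels), detachment
(pixels of instances with no other instance within a Chebyshev radius,
default 1 = 8-connected touch, over all instance pixels), flagged-class
pixel fraction (the morphological classification itself is an input),
plaque load (8-connected components inside an ROI, components under
100 µm² removed, surviving pixels as a percent of ROI area), and
vascular amyloid load (amyloid surface over vessel surface, scalar 3-D
surface areas as inputs). Connected components come from an in-package
raster-scan union-find labeler, cross-checked against an independent
flood-fill oracle. Background thresholding selects the smallest
intensity threshold whose suprathreshold background density does not
exceed the target (7–10 pixels per 150 µm² in the source protocol,
read as a ceiling; the target is a parameter, not a midpoint
assumption). The mask generator constructs scenes with exact pixel
counts (±1 pixel rounding at the coverage and detachment targets), so
the round-trip tests are exact rather than statistical.

## Problem sizes and tolerances used in validation

Validation runs use: 125-point noiseless parameter grids for TTP
recovery (tolerance: one 20 ms line period); 50 replicate cohorts of
147 (or 117) vessels for flow recovery (mean within 5 percentage
points, bootstrap CI coverage ≥ 90% at 400 draws); 100 replicates of 33
arterioles for the amyloid regression; 40 seeded 120 s recordings for
coupling localization; 100 uncoupled 60 s recordings for family-wise
error calibration (the 60 s window halves the cost of a pure-noise run
and the FWER of the threshold rule does not depend on window length);
and 1000 random 64×64 masks for the labeling oracle. These sizes were
chosen to give stable Monte-Carlo estimates at desk scale; all are
parameters of the test and script code, not of the package.

## Known limitations

* The reported MI units of the source study (tens, on some toolbox
  scale) are not reproducible from a contract that leaves the
  normalization unstated; the package reports raw MI (a.u.) and
  surrogate z and labels them explicitly.
* Mixed-effects inference (animal random effects) is replaced by the
  hierarchical bootstrap; p-values for group contrasts are therefore
  not reproduced, only estimates with CIs.
* The gamma-variate fit assumes a single bolus passage; strongly
  recirculating traces need the optional truncation.
* Detachment is defined purely geometrically (Chebyshev contact);
  biological contact through out-of-plane processes is invisible to a
  2-D mask.
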