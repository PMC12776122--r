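---
title: "Time-resolved aperiodic slope dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved aperiodic slope dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aperiodics)
```

## The model

Broadband EEG power falls with frequency approximately as a power law,
$P(f) \propto f^{-x}$, equivalently $\log P(f) = b - x \log f$. The
aperiodic exponent $x$ (the negative of the log-log regression slope) is
interpreted as an index of the excitation-inhibition balance of the
underlying circuits: steeper spectra (larger $x$, more negative slope) are
read as relatively stronger inhibition. `aperiodics` estimates this slope at
every time point of stimulus-locked epochs and asks how it is modulated by
the current trial's congruency and by the preceding trial's congruency (the
congruency effect, CE, and congruency sequence effect, CSE, of conflict
tasks).

The estimator follows a deliberately temporal-resolution-first design:
epochs are convolved with *single-cycle* cosine/sine wavelet pairs at a
sparse grid of 2.5, 5, 7.5, 15 and 25 Hz, quadrature outputs are combined
into instantaneous power, and a per-timepoint ordinary least-squares fit of
$\log_{10}$ power on $\log_{10}$ frequency yields slope and intercept. The
7.5 and 15 Hz grid points are excluded from the fit so that theta/alpha/beta
oscillatory peaks do not bias the aperiodic estimate. Slopes are smoothed
with a 5-point moving average and epochs with implausible values are
censored before condition averaging, PCA reduction and windowed statistics.

## Assumptions and what single-cycle kernels can and cannot do

A one-cycle kernel at frequency $f$ lasts $1/f$ seconds, so its bandwidth is
proportional to $f$ (constant-Q analysis). Two consequences matter and are
easy to miss:

* **Density normalization.** Raw quadrature power of a $1/f^x$ background
  scales as $f\cdot f^{-x}$: the widening passband injects extra power at
  high frequencies, and a log-log fit on raw power recovers $-(x-1)$, not
  $-x$. `waveletPower(..., normalize = "density")` (the default) divides
  each frequency's power by twice the kernel frequency — the exact
  equivalent-noise-bandwidth correction for these kernels — putting the fit
  on a spectral-density scale that recovers $-x$. The correction is itself a
  power law, so it shifts every slope by exactly $+1$ and every intercept by
  a constant; `normalize = "amplitude"` restores the raw scale in which a
  unit-amplitude matched sinusoid yields power 1.
* **Broadband leakage above ~10 Hz.** The 25 Hz kernel is 20 samples long at
  512 Hz; its spectral main lobe spans roughly 0–50 Hz, and its amplitude
  response at 10 Hz is 0.985. A 10 Hz oscillation therefore leaks almost
  fully into the 25 Hz power estimate no matter which grid points are
  fit-masked. At the generator's default oscillation amplitude (4 µV against
  a 10 µV broadband background) the induced slope bias is below 0.1 for
  $x = 1$ and grows with $x$ (less genuine high-frequency power to dilute
  the leak): about 0.11 at $x = 1.5$ and 0.37 at $x = 2$. The same
  mechanism biases recovery of very steep backgrounds ($x = 3$) upward by
  roughly 0.2, because low-frequency power leaks *into* the 25 Hz estimate.
  These are properties of the printed kernel design, not of the
  implementation; the test suite asserts them at face value and documents
  where they fail.

## Censoring scale

Plausibility censoring excludes epochs whose smoothed slope exceeds ±4
anywhere. That bound is conventionally stated on the raw-power slope scale,
where typical task-EEG values sit around −0.5 and ±4 is a generous outlier
fence. On the density-normalized scale every slope is exactly 1 lower, and
applying ±4 there would sit inside the bulk of the per-sample estimate
distribution — under this package's own default simulation it censors
essentially every epoch (56 channels × 1024 samples of
chi-square-distributed instantaneous log-power give per-epoch maxima of
4.2–5.5). `smoothAndCensor()` therefore tests `|slope + 1| > bound` for
density-normalized series and `|slope| > bound` for amplitude-normalized
ones; a `SlopeSeries` carries its normalization tag. Under the default
generator this retains roughly 60–75% of epochs, with strong dependence on
the participant's baseline exponent — mirroring the wide retention ranges
such censoring produces in practice.

## The synthetic study

The generator is the package's test bench; its defaults are the simulated
study's conditions, chosen once:

* **Design**: 49 participants, two blocks, four Previous × Current
  congruency cells balanced exactly (an Eulerian-circuit construction gives
  every block `4m + 1` trials with exactly `m` of each transition), RSI
  labels drawn from {1000, 2000, 3000, 5000} ms with no signal attached.
* **Recording**: 56 channels on an 8 × 7 scalp grid at 512 Hz, 2000-ms
  epochs spanning −500…1500 ms.
* **Background**: five independent $1/f^x$ sources with Gaussian scalp maps
  — frontal, central, occipital at 10 µV, left/right-temporal at half
  amplitude. Three equal strong sources alone make the PCA variance filter
  degenerate (see below); the five-source topography also matches the
  five-region component structure such data exhibit. Baseline exponent 1.5,
  participant offsets SD 0.1.
* **Programmed dynamics**: +0.25 exponent everywhere from 100–1300 ms
  (stimulus-induced steepening) and +0.3 on the frontal source from
  400–1300 ms for incongruent trials preceded by congruent ones — a pure
  CSE-patterned effect whose size was chosen to land the windowed ANOVA
  partial $\eta^2$ in the 0.08–0.2 range at $n = 49$.
* **Oscillation and ERP**: 10 Hz occipital oscillation (4 µV, random phase
  per trial); phase-locked condition ERPs (early occipital transient plus a
  central positivity, 4/5 µV for congruent/incongruent); 2 µV white sensor
  noise.
* **Behavior**: RT cell means (630, 662, 648, 654 ms) that reproduce
  congruent/incongruent marginals of ~642/656 ms with a congruency cost
  only after congruent trials; within-participant RT SD 150 ms, participant
  offsets SD 100 ms; per-cell error probabilities of 2.4–3.8%.

Time-varying exponents are realized by overlap-adding 500-ms stationary
frequency-domain-shaped segments under a 50%-overlap Hann crossfade;
stationary signals are generated in one shot with exact $f^{-x/2}$
amplitude shaping and random phases.

What the generator does **not** emulate: ocular and movement artifacts,
electrode drift, line noise, cross-frequency amplitude co-modulation,
non-Gaussian amplitude statistics, or volume-conduction mixing beyond fixed
Gaussian maps. Passing recovery tests therefore demonstrate correctness of
the pipeline's computations under the stated spectral model, not robustness
to everything real EEG contains.

## Reduction choices

* **PCA matrix**: components are extracted from the covariance matrix of
  the condition-averaged slope maps (electrodes or decimated timepoints as
  variables), because the regression score formula
  (data × covariance⁻¹ × unstandardized loadings) is covariance-based;
  eigenvalues are rescaled to correlation metric (sum = number of
  variables) only for the Empirical Kaiser Criterion test.
* **EKC**: the serial reference-value rule
  $l^{ref}_j = \max\{(1+\sqrt{p/n})^2 (p-\sum_{i<j}\lambda_i)/(p-j+1),\,1\}$,
  retaining while $\lambda_j > l^{ref}_j$.
* **1/x variance filter**: after varimax, any component explaining less
  than $1/x$ of the variance is dropped, with $x$ the number of
  EKC-extracted components. The share is computed **within the extracted
  variance**, not total variance: varimax redistributes the extracted
  variance nearly evenly, so with a noise floor present the total-variance
  reading excludes *every* component whenever the extracted subspace holds
  less than 100% of the variance — a degenerate outcome observed directly at
  desk-scale simulations. On the extracted shares the filter reproduces the
  intended behavior (weak lateral components dropped, three regional
  components kept).
* **Temporal PCA** decimates the cropped slope series by 10 (to ~51 Hz), so
  a 160-ms window holds 8–9 points; cases are
  participant × condition × electrode rows, symmetric to the spatial PCA.
* **Windows**: the −300…1300 ms crop (wavelet edge effects excluded) is
  segmented into 160-ms windows anchored at 0 ms — `[−160,0]`, `(0,160]`,
  …, `(1120,1280]`; the pre-stimulus window is closed on both ends,
  post-stimulus windows are lower-exclusive. No baseline correction is
  applied anywhere.
* **Signs and names**: each component's sign is fixed so its
  largest-magnitude loading is positive; spatial components are named by
  the scalp region of their peak loading.

## Statistics

All 2 × 2 within-subject ANOVAs are computed exactly as squared paired
t-statistics on the within-participant contrasts ($F(1, n-1) = t^2$), with
$\eta_p^2 = F/(F + df_{err})$ and Huynh–Feldt $\varepsilon = 1$ recorded
(two-level factors satisfy sphericity trivially; the general
$\varepsilon$ machinery in `hfEpsilon()` is exercised for $k > 2$). Paired
follow-ups report $d = \bar d / SD(d)$. Raw p-values are reported with no
multiple-testing correction by default (a Benjamini–Hochberg option
exists), and follow-up simple effects are gated on interaction $p < .05$.
Zero-variance degenerate inputs return $t = 0, p = 1$ (identical pairs) or
infinite statistics with $p = 0$ (constant nonzero differences).

## Numerical choices

* Power is floored at $10^{-12}$ µV² before $\log_{10}$ (guards exact-zero
  inputs; a pathological all-floor sample fits slope 0).
* Convolution uses FFTs padded to the next 5-smooth length with kernels
  circularly pre-shifted for centred alignment; epoch edges are
  zero-padded, and the first/last 200 ms are excluded from all analyses by
  the crop.
* The moving average uses shrinking windows at epoch edges.
* The compiled fused path (wavelet → fit → smooth → censor in one pass) is
  asserted in the test suite to agree with the composed R-level functions to
  ~1e-13.
* FWHM uses linear interpolation to the half-maximum crossings nearest the
  peak; a side that never crosses is truncated at the crop edge and
  flagged.

## Problem sizes used in the tests

The test suite runs the study design at reduced trial counts so the whole
suite completes on one CPU in minutes: end-to-end CE/CSE recovery uses 49
participants × 1 block × 6 trials/cell over 20 seeds; slope-recovery checks
use 100 single-channel epochs per exponent; PCA recovery uses 320-case
five-source maps over 50 seeds; null calibration uses 10,000 draws at
n = 12. The acceptance script reruns the behavioral analysis at the full
960-trial design and the EEG pipeline at the reduced trial count.

## Known limitations

* The 25 Hz single-cycle kernel is effectively broadband; oscillations
  anywhere below ~35 Hz bias the high-frequency power estimate, and the
  advertised immunity of the fit to alpha holds only for modest oscillation
  amplitudes and shallow backgrounds (quantified above).
* Slope recovery carries an upward bias of ~0.2 at $x = 3$ for the same
  reason; results for typical EEG exponents (1–2) are accurate to a few
  hundredths.
* The censored-regression refinement of the slope fit referenced in the
  surrounding literature is approximated by plain least squares with a
  power floor.
* Condition cells left empty by censoring yield missing scores; affected
  participants are dropped from the windowed ANOVAs with a warning.
* No reader for real epoched EEG formats is bundled; epochs enter as
  in-memory arrays via `eegEpochs()`.
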