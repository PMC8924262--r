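---
title: "Quantifying PIEZO2 mechanotransduction assays with piezoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PIEZO2 mechanotransduction assays with piezoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezoquant)
```

PIEZO2 is a mechanically activated cation channel studied with two
complementary electrophysiological assays and live-cell imaging. piezoquant
implements the quantification stack for all three, together with seeded
synthetic-data generators that emulate the recordings, so that every analysis
stage can be validated against known ground truth without laboratory data.
This vignette explains the models behind each stage, the parameters that
matter, and the numerical choices the package makes.

## Whole-cell poking currents

In the poking (membrane indentation) assay a blunt glass probe indents a
voltage-clamped cell in a series of ramp-and-hold displacement steps — by
default 13 steps in 0.4 µm increments at 1 µm/ms, sampled at 200 kHz and
low-pass filtered at 2.9 kHz, holding at −60 mV. Analysis proceeds per sweep:

- **Leak subtraction** (`subtract_leak()`): the mean of the baseline window
  (the pre-stimulus segment minus its first 5 ms, a settling allowance the
  acquisition literature leaves implicit) is subtracted so the baseline mean
  is exactly zero.
- **Peak current** (`peak_current()`): the signed extremum of largest
  magnitude between stimulus onset and 5 ms past stimulus end; the search is
  bounded to avoid off-stimulus artifacts.
- **Onset and mechanical threshold** (`detect_onset()`): the onset is the
  first sample after stimulus onset at which the current crosses
  `baseline_mean − 6 × baseline_SD` (inward convention; the side flips for
  outward currents at positive potentials, a symmetric treatment the
  recording convention leaves unstated). The threshold displacement is
  latency × probe velocity, clamped at the ramp amplitude when the crossing
  falls in the hold phase. Because the onset crossing sits low on the filter's
  rising edge, the latency is corrected by the filter's *dead time* — the
  time its step response takes to reach 5% of its final value — rather than
  the 50% group delay, which would over-correct. On noiseless synthetic
  sweeps threshold recovery is accurate to one sample equivalent plus this
  delay allowance. A noiseless baseline has zero SD; `min_sd` provides an
  explicit floor for that degenerate case, and the default errors instead of
  silently detecting everything.
- **Inactivation** (`fit_inactivation()`): least-squares fit of
  `C1 + C2·exp(−(t − t0)/τ)` on the decay, with `t0` fixed at the peak time.
  Fixing `t0` makes `C1` and `C2` identifiable; the fit is seeded by a
  log-linear regression restricted to the early decay (the tail is dominated
  by filter ripple once the exponential has died away). Flat windows raise a
  "no decay component" error rather than returning a meaningless τ.
- **Displacement–response, velocity sensitivity, reversal potential**:
  `displacement_response()` collects peak magnitudes per step and flags
  sweeps whose peak stays within 6 baseline SDs; `velocity_ratio()` computes
  `I(test velocity)/I(reference velocity)` from mean amplitudes and excludes
  cells whose last three reference responses have a coefficient of variation
  above 0.2; `reversal_potential()` interpolates the zero crossing of the
  I/V relation linearly between the sign-change pair, falling back to a
  flagged least-squares extrapolation when no sign change exists.

The synthetic poking generator uses a Boltzmann displacement–response
`B(A) = 1/(1 + exp(−(A − A½)/k))` (defaults A½ = 4.2 µm, k = 0.5 µm) gated at
a threshold displacement (default 2.8 µm), a Hill velocity scaling normalized
to 1 at 1 µm/ms (defaults give a 0.25 : 1 µm/ms amplitude ratio of 0.40,
i.e. currents ~60% smaller at the slow velocity), a saturating peak of
−1200 pA, mono-exponential inactivation (default τ = 6 ms), constant leak and
Gaussian noise. These functional forms are smooth, saturating stand-ins with
the qualitative shape of measured displacement–response and velocity curves;
the assays themselves do not constrain the functional form, only its
monotonicity and saturation.

## Cell-attached pressure clamp

Membrane stretch is applied as 3-s negative-pressure steps (−20 to −80 mmHg)
through the patch pipette at −100 mV, 50 kHz sampling. Because stretch
responses frequently fail to inactivate, a peak current is ill-defined; the
stimulus–response quantity is the **charge transfer** — the trapezoidal area
under the leak-subtracted current over the stimulus window, in pC
(`charge_transfer()`). There is deliberately no stretch peak-current
operation.

Single-channel properties come from **amplitude histograms**
(`amplitude_histogram()`): the all-points histogram of a 500-ms segment is
fitted with a two-component Gaussian, and the unitary current is the distance
between the fitted peaks. The bin width defaults to
`max(0.1 pA, 2·noise_SD/5)` with the noise SD estimated robustly from first
differences; the fit is initialized from the two largest histogram modes,
ties broken toward the mode nearer 0 pA as the closed level. Openings are
declared unresolvable — an error, not a silent zero — when either component
weight falls under 2%, the separation falls under twice the pooled component
SD (or the counting bound `2·pooled/√n`), or a one-Gaussian fit explains the
histogram nearly as well. Noiseless two-level traces are singular for a
continuous mixture fit; the package falls back to a two-cluster split at the
inter-mode midpoint in that degenerate case.

**Unitary conductance** (`unitary_conductance()`) is the ordinary
least-squares slope of the per-cell I/V relation over −120 to −40 mV in
20 mV steps, converted to pS. **Patch QC** (`qc_patch()`) excludes recordings
with baseline leak above 4 pA in magnitude (strict inequality) or baseline
drift above a configurable bound (default 2 pA/s, a package choice).

**Responder calling** (`classify_responder()`): a cell responds when the
charge at any tested pressure exceeds 5 × the SD of charges measured on
stimulus-free baseline sweeps of equal duration. The SD is taken over the
*signed* baseline charges: baseline charge is a zero-mean quantity, and the
SD of its magnitudes underestimates the noise scale by a factor ≈ 0.6, which
would turn the 5-SD criterion into an effective 3-SD one and produce ~10%
false positives. With signed charges and the default of 8 baseline sweeps
the measured false-positive rate on channel-free simulations is below 1%.

The synthetic generator models each channel as an independent two-state
(closed/open) continuous-time Markov chain whose stationary open probability
follows a Boltzmann function of pressure (default midpoint −45 mmHg, slope
12 mmHg) with a mean open dwell of 5 ms; open channels each contribute
`g·(V − E_rev)/1000` pA. Every sweep carries its full event bookkeeping
(open intervals, dwell times, total open time in the stimulus window) in
metadata, which is what the charge-transfer oracle test integrates against.

## TIRF cluster tracking

Channel clusters are imaged at ~10 Hz with 0.11 µm pixels. The pipeline is:

- **Detection** (`detect_spots()`): difference-of-Gaussians blob filter at
  scales set by the expected 0.7 µm blob diameter, 8-neighbour maxima,
  sub-pixel refinement by per-axis quadratic interpolation. Spot quality is
  the DoG response normalized by a robust (MAD) noise estimate of the DoG
  image, so the quality threshold has a reproducible meaning — the
  arbitrary-unit quality scales of interactive trackers do not transfer
  across implementations, and no attempt is made to match them numerically.
- **Linking** (`link_tracks()`): greedy nearest-neighbour assignment on
  squared distance per adjacent frame pair, capped at 0.5 µm, then gap
  closing (≤ 0.7 µm, ≤ 2 missed frames, linearly interpolated and flagged),
  then a 40-frame minimum-duration filter. A globally optimal
  linear-assignment solver would differ only when spots approach within the
  link distance; at the densities simulated and validated here the greedy
  assignment recovers ≥ 95% pure tracks, and the deviation is documented.
- **MSD and classification** (`compute_msd()`, `classify_track()`): the
  time-averaged MSD over all overlapping pairs, lags up to 25% of track
  duration. The anomalous exponent α is the log–log slope over the first
  five lags; tracks are *directed* when α ≥ 1.5 or net/total straightness
  ≥ 0.6, *confined* when α < 0.3 or the normalized long/short-lag ratio
  `msd(τ₅)/(5·msd(τ₁))` < 0.3, *subdiffusive* for 0.3 ≤ α < 0.85, else
  *normal diffusion*. This transparent threshold rule replaces trained
  random-forest classifiers, which would require shipping opaque weights; it
  is validated by recovery on synthetic motion models with ≥ 85% per-class
  accuracy. `D_fit = msd(τ₁)/(4τ₁)`.
- **Cluster geometry** (`cluster_diameter()`, `cluster_density()`): an
  elliptical 2D Gaussian fit to a patch around each spot; the diameter is
  2 × the mean of σx and σy in µm. Density is first-frame spot count over
  the (externally measured) cell area.

The movie generator renders each spot as an isotropic 2D Gaussian on a noisy
background and supports four motion regimes: Brownian; subdiffusive via
fractional-Gaussian-noise increments with Hurst exponent α/2 (so the per-axis
MSD grows as 2Dt^α); confined as Brownian steps reflected radially in a disc;
directed as Brownian plus constant drift in a random direction. What the
generator does *not* emulate: photobleaching (hence no bleach-correction
stage; a preprocessing hook exists in the sense that any array can be passed
to detection), intensity fluctuations of real fluorophores, spot merging and
splitting, and heterogeneous background. Passing tests therefore demonstrate
correctness of the estimators on idealized inputs, not robustness to every
artifact of real movies.

## Responder and neurite statistics

`fisher_exact_2x2()` computes the exact two-sided test by hypergeometric
enumeration with the sum-of-small-p convention: the p-value is the sum of
point probabilities, over all tables with the observed margins, that do not
exceed the observed table's probability (relative tie tolerance 1e−7).
Degenerate margins return p = 1 with a flag. The test suite proves exact
agreement with an independent log-binomial enumeration oracle over every
2×2 table with total n ≤ 30.

`proportion_percent()` reports exact and integer-rounded percentages
(halves away from zero). `summarize_neurites()` gives per-group
neurite-bearing percentages, the mean ± SEM of the longest neurite over
neurite-bearing cells, and the cumulative distribution of neurite counts
over all cells.

`group_compare()` implements normality-gated dispatch: every group is
screened with the D'Agostino–Pearson omnibus test (α = 0.05; Shapiro–Wilk
below n = 8, where the moment-based test is unreliable). If all groups pass,
the parametric branch runs (Welch's t for two groups; one-way ANOVA with
Dunnett's post-hoc against the first group otherwise); otherwise the
nonparametric branch runs (Mann–Whitney; Kruskal–Wallis with Dunn's
rank-based z post-hoc). Dunn p-values are unadjusted by default and the
adjustment method is configurable, since reporting conventions differ.

The cell-table generator draws responder flags as Bernoulli trials,
neurite-bearing flags as Bernoulli trials, longest-neurite lengths as
log-normal with a specified mean (σ_log = 0.6, consistent with the observed
SEM-to-mean ratios of neurite-length distributions), and neurite counts as
zero-truncated Poisson for bearing cells. Its default group table carries the
tested-cell counts and observed rates of the responder and neurite
experiments.

## Numerical choices

- **Filter**: a 4-pole Bessel-type low-pass designed from the analog
  prototype poles by bilinear transform with cutoff pre-warping, applied
  forward only — causal, like the acquisition chain. A constant input is
  conserved to well within 0.1%.
- **Units and time base**: seconds internally; ms for latencies and τ in
  reports; pA, pC, pS, µm, mmHg throughout. Inward current is negative;
  summaries report magnitudes.
- **Randomness**: every generator takes a `seed` and is bit-reproducible
  given (configuration, seed); generators restore the caller's RNG state.
- **Degenerate inputs** error loudly (empty windows, zero-variance baselines
  without an explicit floor, unresolvable histograms, sub-2-pixel blob
  diameters) rather than returning plausible numbers.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise each estimator meaningfully: 200 replicates across
the τ ∈ {2, 5, 10, 20} ms grid at 5% noise; 20 cells per conductance value
over g ∈ {15, 25, 35, 45} pS with five holding potentials each (0.6-s
pressure steps, which already give 25,000-sample histogram segments);
200 Brownian tracks of 100 frames for diffusion recovery; 100 tracks per
motion class for the classification panel; 1000 seeded replicates for the
6-SD false-positive bound; and exhaustive enumeration of all 2×2 tables with
n ≤ 30 for the exact-test oracle.

## Known limitations

- The evoked-current and gating models are generative stand-ins: recovery
  tests certify the estimators, not biological fidelity of the waveforms.
- The greedy linker is not a global assignment solver and will split or swap
  tracks at densities where spots routinely approach within the link radius.
- The motility classifier's thresholds are calibrated for ~10 Hz, 100-frame
  tracks; very short tracks estimate α too noisily for reliable class calls.
- `group_compare()` covers the two designs used here (two-group unpaired,
  k-group with a single control); it is not a general linear-model interface.
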