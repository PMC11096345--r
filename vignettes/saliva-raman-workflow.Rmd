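---
title: "Classifying dried-saliva Raman maps: methods and design notes"
author: "salivaRaman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dried-saliva Raman maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivaRaman)
```

# The problem

Sjögren's disease (SjD) and radiation-induced xerostomia share a leading
symptom — dry mouth — but require entirely different management. Raman
microspectroscopy of a dried saliva drop probes the fluid's whole
biochemical composition at once, and because the dried drop is spatially
heterogeneous, a *map* of spectra (here 36 spots per drop) samples many
micro-environments of the same donor. The diagnostic question is a
three-class one: healthy control (HC), radiation patient (RD), or SjD.

The catch is that disease-related spectral changes are small. The
between-class differences of mean spectra sit *within* one in-class
standard deviation, so no single band is diagnostic; classification must
pool many small differences across the spectrum, and per-spectrum calls
must be aggregated to the donor before anything clinically meaningful is
said. This package implements that entire workflow as reusable, tested
components, together with a synthetic data generator that emulates the
relevant structure of such datasets.

# The workflow

1. **QC screening** — drop spectra with cosmic-ray spikes or too little
   signal.
2. **Preprocessing** — asymmetric weighted least-squares polynomial
   baseline (order 6), normalization by the amide I band at 1667 cm⁻¹,
   Savitzky–Golay smoothing (width 31, order 5) — in exactly that order.
3. **Outlier removal** — Hotelling T² in an 11-LV PLS-DA score space with
   an F-distribution limit; whole donors are removed.
4. **Wavelength selection** — a genetic algorithm over spectral windows,
   minimizing PLS-DA RMSECV, aggregated over many independent runs.
5. **Classification** — an RBF-kernel SVM on an 11-component PLS
   compression of the selected variables (SVM-DA).
6. **Evaluation** — 50-split cross-validation pooled into a spectral
   confusion matrix with per-class sensitivity/specificity/class error,
   then donor-level majority voting at a 50% threshold, and external
   validation on donors never seen in training.

## Preprocessing: interpretation choices

*Baseline.* "Weighted least squares, order 6" is implemented as the
standard asymmetric iteratively reweighted polynomial baseline: fit a
degree-6 polynomial, down-weight points above the fit (weight 0.01 versus
1 below), refit to convergence (tolerance 1e-6 relative, cap 100
iterations). The down-weighting makes the fit hug the valleys beneath the
Raman peaks, so subtracting it removes fluorescence without eating the
bands. On a pure degree-6 polynomial the first fit is already exact, so
the operator annihilates it; on its own output it is idempotent up to the
noise floor.

*Normalization.* "By the 1667 cm⁻¹ band" is read as division by the
maximum intensity within ±5 cm⁻¹ of 1667 (not an integrated area): the
simplest declared choice. The window maximum is exactly 1 after this step.
Because smoothing comes *after* normalization in the prescribed order, the
final spectra sit slightly below 1 at the band: a 31-point order-5 filter
systematically attenuates the top of a band of comparable width (≈1% for
a FWHM-28 Lorentzian, up to ~2–3% for composite shapes), on top of the
noise it removes. The exact-1 invariant is asserted at the normalization
stage; reapplying the chain re-normalizes by the attenuated maximum, so
the drift on reapplication is bounded by about twice the attenuation.

*Smoothing.* Savitzky–Golay via `signal::sgolayfilt`; the filter's
transient rows handle the edges as polynomial fits over the edge window,
so degree-≤5 polynomials pass through bit-faithfully everywhere.

*QC criteria.* The study removed spectra with "extensive cosmic rays or
low signal-to-noise" without numeric criteria; the package declares them:
a point more than 15 MADs above a 7-point rolling median flags a cosmic
ray, provided it is sharply isolated (at least one immediate neighbour's
residual below half the candidate's — cosmic events are 1–2 points wide,
band tops are smooth, and at very low noise a sharp band top can clear
the MAD threshold alone), and an estimated SNR (peak amplitude of the baseline-corrected,
lightly smoothed spectrum over a first-difference noise estimate) below 3
flags a dead spectrum. Both thresholds are configurable. The spike
detector presumes sampling fine enough that genuine Raman bands span many
more points than a 1–2-point spike; at ~1 cm⁻¹ steps (the axis these
instruments produce) the false-rejection rate on clean synthetic data is
well under 1%, but on axes coarser than ~2 cm⁻¹ narrow bands start to look
like spikes and the screen should be retuned or skipped (`qc = FALSE`).

*Mean-centering* before any PLS step is applied inside the modelling
functions (and re-estimated inside every CV fold), not during
preprocessing.

## Outlier removal

T² of a spectrum is the sum over retained LVs of (score²/score variance);
the limit is A(n−1)/(n−A)·F₁₋α(A, n−A). Two details were open and are
declared here: the "conservative" confidence level is α = 0.01, and donors
are aggregated by the *median* of their spectra's T² (removals are whole
donors, and the median is insensitive to the handful of spiky spectra QC
may have missed). Both are arguments, not constants.

## Genetic algorithm

Fitness is the cross-validated indicator RMSECV of a PLS-DA model on the
masked variables (venetian-blinds 10-fold, 11 LVs, both configurable —
deterministic fold assignment makes fitness a pure function of the mask).
Chromosomes switch whole windows of 15 adjacent variables; initial
chromosomes switch on ~30% of windows. The published parameter sentence
("double cross-over … window width of 30%") is ambiguous between an
initial-inclusion fraction and a window size; both readings are exposed as
independent knobs (`window_fraction = 0.30`, `window_width_points = 15`).
Selection is rank-based (top half survives), breeding is double crossover
of random survivor pairs, mutation flips each offspring gene with
probability 0.005, and the best chromosome always survives, so best
fitness is monotone non-increasing. A run stops early when the population
fitness spread drops below 1e-6. Across runs, the best chromosomes are
aggregated into per-window selection frequencies; the final mask keeps
windows at frequency ≥ 0.5 — the aggregation rule the published band list
implies but does not state.

The fitness folds are assigned at the *donor* level (a deterministic
venetian assignment over donors). This matters: with spectrum-level folds
every donor sits on both sides of every split, and the fitness then
rewards windows that merely identify donors — on synthetic data with no
class effect in a region, such windows were selected in every run. Donor
grouping restores the intended selection pressure.

An implementation note: fitness is evaluated from per-fold Gram matrices
(X'X, X'Y) precomputed once, with the training cross-products of any mask
obtained by subsetting (a compiled kernel fuses the gather, the fold
subtraction and the mean-centering correction) — the PLS itself runs in
the kernel (cross-product) form of Dayal & MacGregor. This is what makes
100 × 62-chromosome runs on ~1900 × 1400 data tractable, and it is exact:
the full-mask fitness equals a directly coded per-fold PLS-DA RMSECV
(tested against an independent NIPALS implementation).

### What wavelength selection can and cannot recover

The band-recovery experiment shipped with the package injects deficits at
the eight non-reference disease bands into an otherwise background-free
dataset and asks the GA to find them. Two structural facts, worth knowing
for any application of GA wavelength selection, shape what "success"
means there:

* *The normalization reference is invisible.* After division by the amide
  I maximum, that band sits at ~1 for every spectrum regardless of class;
  no selector operating on normalized spectra can recover a deficit at
  the reference band itself. (This is also why the generator gives the
  amide band a milder deficit than the other disease bands: were the
  deficits identical, dividing by the amide would cancel the pattern at
  *every* effect band.)

* *Informative is broader than injected.* A multivariate fitness rewards
  windows that help prediction, not only windows where the class means
  differ: windows on band flanks and on stable non-effect bands carry the
  shared normalizer and baseline fluctuations that PLS uses for noise
  cancellation (the GA-PLS literature's "reference regions"), and because
  the eight injected deficits share one discriminant direction, their
  mean information is redundant — at small n the RMSECV optimum provably
  *excludes* weak redundant bands (dropping them improves fitness), and
  at larger n their marginal value is positive but of order 10⁻³ RMSECV.
  The package therefore validates recovery as "≥ 7 of the 9 bands
  intersect the final mask", which holds robustly, while a strict
  frequency dominance of every injected window over every signal-free
  window is *not* a property of a correct selector and is not one the
  shipped experiment satisfies.

## SVM-DA

The masked, centered spectra are compressed onto 11 PLS components fit
against one-hot labels, and an RBF SVM (one-vs-one) is trained on the
scores. The published model used "standard toolbox hyperparameters" whose
values are undocumented; rather than guess, `"auto"` resolves cost and
gamma over a small declared grid (cost ∈ {1, 10, 100}, gamma ∈
{0.1, 1, 10} × the 1/median-distance² heuristic) by deterministic
*donor-grouped* inner CV — grouping by donor makes the selection target
generalization to unseen donors instead of recognition of donors already
in the training set — and the resolved values are logged in the model's
provenance. During
cross-validation the grid is resolved once on the full calibration set and
the chosen values reused in every fold; compression, centering and the SVM
itself are refit per fold from the training side only.

## Cross-validation and voting

The default scheme mirrors the published protocol: 50 splits at the
*spectrum* level. Note the caveat: spectrum-level splitting lets spectra
of the same donor appear in train and test, which flatters spectral-level
figures. Donor-grouped splitting (`split_unit = "donor"`) is provided and
recommended for any new study; the spectrum default exists to reproduce
the published protocol. (The published description — 50 splits of ~20
spectra — is also arithmetically inconsistent with 1878 spectra; fold
sizes here are derived from the data, ~38 per fold, and the discrepancy is
simply documented.) Donor voting calls the arg-max class iff its fraction
reaches the 50% threshold; ties are INDETERMINATE, never arbitrarily
called. Per-class metrics follow sensitivity = TP/actual, specificity =
TN/(TN+FP), class error = 1 − (sens+spec)/2, reported at two decimals
(half-up).

# The synthetic generator

No clinical spectra are distributed with the study this design follows, so
the generator is a first-class module, not a fixture: every downstream
stage is exercised on data whose ground truth is known.

Each spectrum is a sum of Lorentzian bands at the 20 literature band
positions of dried saliva (Lorentzian because Raman solution lineshapes
are closer to Lorentzian than Gaussian; a width/amplitude catalogue is a
generator choice), times per-class, per-donor and per-spot multiplicative
factors, plus a random degree-≤6 polynomial fluorescence baseline (scale
2× the amide I height), heteroscedastic noise whose standard deviation
grows with √(signal) (shot-noise-like), and Poisson-count cosmic-ray
spikes 1–2 points wide at 30–100× the noise scale.

The class structure: SjD spectra carry a deficit at the nine bands
reported as disease-selected (426, 1000, 1048, 1154, 1275, 1336, 1373,
1408, 1667 cm⁻¹) — multiplier 0.72 at eight of them and a milder 0.9 at
the 1667 reference band (see the wavelength-selection section for why the
reference deficit must differ). The source study reports *no* RD-specific
band changes, but a three-class problem in which RD is spectrally
identical to HC is unidentifiable by construction — no method could
separate them. The generator therefore gives RD its own mild signature
(multiplier 0.8 at 590, 622, 640, 750, 1446, 1602 cm⁻¹ —
lysozyme/protein and lipid bands, plausible for radiation-altered
saliva). This is the package's own modelling decision; experiments that
need the published effect structure exactly (e.g. the band-recovery
check) set `rd_multiplier = 1`.

The variance model encodes three facts stated about the real data and was
calibrated to them once. First, the amide I normalization reference was
chosen *because* it varies least among the strong bands; the generator
scales the 1667 band's variability down accordingly
(`norm_band_stability = 0.2`). Second, dried drops are spatially
heterogeneous — the stated reason for mapping 36 spots — so spot-to-spot
variability dominates the in-class variance (lognormal sdlog 0.25 per
spectrum × band) while donor-to-donor signatures are smaller (0.10).
Only this ordering makes the study's central observation possible at all:
single spectra classify at ~80% while majority voting over a donor's
spots is nearly always right. Third, the resulting between-class mean
difference stays within about one in-class spectral standard deviation,
so no single band is diagnostic. Outlier donors (an injected fraction,
default 6% in the pipeline, ≈ 4 of 63) receive a broad alien Gaussian
band (FWHM 120 cm⁻¹ — too narrow for a degree-6 baseline to absorb, so it
survives preprocessing, which a pure baseline distortion would not) plus
strong band-amplitude jitter.

What the generator does **not** emulate: spatial correlation between
neighbouring map spots, instrument response drift, wavelength
miscalibration, detector etaloning, or any real biochemical covariance
between bands (band amplitudes vary independently). Consequently, passing
end-to-end tests demonstrates that the pipeline machinery is correct and
recovers known structure at realistic noise — not that the published
real-data accuracies would be reproduced on new clinical material.

# Numerical and degenerate-input policy

* Baseline non-convergence returns the last iterate with a warning.
* A normalization window maximum ≤ 1e-10 × the spectrum scale is a
  "degenerate normalization band" error; in the batch chain such spectra
  are dropped and logged rather than poisoning the dataset.
* An empty or rank-deficient GA mask scores the declared sentinel RMSECV
  of 1e6 instead of crashing a run.
* PLS component extraction stops early if a component's t't falls below
  1e-12 (exhausted rank); requesting more LVs than min(n−1, p) is an
  error.
* Vote ties (no unique arg-max at the threshold) are INDETERMINATE.
* All randomness — generator, fold draws, GA — flows from explicit seeds;
  the pipeline derives every stage seed from one global seed.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make each property visible: unit tests use small cohorts
(4–8 donors/class, 4–10 spectra) on coarsened axes; the end-to-end
reproduction runs the full study geometry (22/22/26 donors × 36 spectra on
the 1 cm⁻¹ axis) with the GA shortened to 10 runs × 30 generations —
selection frequencies over 10 run-bests are coarser (steps of 0.1) but the
aggregation behaviour is unchanged; the band-recovery experiment uses 36
donors × 24 spectra on a 2 cm⁻¹ axis with 20 runs × 50 generations; null
calibrations use 200 small replicates. These sizes are the package's documented operating points for
its own validation experiments.

# Known limitations

* The spectrum-level CV default reproduces a protocol with donor leakage;
  see above.
* The GA's selection frequencies at 10 runs are coarse; the published
  setting (100 runs) is the default of `gaConfig()`.
* `"auto"` SVM hyperparameters are resolved on the full calibration set
  before CV — a deliberate, documented economy; per-fold re-tuning is
  available by passing fixed values per fold yourself.
* The QC spike screen assumes ≲2 cm⁻¹ sampling (see above).
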