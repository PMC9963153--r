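---
title: "Decoding bacterial-lysate SERS spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding bacterial-lysate SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The sensing problem

A bacterial culture exposed to trace heavy metals mounts a metabolic stress
response within hours, well before any growth inhibition is measurable.
Surface-enhanced Raman scattering (SERS) of the thermally lysed culture
records the released metabolites as a vibrational fingerprint: a spectrum of
intensity versus Raman shift (cm^-1^). `sersdecoder` implements the
machine-learning pipeline that decodes such fingerprints into (i) an
exposure-concentration class, (ii) the identity of the metal (Cr^6+^ versus
As^3+^), (iii) a continuous concentration estimate with detection and
quantification limits, and (iv) an above/below drinking-water-limit verdict
for unseen water matrices via transfer learning.

The experimental design the package mirrors uses decade ladders of exposure:
9 Cr^6+^ concentrations (0.68 pM-68 µM, from K~2~Cr~2~O~7~) and 13 As^3+^
concentrations (5 fM-5 mM, from NaAsO~2~), each class acquired as three
20 × 20 Raman maps (1,200 spectra/class), plus a control class pooled from
eight sensor surfaces in biological duplicate (9,600 spectra). Class labels
are log-decade indices: 0 for the control, then `1 + log10(c / c_min)`.

## The synthetic-data generator

Real acquisitions are large and instrument-bound, so every stage here is
driven by a generator that emulates the statistical structure the analysis
relies on, not the underlying biochemistry:

* **Line shapes.** Metabolite bands are Lorentzians, the natural line shape
  for Raman modes; the silicon substrate phonon line sits at 520 cm^-1^ with
  no dose response.
* **Dose-response.** Each band's amplitude follows a Hill curve in the
  exposure concentration, `A(c) = A0 (1 + d·M·c^h/(K^h + c^h))` with
  direction `d = ±1`. Half-effect concentrations `K` are staggered along the
  decade ladder and the slopes are shallow (`h ≈ 0.6-0.7`), so every decade
  transition moves at least one band appreciably — this is what makes a
  decade ladder classifiable at all, and it encodes the assumption that
  different metabolites respond at different exposure levels. The dominant
  band is placed at 730 cm^-1^, inside the 700-750 cm^-1^ region where
  nucleotide-related features carry the most spectral variance.
* **Nuisance structure.** Surface-to-surface and replicate-to-replicate
  variation are multiplicative log-normal gains (SD 0.15 and 0.05 on the log
  scale) applied *before* additive Gaussian noise (SD 2 counts against a
  silicon amplitude of 200). The gains are exactly what silicon
  normalization must cancel, so preprocessing is genuinely load-bearing in
  every downstream test. Gaussian noise is a desk-scale stand-in for shot
  noise.
* **Water matrices.** Tap water and wastewater add constant-amplitude
  background bands (e.g. 980/1049 cm^-1^ for tap; a denser organic
  background for wastewater) and a baseline shift, while the
  dose-responsive bands and the silicon line are untouched. Transfer
  learning has to absorb exactly this kind of shift.
* **Grid.** The canonical synthetic grid is 300-1800 cm^-1^ at 1 cm^-1^
  spacing; files read from disk keep their native grid.

What the generator does **not** emulate: real metabolite kinetics, peak
overlap congestion of a true lysate, instrument drift, cosmic-ray spikes,
or the possibility that the dose-response is non-monotone. A passing
recovery test therefore demonstrates that the pipeline's statistics are
implemented correctly, not that the biological assay works.

## Preprocessing

The chain is asymmetric-least-squares (AsLS) baseline correction, then
Savitzky-Golay smoothing, then silicon internal-standard normalization —
normalizing last keeps the silicon window maximum at exactly 1. The chain
is deliberately not idempotent; re-application raises a warning via a
provenance flag.

* **AsLS** minimizes `Σ w_i (y_i − z_i)² + λ Σ (Δ²z)²` with asymmetric
  weights (`p` where `y > z`, `1 − p` otherwise), iterated with weights from
  the previous solution (all ones on the first pass). Defaults `λ = 1e5`,
  `p = 0.01`, 10 iterations are standard chemometric values; the source
  protocol names the method but no constants, so all are exposed. The
  banded normal equations are solved sparsely; tests pin the solution to a
  dense penalized-least-squares oracle at 1e-8 on traces up to 50 points.
* **Savitzky-Golay** uses window 11, order 3, with edge points taken from
  the first/last full-window polynomial fits. The implementation wraps
  `signal::sgolayfilt`; tests verify it against brute-force windowed fits,
  including the edges.
* **Silicon normalization** divides by the *maximum within 520 ± 15 cm^-1^*
  rather than a fixed index, tolerating a few cm^-1^ of calibration shift.
  The window maximum is the natural reading of "the silicon band is set
  to 1". Spectra whose window maximum is nonpositive are reported as errors
  with their ids rather than silently propagated.

## Features: PCA, SMOTE, t-SNE

Spectra are reduced to **22 principal-component scores**, the input
dimensionality of every model. The basis is fit on the *training partition
only* and applied to the holdout; fitting on all data would leak holdout
structure into the features. A `pca_fit_all` switch reproduces the
whole-dataset fit for comparison with published variance fractions
(93-95% for 22 components at full scale). Component signs follow the
largest-entry-positive convention so bases are comparable across fits.

The control class is eight times larger than the exposed classes, so
training partitions are rebalanced with **SMOTE**: a synthetic row is
`x + u(x_nn − x)` with `u ~ U(0,1)` and `x_nn` one of the `k = 5` nearest
same-class neighbours (`k` is the canonical default; the protocol names no
value). SMOTE runs strictly *after* any split — inside each
cross-validation fold, never before — and synthetic rows carry a
`synthetic` flag so tests can audit that none ever reaches a validation or
holdout partition. Down-sampling (control to 240 for interval statistics)
is seeded uniform sampling without replacement.

t-SNE is provided for diagnostics only (the environment offers no
implementation, so an exact O(n²) embedding is included); its contract is
visual, and nothing downstream consumes it.

## SVM classification and the detection-limit rule

The concentration classifier is a multiclass RBF support-vector machine
with `C = 1` and `gamma = "scale"` (`1/(22 · Var(scores))`, computed
explicitly so the kernel matches the scikit-learn convention rather than
`e1071`'s default). The metal-type discriminator is the same path with
binary metal labels on the two metals' ladders up to ~WHO level; the
per-concentration classes are balanced by design there, so no SMOTE is
applied in that recipe.

The **classification LOD** operationalizes "better than 98% distinguished
from control" symmetrically: class `c` passes when `< 2%` of its holdout
spectra are predicted as control *and* `< 2%` of control holdout is
predicted as `c`; the LOD is the smallest concentration from which every
higher class also passes, which forces monotonicity. The row-only reading
(first direction only) is available via `rule = "row_only"`. Both
directions are gated because the source protocol states a 98% accuracy
criterion alongside a sub-0.3% false-control observation.

## The 1D CNN regressor

The architecture is fixed: four 1D convolutions (22, 22, 44, 44 filters,
kernel 7, stride 1, same padding, ReLU), each followed by batch
normalization and 20% dropout; flatten + dropout; a 22-unit ReLU dense
layer with L2 penalty 0.001; one linear output. Same padding on all four
layers (the protocol specifies it only for the first) keeps the spatial
length at 22 so the printed filter counts compose. Targets are the
log-decade class indices (0-9 for Cr, 0-13 for As); predictions are not
clipped. Training is mini-batch Adam (batch 44, learning rate 0.001, MSE),
at most 35 epochs, early stopping when validation loss has risen for more
than 10 consecutive epochs; the final-model default is the fixed 35-epoch
budget, matching the convergence the protocol reports. The network engine
is implemented in-package (no deep-learning framework exists in this R
environment) and its backpropagation is pinned to finite differences in the
tests.

One numerical choice deserves note: with few batches per epoch, the
conventional exponential running average of batch-normalization statistics
lags the quickly-moving activations badly, making inference-mode
predictions meaningless early on. The engine therefore re-estimates the
population statistics from a full training-set pass at each epoch end —
a standard post-hoc recalibration — which also makes the early-stopping
monitor meaningful.

**Detection limits from predictions.** Per class, the central 99% interval
`[P0.5, P99.5]` of holdout predictions is taken with linear interpolation
between order statistics (quantile type 7). The LOB is the control
interval; the LOD is the smallest concentration whose class and all higher
classes keep `< 0.5%` of predictions inside the LOB; the LOQ additionally
requires `< 0.5%` overlap with each existing neighbour's interval (and
implies detection, so LOQ ≥ LOD by construction). "Overlap" had to be
operationalized — the fraction of one class's predictions inside the
neighbour's interval is brute-force countable, symmetric enough, and shared
with the box-plot statistics (quartiles and 99% whiskers use the same
percentile definitions). The dynamic range runs from the LOQ to the top of
the ladder.

## Transfer learning

A binary above/below-WHO model reuses the convolutional body with a single
sigmoid output on the flattened features, trained with binary
cross-entropy. Pretraining uses DI-water ladders straddling the As^3+^
limit of 0.13 µM (0.05/0.5/5 nM below; 5/50/500 µM above). Fine-tuning to
tap water (1.3 nM, 13 nM, 1.3 µM) or wastewater (plus 13 µM) updates conv
layers 1-2, the batch-normalization parameters and the head on 80 spectra
per class while conv layers 3-4 stay bit-frozen; the epoch budget reuses
the regression protocol (unstated at the source; 35 with patience 10, and
shorter budgets in the desk-scale runs). Sample verdicts are per-spectrum
calls at probability 0.5 with a majority vote; ties resolve to "above" as
the fail-safe for water safety.

## Dosimetry

Conversions are exact arithmetic: salt basis divides by the salt molar
mass, ion basis multiplies by ions per formula unit (2 Cr per
K~2~Cr~2~O~7~), and element basis — used for WHO limits quoted as µg/L of
the element — divides by the elemental mass (0.13 µM follows from As =
74.92 g/mol). The ions-per-bacterium ratio divides ions/mL by
`OD × cells_per_mL_per_OD`. The OD calibration of **1 × 10^9^ mL^-1^
OD^-1^** is inferred, not stated: it is the unique round-number factor that
reproduces both printed ratios (0.6 As^3+^ and 8.2 Cr^6+^ ions per cell at
OD 0.5 from the respective detection limits), and it is exposed in
`culture_spec()` and documented as inferred.

## Problem sizes used in tests and the acceptance script

Simulated checks use reduced acquisitions chosen as the package's own
test-design points: recovery runs use 100 spectra per class (one 10 × 10
map) with the full 1 cm^-1^ grid; the learning-curve study uses one
20 × 20 map per class with four control surfaces so that the 1,000-per-class
point is reachable by SMOTE under the augmentation ceiling; dataset-
arithmetic checks of the full 1,200/9,600 layout run on a coarse grid,
since counts are grid-independent. Ten training epochs are used in the
desk-scale CNN runs. Full-campaign performance numbers (97%+ SVM metrics,
R² ≈ 0.99, pM-scale limits) belong to the archived laboratory dataset and
are exposed only as replication targets in `reference_performance()`.

## Known limitations

* The generator's dose-response is monotone and noise Gaussian; neither
  saturation artifacts nor heteroscedastic shot noise are modelled.
* The CNN engine is single-threaded R; it is sized for the 22-score input,
  not for raw-spectrum deep learning.
* t-SNE is exact O(n²) and intended for at most a few thousand points.
* The LOD/LOQ rules assume the decade-ladder design; arbitrary
  concentration grids work but "neighbouring class" then means adjacent in
  the sorted ladder.
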