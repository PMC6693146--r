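---
title: "Methods: REIMS fingerprint classification of faecal samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: REIMS fingerprint classification of faecal samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Rapid evaporative ionisation mass spectrometry (REIMS) burns a hydrated
faecal pellet with a diathermy electrode; the aerosol is mass-analysed
without any sample preparation, giving a complex negative-ion spectrum in
a few seconds. The spectrum is treated as an *uninterpreted molecular
fingerprint*: no ion is identified, and phenotype (species, sex,
maturity, strain) is read from the overall pattern by multivariate
classifiers. `reimsfp` implements the full workflow — from raw scan
series to classification reports and diagnostic analyses — together with
a synthetic data generator, so every stage can be exercised and validated
without instrument data.

The pipeline is, in order:

1. **Burn-event detection** on the total ion current (TIC) of a scan
   series.
2. **Aggregation** of each burn: centroids above the instrument intensity
   threshold (3 × 10⁵ counts) are summed per m/z over the member scans.
3. **Lockmass correction**: a single-point multiplicative recalibration
   of the m/z axis against a reference ion of known mass.
4. **Binning** onto a fixed grid over 400–1100 m/z (0.1 Da → 7001 points;
   0.05 Da → 14001 points).
5. **Total-ion normalisation** of each pellet spectrum, then the
   arithmetic **mean over an individual's pellets** (typically 3–4).
6. **Classification**: PCA on the feature matrix, discriminant function
   analysis (DFA) on the top 12 principal components; and random-forest
   classification evaluated out-of-bag ("all data") or on a stratified
   70/30 split, plus hold-out prediction of samples from populations
   absent from training.
7. **Diagnostics**: permutation-importance ranking of m/z bins,
   label-randomisation ("pseudospecies") null tests, isotopomer
   cross-correlation, and annotation of misclassified samples.

## What the simulator emulates

`simulate_dataset()` generates one scan series per pellet at 1 scan/s
over 50–1200 m/z. Each pellet burn is a truncated-Gaussian burst of ion
current (default 4 s, within the 2–5 s protocol range) embedded in
baseline scans. The molecular content is a list of `peak_template()`
objects — by default `lipid_peak_profile()`: 60 peaks, three quarters of
them in the phospholipid-dominated 600–900 m/z region, log-intensities
spanning about a decade around 5 × 10⁶ counts, and carbon counts of
30–50 typical of glycerophospholipids. Twenty peaks carry class-specific
multiplicative effects (default ×4, assigned round-robin across
classes); a few carry a modest sex effect (×1.5).

Each template emits its monoisotopic centroid and a first ¹³C isotopomer
at +1.00336 Da with intensity ratio 0.0107 × carbon count (the
single-substitution binomial approximation at natural abundance; the
exact binomial ratio C·p/(1−p) differs by ~1%, which a test verifies).
Intensity variation is log-normal with per-peak random effects at the
individual (SD 0.4) and pellet (SD 0.2) level. Templates can share a
`coregulation_group`, which ties their random effects together and is
how correlated-but-non-isotopic ion pairs are planted. Chemical noise is
Poisson-many exponential-intensity centroids per scan (mean 2 × 10⁴
counts, well below the instrument threshold). The continuously infused
lockmass reference (leu-enkephalin \[M−H\]⁻, 554.26) appears in every
scan at a constant 2 × 10⁶ counts and is subject to the same run-level
drift as everything else; the default profile keeps a ±1.6 Da exclusion
zone around both lockmass references so an analyte cannot hijack the
single-point correction.

Calibration drift is a per-acquisition-run additive m/z offset drawn
uniformly within ±`calibration_drift` (default 0.02 Da, bounded at
0.05); each pellet burn is one run. The burn-to-burn variance defaults
are the package's own choice of what a REIMS practitioner would call
realistic — no public quantitative estimates exist — and they are fixed:
all validation below runs at these settings.

What the simulator does **not** emulate: real lipid fragmentation and
adduct chemistry, positive-ion mode, profile-mode peak shapes,
chromatography, matrix effects, or instrument-specific detector
saturation. Passing tests therefore demonstrate that the *workflow*
recovers planted structure under realistic noise; they do not certify
accuracy on instrument data.

## Numerical choices

* **Bin grid.** Points at `start + k·width`, k = 0…n−1 with
  `n = round((end − start)/width) + 1`; 400–1100 at 0.1 Da gives exactly
  7001 points. Centroids are assigned to the nearest grid point, ties to
  the lower point; the window is `[start − w/2, end + w/2)`, closed on
  the left.
* **Burn detection.** Threshold at `median(TIC) + 0.1 × (max(TIC) −
  median(TIC))` with 2-scan hysteresis. Anchoring at the median makes
  detection robust to the constant current of the infused lockmass ion;
  with a zero baseline it reduces to a plain fraction-of-maximum cut.
* **Thresholding order.** The 3 × 10⁵ cut is applied per scan *before*
  summation — the conservative reading of "data above the threshold were
  summed".
* **Lockmass model.** Multiplicative (single-point gain), because
  time-of-flight mass error scales with m/z; the reference is the
  strongest peak within ±0.25 Da of the nominal mass, and correction is
  exactly idempotent. Correcting an *additive* drift multiplicatively
  leaves a residual `drift × (1 − mz/ref)`, ≈ 0.002 Da at 500 m/z for a
  0.02 Da drift — bins can flip for peaks sitting within that residual
  of a bin boundary, which is genuine behaviour of single-point
  recalibration, not an artefact.
* **DFA.** PCA (mean-centred, unscaled) via `prcomp`, then discriminant
  axes as eigenvectors of `W⁻¹B` on the top-12 PC scores, with a ridge
  of `1e-6 × trace(W)` on `W` so degenerate (zero within-class variance)
  inputs are handled; samples are classified by the nearest class mean
  in discriminant space. This in-package DFA is cross-checked against an
  independent LDA implementation in the test suite.
* **Random forests.** 500 trees, `mtry = √p`. Trees are grown on
  stratified equal-size subsamples without replacement (0.632 × smallest
  class, per class) rather than plain bootstrap: bootstrap OOB voting
  under-represents a sample's own class among its voting trees, which
  biases the chance level on label-permuted data well below 1/k; the
  stratified option (native to the randomForest package) removes that
  bias so a no-signal evaluation sits at chance, and it also guards
  against class imbalance. The "all data" evaluation is out-of-bag —
  resubstitution would be trivially ~100% and uninformative. Samples are
  sorted into canonical (rowname) order before fitting so results do not
  depend on input row order. The randomisation test uses 250 trees per
  shuffle: a chance-level estimate stabilises with fewer trees than the
  headline classifier, and permuted-label forests are the slowest to
  grow.
* **Importance.** Permutation importance (mean decrease in OOB accuracy,
  aggregated over all trees). The displayed top-k collapses isotopomer
  pairs: when a top bin is the heavier member of a detected isotopic
  pair, its monoisotopic partner is displayed instead, and both members
  of a pair are never shown — both, of course, stay in the model.
* **Isotopomer pairs.** For every bin pair separated by the ¹³C spacing,
  Pearson correlation across samples plus the median heavy/light ratio.
  Verdict "isotopic" needs r ≥ 0.9, ratio in [0.1, 1.0] (the first-¹³C
  range for C10–C90 species), and joint support in ≥ 50% of samples —
  the support guard exists because two sparse noise bins co-occurring in
  a single sample give a degenerate r = 1. Both whole-bin offsets
  (⌊spacing/width⌋ and ⌈spacing/width⌉) are scanned, since the true
  position of a peak within its bin is unknown and a mono/iso pair can
  legitimately land either 10 or 11 bins apart at 0.1 Da.

## Validation design and problem sizes

The package validates itself on planted-signal simulations, chosen to
be comfortably tractable on one CPU:

* *Five-class cohort*: 5 classes × 20 individuals × 3 pellets (the
  default profile). Random-forest OOB, stratified split and PCA+DFA all
  recover the planted structure; the label-randomisation null (50
  shuffles) sits at the 20% chance level while the true labels score far
  above the null's 95th percentile.
* *Isotopomer recovery*: 10 planted C40 pairs plus one co-regulated
  ratio-2 pair across 50 samples, preprocessed at threshold 0 so noise
  bins populate the candidate set (several thousand candidate pairs).
  Drift is disabled here: pair recovery is a statement about bin-stable
  spectra, and run-level drift can legitimately split a
  boundary-straddling peak across two bins.
* *Importance recovery*: 3 planted discriminant peaks among 8 shared
  ones, 10 independent seeds; the planted monoisotopic bins must appear
  in the displayed top-5 in at least 9 seeds.
* *Scale invariance*: quartering all pellet intensities (with the
  instrument threshold disabled) leaves normalised feature vectors and
  classifications bit-identical — the half/quarter-pellet robustness
  argument.

`scripts/acceptance.R` re-runs all of the above from scratch under a
caller-supplied seed and writes the measured quantities as JSON.

## Known limitations and open edges

* The vendor software's normalise/scale internals are proprietary; TIC
  normalisation is the declared stand-in, and any per-bin
  standardisation is left to matrix-level options.
* The two lockmass values that circulate for leu-enkephalin (544.26 vs
  554.26) are inconsistent; the package defaults to 554.26, the correct
  \[M−H\]⁻ mass, and exposes the choice as a parameter.
* Only the first ¹³C isotopologue is modelled; +2 isotopes, adducts and
  in-source fragments are absent, so real spectra will show correlated
  structure the simulator never produces.
* Profile-mode (non-centroided) spectra are rejected rather than peak-
  picked.
* Hold-out prediction assumes the test population shares the training
  grid and classes; site-level effects degrade accuracy gracefully only
  while class effects dominate, which the test suite demonstrates at a
  4:1 effect ratio.
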