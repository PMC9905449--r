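---
title: "Local radiomic analysis of perfusion SPECT/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local radiomic analysis of perfusion SPECT/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Perfusion SPECT/CT (Q-SPECT/CT) pairs a CT volume, which shows lung
structure, with a perfusion scintigraphy volume, which shows where blood
actually flows. The clinically decisive patterns are *local*: a pulmonary
embolism (PE) presents as a perfusion defect in lung that looks normal on
CT, while pneumonia presents as consolidated CT with largely preserved
perfusion. A whole-scan classifier can miss a small PE next to a large
pneumonia; `qspect` therefore classifies *pixels*, through small windows
centered at every pixel of expert-annotated 2D regions of interest (ROIs),
and only afterwards aggregates window decisions into a lesion-level
diagnosis.

The pipeline is: fuse the two modalities onto the CT grid; normalize SPECT
intensities; extract a fixed set of 14 radiomic features per modality from
each window; classify the 28-value vector into six tissue patterns with a
class-weighted fully connected network; vote within each ROI; and score
everything with standard diagnostic-test statistics.

## Tissue classes

Six patterns are modeled. Three are the clinical targets: healthy lung
(normal CT, normal perfusion), PE (normal CT, localized perfusion defect)
and pneumonia (abnormal CT, preserved or atypically reduced perfusion).
Three extra categories — abnormal CT with low perfusion, black background,
and extrapulmonary body tissue — are included so that the classifier learns
what the targets are *not*; without them, every window would be forced into
a clinical class and background texture would leak into clinical decisions.
Extra-category votes are kept in the ROI majority vote; a region where they
win is reported negative for all three clinical calls.

## Preprocessing

**Lung segmentation.** CT lungs are voxels in the closed interval
[-950, -300] HU (aerated parenchyma; below -950 is outside air, above
-300 is soft tissue), reduced to the largest 26-connected component and
smoothed by morphological closing with a discrete ball of radius 5 voxels,
which fills vessels and concave notches. SPECT lungs are simply voxels with
counts strictly above 20 — background tissue receives essentially no
tracer. In the full pipeline the SPECT mask is also closed with the same
ball so that perfusion-defect holes do not bias registration (a defect is
absent from the SPECT mask but present in the CT mask; closing makes the
two shapes comparable before the MSE cost sees them).

**Registration.** The SPECT volume is first resized to the CT grid shape by
trilinear, corner-aligned interpolation. Because CT and SPECT intensities
are incommensurable, the affine registration operates on the *binary lung
masks*, where a mean-squared-error cost is meaningful and cheap, rather
than on intensities with mutual information. Both masks are smoothed with a
small Gaussian (sigma 2 voxels) to make the cost differentiable; a
12-parameter affine is then estimated by BFGS with analytic gradients over
a 3-level multi-resolution pyramid (downsampling factors 4, 2, 1; at full
resolution the support voxels are subsampled with stride 2 in-plane, which
preserves sub-voxel accuracy at a quarter of the cost). Initialization is
center-of-mass alignment. On phantom lungs, random affines with
translations up to 10 voxels and scales 0.9-1.1 are recovered with mask
Dice >= 0.98. The estimated transform is finally applied to the SPECT
*intensities* (trilinear pull-back, zero fill outside the field of view).

**Normalization.** Tracer concentration varies between scans, so SPECT
values are made comparable in one of two ways, both shift-invariant and
computed over the full volume:

* `MAX`: `(x - min) / (max - min)`, mapping the scan exactly onto [0, 1];
* `PERCENTILE99`: `(x - min) / (percentile(x, 99) - min)`, mapping the
  99th-percentile intensity to exactly 1 and letting values above it exceed
  1 (no clipping; the percentile uses linear interpolation between order
  statistics, R's default type 7).

The percentile variant exists because focal hotspot artifacts — a few
voxels of very high counts unrelated to true perfusion — inflate the
maximum and compress the whole lung toward 0 under `MAX`, mimicking a
global perfusion drop. A single voxel cannot move the 99th percentile of a
volume, so `PERCENTILE99` is robust to them; the package's tests quantify
this (a 50x hotspot moves `MAX`-normalized lung means more than 10 times as
much as percentile-normalized ones).

## Window samples and radiomic features

A pixel of an ROI is a *sample* when the full `sze x sze` window centered
on it lies inside the ROI, so features never mix annotated and unannotated
tissue. Window sides 3 and 5 are the two studied settings ("3 x 3" means a
3 x 3 pixel square). Containment is monotone: every valid 5x5 center is a
valid 3x3 center. Because larger windows yield fewer samples, the 3x3
tables are count-matched to the 5x5 tables before any comparative
statistic. `run_experiment()` matches by *keeping exactly the 3x3 samples
at 5x5-valid centers*: this equalizes the per-patient, per-class counts and
simultaneously pairs the two window sizes sample-for-sample, which the
paired DeLong comparisons require. (A seeded, stratified random subsample,
`match_sample_counts()`, is provided as the general alternative.)

Each window contributes 14 features per modality, concatenated CT-then-
SPECT into 28 values:

* first order: Entropy, TotalEnergy, Uniformity;
* GLCM (gray-level co-occurrence): Id, Idm, JointEnergy, MaximumProbability;
* GLDM (gray-level dependence): DependenceNonUniformityNormalized,
  DependenceVariance, LargeDependenceEmphasis;
* GLRLM (run length): GrayLevelNonUniformityNormalized,
  RunLengthNonUniformityNormalized, RunPercentage, ShortRunEmphasis.

Texture matrices use the conventional 2D settings, fixed for determinism:
GLCM at distance 1 in the four 2D directions, symmetrized, pooled across
directions and normalized to sum 1; GLRLM counted per direction and
features averaged over the four directions; GLDM dependence = 1 + the
number of 8-neighbors with identical level (similarity tolerance alpha =
0). Entropy uses log base 2 with guard epsilon 2.2e-16; TotalEnergy scales
the raw sum of squares by the voxel volume (1 mm^3 in unitless test
configurations).

**Discretization.** Windows of 9 or 25 pixels make per-window min-max
binning unstable (a single outlier redefines all levels), so gray levels
use *fixed global bin edges per modality*: CT at 25 HU width over
[-1050, 400] HU, normalized SPECT at 0.05 width over [0, 1.5]. Every window
of a modality shares edges, making features comparable across samples and
patients; values outside the range are clamped into the end bins. CT
features are computed on raw HU.

Every feature is verified against an independent brute-force enumeration
(explicit loops over pixel pairs, neighbor counts and runs) on hundreds of
random windows at 1e-10 tolerance, and degenerate windows take their
closed-form values (constant window: Entropy 0, Uniformity 1, all four
GLCM features 1; all-distinct window: ShortRunEmphasis, RunPercentage and
LargeDependenceEmphasis all 1).

## Classifier

The network is `28 -> dense(128) -> ReLU -> dense(128) -> dense(6)` with a
per-class sigmoid output and one-hot targets; the hard label is the argmax
(restricted to classes present in training). Features are z-scored with
training statistics frozen into the model.

**Class weights.** Imbalance is corrected by weighting each class's loss by
the inverse of its frequency, normalized to sum one: `w_i` proportional to
`1 / rho_i`, `rho_i = n_i / n`. The rarest pattern (typically PE) gets the
largest weight. The direct-frequency variant (`w_i = rho_i`) is available
behind `inverse_weights = FALSE` for comparison but is not a sensible
imbalance correction (it *down*-weights rare classes).

**Loss.** Two related losses exist in the package, deliberately:

* `weighted_cross_entropy()` scores only the true-class output,
  `Loss_i = mean(-ln s_true)` over class-`i` samples, combined as
  `sum w_i Loss_i` (a uniform predictor over six classes scores exactly
  `ln 6`). It is reported for comparability.
* `weighted_full_cross_entropy()` is the *training objective*: the full
  one-hot cross-entropy over all six sigmoid outputs,
  `-sum_k [y_k ln s_k + (1 - y_k) ln(1 - s_k)]`, with the same per-class
  weighted structure. The distinction matters: a loss that only rewards the
  true-class score has a degenerate minimum in which every output saturates
  at 1 for every input — zero loss, no discrimination — and in practice an
  argmax rule trained on it stalls around 75% accuracy even on linearly
  separable data. The full cross-entropy also pushes wrong-class scores
  down and trains cleanly; for a sigmoid output layer it is the standard
  reading of "weighted cross-entropy".

Optimization is mini-batch Adam (learning rate 1e-3, batch 256, at most 200
epochs) with early stopping when a 10% held-out split fails to improve by
at least `min_delta = 1e-3` for 20 epochs (the margin matters: the held-out
loss keeps improving microscopically long after the classification has
converged, and without it the patience rule never fires; the best weights
seen are still kept at full precision). All of these are
configuration-exposed; none is specified by the underlying method, and the
defaults were chosen once for stable training on tables of 10^3-10^4 rows.
Training is bit-reproducible under a fixed seed.

## Lesion-level diagnosis

The ROI diagnosis is the most frequent predicted pattern among its samples.
Count ties break by clinical severity (PE > pneumonia > abnormal-CT/low-
perfusion > healthy > body > background): a tie involving the most
dangerous pattern should never be resolved away from it, which maximizes
PE sensitivity — the rule-out role the method targets. The vote uses hard
labels, not averaged scores ("most frequent pattern" is a vote), and
extra-category votes are retained. Exactly one class is modal, so at most
one of the three binary calls (PE, pneumonia, healthy) is positive.

## Evaluation

One-vs-rest panels for the three clinical classes, with extra categories
excluded from clinical metrics: positives are samples (or ROIs) of the
class, negatives the other two clinical classes. Sample-level ROC uses the
class's sigmoid score. AUC is the Mann-Whitney pair statistic with DeLong
95% intervals; proportions carry exact Clopper-Pearson intervals; model
AUCs are compared against the gold model with paired DeLong tests and
Bonferroni adjustment (these standard computations are delegated to
`pROC` and `stats::binom.test`, and cross-checked in the tests against
exhaustive pair counting and hand-built contingency tables).

Model selection uses leave-one-patient-out cross-validation on the training
group: all samples of one patient are held out together (windows from one
patient are strongly correlated; row-wise folds would leak), predictions
are pooled over folds, and the gold model is the one with the highest mean
clinical-class AUC — an automatic, deterministic version of picking the
best row of the selection table. The chosen models are then refit on the
full training group and evaluated once on held-out test patients.

## The phantom cohort

No clinical data ships with the package, so a synthetic phantom generator
(`generate_phantom_patient()`, `generate_cohort()`) emulates the study
conditions end to end; its defaults are the package's fixed study
conditions, not tuning knobs:

* 72 x 72 x 20 CT grid at 1.25 x 1.25 x 3 mm; two ellipsoidal lungs
  (CT ~ Normal(-800, 60) HU) joined by an airway-like bridge (so the
  largest-component rule finds one lung object, as on real CT), inside a
  body of Normal(40, 20) HU on a -1024 HU background;
* SPECT: smooth perfusion field (baseline 100 counts, 25% sinusoidal
  modulation) on the lungs with Poisson noise; body and background Poisson
  rates 2 and 0.2 (so the count threshold of 20 separates lung);
* PE: pleural-based wedges (90-120 degree sectors over ~5 slices) where
  SPECT is multiplied by 0.15 and *CT is untouched* — the package's tests
  verify that PE-region CT is statistically indistinguishable from healthy
  lung;
* pneumonia: ellipsoidal blobs with CT raised to Normal(-400, 100) HU
  (>= 300 HU above lung) and perfusion preserved; abnormal-CT/low-perfusion
  blobs combine both changes (multiplier 0.2);
* 3 hotspot voxels at 50x the mean lung count, the artifact that motivates
  percentile normalization;
* the emitted SPECT is downsampled 2x onto a coarser grid and misaligned by
  a known random affine (scale 0.98-1.02, translation up to 3 voxels), so
  resizing and registration are genuinely exercised;
* per patient: 2 PE wedges, 2 pneumonia and 1 abnormal blob (each
  annotated on up to 2 slices), 2 healthy, 1 background and 1 body-tissue
  disc ROIs of radius 4-5 px — a few hundred 3x3 samples and 100-250
  5x5 samples per patient, so a 20-patient training group carries a few
  thousand matched samples, the same order as a realistic annotation
  campaign.

What the phantom does *not* emulate: real airway/vessel anatomy, attenuation
and scatter, respiratory motion, reader variability in ROI placement, and
pneumonia's full textural heterogeneity. Passing the end-to-end criteria on
phantoms therefore demonstrates that the pipeline's machinery is correct
and its directions (percentile normalization beating max normalization
under hotspots; ROI voting raising PE sensitivity) are reproduced under
controlled conditions — not that the clinical performance figures of any
particular cohort are reproduced.

## The experiment

`run_experiment()` runs the four standard arms — `ModelPrct3`,
`ModelPrct5`, `ModelMx3`, `ModelMx5` (window size x normalization) — over a
cohort directory: preprocessing, feature extraction, count matching, LOSO
selection, final fits, test evaluation at sample and ROI level, and AUC
comparison against the gold model. The default problem size used by the
acceptance workflow is 20 training + 20 test phantom patients, which keeps
a full run within a quarter of an hour on one CPU while leaving several
thousand samples per arm. All randomness derives from one master seed;
identical seeds give bit-identical sample tables, model weights and report
files.

## Numerical choices and edge cases

* Coordinates are 1-based `(row, col, slice)` voxel indices throughout,
  matching R indexing; affine transforms map reference coordinates to
  source coordinates (pull-back) in voxel units.
* FFT-based convolution implements 3D dilation/erosion; counts are rounded
  before thresholding, making the morphology exact, and masks are padded by
  the ball radius so closing behaves as on an infinite background
  (extensive and idempotent).
* Connected components: 26-connectivity in 3D (lung masks), 8-connectivity
  in 2D (ROI blobs).
* Constant windows, empty masks, single-class tables, zero denominators in
  metrics and degenerate (singular) affines all error or take documented
  closed-form values rather than propagating NaN.
* Sample tables are written as full-precision TSV; volumes as NIfTI-1;
  transforms as 12-number JSON. A minimal DICOM series reader (uncompressed
  little-endian single-frame series, slope/intercept applied, slices sorted
  by position) covers the standard clinical export path.

## Known limitations

* The affine mask registration recovers synthetic misalignments to sub-voxel
  accuracy, but with a heavily downsampled SPECT grid the *pipeline's*
  residual error against ground truth is 1-2 voxels, dominated by
  interpolation blur rather than the optimizer; boundary windows of small
  lesions are the main casualty.
* Per-class sigmoid scores are not calibrated probabilities and do not sum
  to 1; they are used only through ROC analysis and argmax.
* The phantom's lesions are geometrically simple; models trained on
  phantoms are not transferable to clinical data and exist to validate the
  machinery.
* Whole-patient diagnosis (combining ROI calls into a patient call) is out
  of scope.
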