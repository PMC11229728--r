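---
title: "Voxel-wise prostate cancer risk maps: models, calibration and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise prostate cancer risk maps: models, calibration and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProCaMap)
```

## The problem

Multiparametric MRI (mpMRI) of the prostate combines T2-weighted imaging
(T2W), diffusion-weighted imaging (ADC and FA maps), and dynamic
contrast-enhanced imaging (summarized per voxel by peak enhancement PE,
maximum enhancement slope ES, and washout rate WO). Each contrast carries
partial information about whether a voxel is cancerous: tumors are
typically hypointense on T2W and ADC, enhance fast, and wash out fast.
ProCaMap turns these six parameter volumes into *cancer risk maps*: per
voxel, the probability that the tissue is cancer, and the probability that
cancer there is high grade (Gleason grade group 3 or higher). Binarizing
the maps with calibrated thresholds yields lesion masks from which lesion
count, location and volume (tumor burden) are quantified and evaluated
against a reference lesion set.

## Tissue models

The core classifier is a per-zone logistic regression over the six
normalized MRI parameters and their squares,

$$
\mathbb{P} = \frac{1}{1 + e^{-t}}, \qquad
t = A + \sum_i B_i x_i + \sum_j C_j x_j^2 .
$$

Three model types are fitted separately for the peripheral zone (PZ) and
transition zone (TZ):

* **AFMS vs cancer** — the anterior fibromuscular stroma is benign tissue
  whose DCE appearance mimics cancer; a dedicated model (in which
  fractional anisotropy carries most of the discrimination) identifies it
  so it can be excluded before cancer mapping.
* **cancer vs benign** (AFMS excluded from the benign class),
* **high vs low grade** within cancer.

Term selection is a mixed stepwise search: candidate terms are the six
linear parameters and their six squares; the candidate with the smallest
likelihood-ratio p-value enters while it is at or below 0.15, and any
included term whose p-value rises above 0.15 is removed, until the set is
stable. Entry and removal share the single 0.15 threshold; the final
coefficients are the maximum-likelihood fit on the selected set. Two
safeguards follow:

* **Perfect separation** (possible on clean, small ROI tables) collapses
  the ML problem; the fit falls back to a ridge-regularized logistic
  regression (`glmnet`, alpha 0, lambda 0.01) with a warning and a
  metadata flag. The ridge solution preserves the ranking of voxels, which
  is what thresholding uses.
* **Univariate-consistency pruning**: a linear term whose fitted sign
  contradicts the sign of the difference of its class means (positive
  minus negative class) is removed together with its quadratic partner and
  the model refitted, iterating to a fixed point. Quadratic-only terms
  have no univariate-mean analogue and are left alone.

Model quality is assessed by stratified 4-fold cross-validation of the
held-out AUC, with a t-based 95% confidence interval over the folds. When
the minority class cannot populate every fold the cross-validation is
skipped and flagged — the situation that arises for the AFMS models when
AFMS regions are scarce. With twelve candidate terms and an unadjusted
0.15 entry threshold, some spurious term enters in a substantial fraction
of null tables (roughly $1 - 0.85^{12}$); the per-term inclusion rate
stays near the nominal 15%. This multiplicity behaviour is inherent to
the unadjusted mixed stepwise procedure.

## Normalization

Raw T2W intensities depend on receiver gain and coil loading, and DCE
amplitudes differ between patients. Three normalizations remove the
between-patient variance:

* **Coil bias correction.** The endorectal coil imposes a strong
  multiplicative reception profile on T2W. The correction divides by a
  smooth positive field estimated by normalized-convolution Gaussian
  smoothing inside the body mask (scale: one quarter of the in-plane
  field of view), rescaled to unit mean. This is a deliberately generic
  divide-by-smooth-field estimator.
* **Muscle-referenced T2W scaling**: every voxel is divided by the mean
  T2W over two reference ROIs in the obturator muscles, making the T2W
  scale dimensionless and gain-invariant.
* **DCE scaling**: ES and WO are multiplied by the ratio of the cohort
  PE reference (the mean over cases of the per-case prostate-mean PE) to
  the case's own prostate-mean PE. PE itself differs little between
  prostate tissues, so this removes per-patient contrast amplitude while
  preserving the per-voxel ES/WO ratio. The whole prostate mask is used
  for the per-case PE mean. PE is left on its raw scale; its large
  between-patient variance is exactly why the stepwise search tends to
  drop it.

ADC is computed from a two-b-value pair as $\ln(S_0/S_b)/b$; voxels with
non-positive signal are zeroed and counted. DCE summary features use the
mean of the first two (pre-contrast) frames as baseline, the largest
forward finite-difference slope up to the first peak as ES, and the
negated least-squares slope from the peak onward as WO, so a positive WO
means signal loss after the peak. The displayed "washout" of clinical
reading has the opposite sign convention; the numeric convention here is
applied consistently in fitting and mapping, which is all that matters to
the classifier.

## Registration

Each parameter volume is aligned to the T2W grid by a two-step rigid
registration maximizing normalized mutual information,
NMI $= (H(A)+H(B))/H(A,B)$, over 32 equal-width intensity bins:

1. an in-plane search (x/y translation plus axial rotation) over the full
   field of view, histograms pooled across slices, on a 2x in-plane
   downsampled grid: a coarse grid (2 mm / 3 degree steps) followed by
   Nelder-Mead refinement;
2. a full 6-parameter refinement restricted to the prostate mask dilated
   by 6 mm (subsampled to at most 20,000 voxels), again by Nelder-Mead.

Nelder-Mead was chosen as the derivative-free refiner because NMI over a
trilinear resampling is piecewise smooth but not differentiable; all
optimizer settings are fixed, so the result is deterministic. Quality
control composes the estimated transform with the inverse of a reference
transform and evaluates the mean displacement of prostate voxels, split
into in-plane and out-of-plane components with pass criteria of 2 mm
(one third of the diameter of a 0.1 cc lesion) and 3 mm (the slice
thickness). Transforms use intrinsic rotations with the slice axis
applied last, about the grid centre. Image resampling is trilinear, with
nearest-neighbour for label volumes and an explicit fill value outside
the source field of view.

## Maps, thresholds, lesions

Map construction first applies the AFMS model to every prostate voxel and
removes voxels with AFMS probability at or above 0.5 from the mask
("not cancer" by definition); the surviving voxels get cancer and
high-grade probabilities from their zone's models (the AFMS wedge itself,
when it survives, is scored with the TZ models, which it abuts). All
threshold comparisons are inclusive.

The binarization threshold is not arbitrary: it is *calibrated by volume
ratio*. For each threshold on a fixed grid (0.05 to 0.95, step 0.01), the
per-case ratio of MRI cancer volume to reference cancer volume is
computed and averaged over the cohort; the calibrated threshold is the
grid value whose mean ratio is closest to one (smallest such value on
ties — the mean ratio is non-increasing in the threshold, so ties are
plateaus). The high-grade threshold is calibrated second, sweeping the
high-grade probability inside the already-fixed cancer mask against the
high-grade reference volumes. A high-grade voxel must pass *both*
thresholds: confirmed cancer first, then confirmed high grade, so the
high-grade mask is always a subset of the cancer mask.

Lesions are 26-connected components of the binary masks (6-connectivity
is available); components at or below 0.1 cc are excluded from the lesion
lists but reported separately. Lesion centroids are localized in a
27-sector grid formed by splitting the prostate bounding box into equal
thirds along each anatomical axis.

Matching against reference lesions automates what a reader would do
side-by-side: two lesions are co-located when either centroid falls
inside the other's component or the centroids are within 5 mm; ambiguous
overlaps are resolved greedily by voxel overlap, then volume similarity,
then distance. A matched MRI lesion must also have a *plausible volume*:
within the bounding lines $0.75\,(v_{\mathrm{ref}} - 1)$ cc and
$\tfrac{4}{3} v_{\mathrm{ref}} + 1$ cc, symmetric about the 1:1 line. An
oversized match counts as a false positive, an undersized one as a false
negative for the reference lesion. The printed form of the lower bound is
typographically ambiguous between $0.75\,(v-1)$ and $0.75\,v - 1$; the
symmetric reading is the default and the other is selectable
(`boundConvention = "table"`). The factor tables define no countable
negative unit at the lesion level; this package counts the 27 prostate
sectors containing neither an MRI nor a reference lesion centroid as true
negatives, and records that convention in the match metadata — it is an
interpretation, not part of the factor rules.

Tumor-burden (volume-level) factors are exact: TP = min(MRI, reference),
FP = max(MRI − reference, 0), TN = prostate − max(MRI, reference),
FN = max(reference − MRI, 0); the four always sum to the prostate volume.
Agreement of volumes is summarized by Bland-Altman statistics (mean and SD
of differences, 1.96-SD limits, with splits below and above 1 cc of
reference volume). Threshold-swept ROC curves recompute the masks and
factors at each threshold and integrate trapezoidally with (0,0) and
(1,1) anchors; the operating point maximizes the Youden index, tie-broken
toward equal sensitivity and specificity.

The per-lesion ROC sweeps are centred on each curve's own calibrated
operating threshold (from 0.2 below it up to 0.95, in 0.05 steps). Far
below the calibrated threshold binary masks stop being lesion-like: the
mask floods and merges across the prostate, every reference lesion fails
the volume bounds simultaneously, and the per-lesion factor counts
degenerate (the curve is not even monotone there). Applying the same
centring rule to the all-cancer and the high-grade curve keeps the two
comparable. The volume-level (burden) ROC has no such degeneracy and
sweeps the full 0.05 to 0.95 range.

## The synthetic phantom

Patient data cannot ship with a package, so every stage is exercised on
synthetic cases with known ground truth. A case is a 96 x 96 x 24 grid at
1 x 1 x 3 mm (3 mm slices, sub-millimetre in plane): an elliptical body,
a prostate of about 28 cc with PZ and TZ zones, an anterior midline AFMS
wedge, two obturator-muscle reference regions, and lesions grown as
spheroids around seeds to an exact target voxel count inside their zone.
Distinct lesions are seeded apart (by the sum of their equivalent-sphere
radii plus a buffer) so ground-truth foci remain separate objects, as
distinct histopathology lesions are.

Voxel parameter vectors are drawn from per-class six-dimensional normal
distributions. The class means encode the field's qualitative contrasts —
cancer low in T2W/ADC and high in ES/WO, AFMS distinguished mainly by
high FA with intermediate DCE — and the default separations were chosen
once so that the fitted ROI models land in a realistic accuracy regime
(cancer-vs-benign cross-validated AUC above 0.9, grade models clearly
weaker) while voxel-level maps support lesion detection at calibrated
thresholds. Within-class variance is split between iid voxel noise and a
smooth spatial heterogeneity field (fraction 0.7 of the SD, correlation
length 12 mm, total variance preserved): real tissue variation is
regional, not white. This choice has two visible consequences that mirror
real data: false-positive voxels arrive as coherent blobs rather than
salt-and-pepper noise, and a missed lesion is usually missed whole.

Two acquisition artifacts are simulated: a multiplicative endorectal-coil
reception profile on T2W (amplitude 1.2, decay 40 mm from a posterior
coil position), and per-case DCE amplitude scaling (log-normal, SD 0.3 on
the log scale, across a cohort). Optionally a rigid misalignment is
applied to all non-T2W volumes (the registration module's test bed) and a
smooth random displacement field capped at a configurable millimetre
amplitude distorts ADC/FA, emulating echo-planar distortion. Cohorts vary
prostate size (+/-12%), lesion count (Poisson, mean 3.7, at least one),
lesion volume (clamped log-normal with mean 0.55 cc and SD 0.98 cc),
zone (70% PZ) and grade (40% high); per-case totals are redrawn below
0.5 cc, emulating a biopsy-proven-cancer cohort.

Training tables are built by sampling small spherical ROIs (radius
2.5 mm) fully contained in one tissue class and recording the mean of
each parameter. The study pipeline additionally jitters each ROI centre
by a 2 mm (SD) random offset *after* selection, without re-checking
class purity: this emulates the error of transferring histology regions
onto MRI via anatomical landmarks, and it is the feature that keeps ROI
tables from being trivially separable — without it, stepwise selection
collapses to a single term and the fitted models underuse the available
contrasts. The operation itself defaults to no jitter, so its
mean-recovery property is exact.

What the phantom does *not* emulate: MR physics (k-space, noise spectra,
partial volume), pharmacokinetics beyond the three DCE summaries,
deformable anatomy, histopathology processing distortion, and reader
variability. Passing tests on the phantom therefore demonstrate that the
pipeline's logic — normalization, fitting, calibration, matching,
scoring — behaves correctly under controlled conditions, not that the
fitted models transfer to any particular scanner or cohort.

## Problem sizes and numerical choices

The packaged study runs 40 phantom cases with 8 ROIs per class per case
and 4-fold cross-validation; the registration experiment recovers 40
random misalignments within +/-5 mm and +/-5 degrees. Calibration sweeps
run at 0.01 steps; per-lesion ROC sweeps at 0.05 steps over 0.35–0.95.
Histogram NMI uses 32 bins; optimizer tolerances are fixed in code.
Degenerate inputs are handled explicitly: empty masks error, all-zero
T2W passes the bias correction unchanged, flat DCE series give zero
features, single-class label sets refuse ROC computation, and zero
denominators yield flagged `NA` metrics rather than silent zeros.

## Known limitations

* The coil correction is a generic homomorphic-style estimator; dedicated
  coil-profile corrections will do better near the coil.
* The lesion-level true-negative unit is a convention (27 sectors); other
  conventions change specificity but not sensitivity/PPV.
* Matching is centroid/overlap-based and one-to-one; a single MRI
  component spanning two reference lesions credits only one of them.
* The stepwise entry threshold of 0.15 with twelve candidates admits
  spurious terms at the expected multiplicity rate; consistency pruning
  removes only sign-contradictory ones.
* Diffusion distortion is modelled but not corrected; registration is
  rigid by design.
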