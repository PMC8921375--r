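---
title: "Bullous parametric response mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bullous parametric response mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bprm)
```

# The problem

Spirometry (FEV1/FVC%) grades airflow limitation in COPD globally, but the
tissue destruction driving it — emphysema and functional small-airway disease
(fSAD) — is spatially heterogeneous. Paired inspiratory/expiratory chest CT
can localize both: emphysematous tissue stays abnormally dark (low
attenuation) in both breathing phases, while air trapped behind diseased
small airways makes tissue dark only on the expiratory scan. This package
quantifies both processes, fits a linear model that predicts FEV1/FVC% from
the size-and-location composition of the lesions, and projects the fitted
model back onto the lung as a grid severity map (the bullous parametric
response map, BPRM) intended to rank candidate target regions for
bronchoscopic lung volume reduction.

The pipeline is: lung/airway segmentation → upper/lower lobe-group partition
→ non-rigid expiratory-to-inspiratory registration → voxel-wise PRM
classification → low attenuation cluster (LAC) extraction → 10-scale LAD
predictor assembly → linear model with backward selection → grid severity
map.

# Densitometry and the PRM

A voxel is a lesion voxel when its HU lies **strictly below** a threshold
(one convention everywhere; the boundary value itself is not a lesion):

* mild emphysema, inspiratory CT, −920 HU (a −930 variant is selectable via
  `thresholds(emph_mild = -930)`);
* severe emphysema, inspiratory CT, −950 HU;
* air trapping, co-registered expiratory CT, −856 HU.

`LAV%` is 100 × lesion voxels / parenchyma voxels, where parenchyma is the
lung mask minus the airway, restricted to the voxels whose warped expiratory
sample stayed inside the expiratory field of view. Regional values (upper /
lower lobe groups, left / right) use the *whole-lung* denominator, so
regions add to the whole and predictor sums reproduce regional LAV% exactly.

PRM classification on the co-registered pair uses, by default, the rule
that emphysema requires HU < −950 on **both** phases; fSAD is expiratory
HU < −856 excluding emphysema; everything else in the parenchyma is normal.
The classic variant (inspiratory < −950 with expiratory < −856 as
emphysema; fSAD requiring inspiratory ≥ −950) is available as
`emph_rule = "classic_prm"`. The two rules disagree exactly on voxels that
are dark on inspiration but partially recover on expiration
(insp < −950, −950 ≤ exp < −856); both are tested.

# Low attenuation clusters and LAD

LACs are connected components of a lesion mask, refined by an
iterative-erosion analysis: `erosion_depth_map()` counts how many 3×3×3
erosions each voxel survives. *Cores* are the connected components of
`depth ≥ min_core_depth`; every lesion voxel is assigned to exactly one core
by descending-depth region growth (a marker watershed on the negated depth).
Two bullae fused through a thin neck therefore split, while one solid bulla
stays whole. `min_core_depth` defaults to 2 so single-voxel noise never
creates a core; `Inf` turns splitting off entirely and reproduces plain
connected-component labelling (a tested degeneracy). An earlier candidate
definition — local-maximum plateaus of the depth map — fragmented digitized
spheres into dozens of spurious cores (the discrete depth field of a ball is
bumpy) and was rejected in favour of the threshold-component definition,
which is monotone and idempotent.

A cluster's LAD is its voxel count over the parenchyma count; by
construction the LADs of one mask sum to LAV%/100 to machine precision, a
property the tests assert at 1e−12.

Expiratory (−856) clusters are classified by *emphysema predominance*: the
fraction of PRM-emphysema voxels within the cluster. Above the cut
(`ratio_cut`, default 0.5 — "predominant" read as majority) the cluster is
excluded from fSAD accounting; otherwise it is an fSAD cluster whose
*effective* LAD is its PRM-fSAD voxel count over the parenchyma count, and
its size scale is assigned from that effective LAD. Clusters smaller than 8
voxels are kept but flagged, as no size floor is imposed.

# Registration

The expiratory lung is aligned to the inspiratory lung per side with
coherent point drift (CPD) on evenly distributed mask points:

* `sample_points()` bins voxel centres on a physical grid (default pitch
  8 mm) and keeps the voxel nearest each bin centre — deterministic,
  grid-anchored, no randomness. Surface (boundary) and interior roles are
  sampled separately and concatenated as the CPD input; the airway is
  excluded by construction of the side labels.
* `cpd_nonrigid()` implements the Gaussian-mixture EM with motion-coherence
  regularization. Both point sets are normalized to zero mean and unit RMS
  internally — the mixture's uniform-outlier constant is only calibrated in
  normalized units, and without normalization the outlier term swallows the
  data at millimetre scales. The mixture variance is non-increasing across
  iterations (tested to 1e−9), and registering a set to itself is the
  numerical identity (< 1e−6 mm).
* `warp_volume()` interpolates the landmark displacements (moved surface +
  interior points of both sides pooled) with a 3-D polyharmonic spline
  (kernel φ(r) = r, affine term, tiny ridge), evaluated on a coarse lattice
  (4 mm) and trilinearly upsampled. The affine term reproduces uniform
  shifts exactly; the surface landmarks pin the field at the lung boundary.
  Voxels mapping outside the expiratory field of view become −1024 and are
  excluded from all densitometry.

CPD's free parameters are not physical constants; they were fixed by
deformation recovery on the synthetic phantom: kernel width β = 20 mm,
regularization λ = 3, outlier mass 0.1, pitch 8 mm give a mean
target-registration error of 1.7–1.8 mm across phantom seeds (the function
defaults β = 15, λ = 2 are ordinary textbook values; the pipeline config
carries the tuned ones). Point counts at this pitch are a few hundred per
lung, so the full Gram matrix is used; the sampler would need a coarser
pitch before a low-rank approximation became worthwhile.

A limitation worth stating plainly: mask points carry no information about
tangential motion in the lung interior (the aperture problem), so the
smooth interior component of a deformation that does not move the boundary
is unrecoverable by any point-set method. On the phantom this bounds the
achievable HU-mismatch reduction well below what warping with the true
field achieves; the tests therefore assert both an absolute improvement and
a fraction of the oracle improvement rather than an absolute near-perfect
alignment.

# Segmentation

The airway is grown from a trachea seed (found automatically as the
enclosed, central air component walking down from the apex) with a
leak-guarded threshold staircase: growth at successively more permissive HU
thresholds, rejecting a step whose volume jumps more than 3-fold or exceeds
5% of the image — this is the "adaptive" element of seeded region growing.
The lung is then grown from airway-adjacent voxels under an upper bound of
−200 HU; a +200 HU bound (the lung-window convention) would flood soft
tissue from an air seed, so the literal value is available only via
configuration. Enclosed vessels are re-included by morphological closing
plus cavity filling (disabled together by `closing_iter = 0`), and the
airway is subtracted at the end, making parenchyma = lung − airway the
single denominator downstream.

Left/right splitting erodes until the mask separates, keeps the two largest
fragments as seeds, reassigns every original voxel by geodesic distance
inside the mask (Euclidean-nearest seed centroid for unreachable pockets),
and names sides by centroid x (RAS: larger x = patient left). The
upper/lower lobe-group border is a regularized thin plate spline
`z = f(y, x)` through fissure points detected by a Hessian plate filter
(score `|λ1|(1−|λ2|/|λ1|)` for bright plates, non-maximum suppression along
the plate normal); the right middle lobe counts as lower, so one surface
per lung suffices. With fewer than 6 usable points the border falls back to
a horizontal plane at 0.55 of the cranio-caudal extent, with a logged
message.

# The airflow model

Pooled cluster LADs (inspiratory severe-emphysema pool and expiratory fSAD
pool, pooled separately — a joint mode is a one-liner by concatenating the
pools before `fit_scale_model()`) are clustered into 10 size scales by an
exact univariate k-means dynamic program (`ckmeans_1d()`, verified against
exhaustive enumeration); new LADs are assigned by boundary lookup with
clamping at the extremes. The 40 predictors are
100 × Σ LAD per (scale 1–10 × upper/lower × emphysema/fSAD); the model is
ordinary least squares with backward elimination of the highest-p predictor
until all survivors have p < 0.05 (ties broken toward the largest column
index; rank-deficient columns dropped with one warning). Evaluation is
stratified (response-quintile) five-fold cross-validation repeated 30
times, reselecting the model inside every training fold — the honest
variant; a fixed-model mode (`reselect = FALSE`) selects once on the full
data and only refits per fold.

# The synthetic phantom

`make_phantom_pair()` builds what the downstream stages need and no more:
two ellipsoidal lungs (inspiratory parenchyma ~N(−850, 30) HU, expiratory
~N(−760, 30)) in a soft-tissue torso (~+40 HU), a sealed Y-shaped airway at
−1000 HU reaching both lungs, one oblique fissure plane per lung, two small
bright vessels, spherical bullae (~N(−980, 10), both phases) and air-trap
spheres (~N(−900, 15), both phases). These HU choices give every threshold
a ≥ ~3 SD margin to its neighbouring class. Expiration is a known smooth
field — 8% contraction toward each hilum plus a 2 mm sinusoid of 60 mm
wavelength, tapered smoothly to zero outside the lungs — and the expiratory
image is generated by evaluating the analytic geometry at the fixed-point
inverse of that field, so the truth (dense displacement, per-phase lesion
and lung labels, lesion catalog) is exact by construction. One integer seed
drives independent named noise streams, so adding lesions never perturbs
the parenchyma noise and identical seeds give bit-identical volumes.

What the phantom does **not** emulate: scanner point-spread blur and
partial-volume mixtures, anatomically shaped airway trees and fissures,
respiratory sliding at the pleura, and HU calibration drift. Passing the
phantom checks therefore demonstrates the correctness of the algorithms
under known truth, not clinical segmentation or registration performance.

`make_cohort()` generates the statistical study conditions: per subject,
cluster LADs from a log-normal size law (meanlog log 0.002, sdlog 1.2 — a
documented stand-in, as no cohort-level size distribution is available),
assigned to 10 fixed scales (quantile boundaries of that law, heavier on
the small scales), ~20 clusters per (lobe group × lesion type) category,
summed into the 40 predictors. The true model places 16 nonzero negative
coefficients (matching a 16-predictor final model) on scales 6–9 in both
groups and both types, with magnitudes equalizing each term's
linear-predictor variance (closed-form truncated log-normal moments — the
allocation that maximizes mean sign-recovery power); the noise SD follows
from a target population R² of 0.67 and the intercept centres the response
near 54.5 FEV1/FVC% (responses clipped to [10, 95]; < 1% of subjects are
affected at the defaults). At n = 100 this yields a mean repeated-CV
Pearson r of ~0.81. One feasibility fact is documented rather than hidden:
with 40 candidate predictors at n = 100, chance collinearity inflates the
full-model standard errors by ~28%, so p < 0.05 backward selection retains
a true term with its correct sign ~85–86% of the time; an idealized
Gaussian-predictor design does no better (~84%), so this is a property of
backward selection at these sizes, not of the generator. Among retained
true terms the sign is always correct.

# BPRM severity

"Severity" of a grid cell is its signed share of the model's predicted
FEV1/FVC% deviation from the intercept: each voxel of a LAC whose
(scale, group, type) term survived selection carries
`β × 100 / parenchyma_count`, so a LAC's voxels sum exactly to `β × LAD%`
(fSAD clusters paint only their PRM-fSAD voxels, matching their effective
LAD), and cell totals plus the intercept reproduce the subject-level
prediction to 1e−9 relative — the conservation property is the normative
definition, tested also under grid refinement. Cells are cubes (default
20 mm, configurable) anchored at the lung bounding-box corner for
determinism and ranked ascending, most negative first — the convention that
the most severe candidates appear at the top of the exported table and in
blue in `autoplot()`.

fSAD voxel positions are taken on the inspiratory grid: classification
happens on the co-registered expiratory volume, which already lives there.

# Numerical and reproducibility notes

* Problem sizes: the reference phantom is 96³ voxels at 1 mm isotropic
  (lungs ≈ 88 cm³), the synthetic cohort 100 subjects; the full test suite
  and the acceptance script each run in a few minutes on one CPU at these
  sizes.
* Morphology uses 26-connectivity by default (6 selectable) everywhere;
  component labels are assigned in raster-scan order and the watershed
  processes equal depths first-in-first-out, so every labelling is
  deterministic.
* CPD solves its kernel system directly and retries once with a small ridge
  before raising a numeric error; the TPS interpolant carries a 1e−6 ridge.
* All randomness flows through one integer seed via named streams
  (`derive_seed`), including CV shuffles; `run_subject()` contains no
  randomness at all, so repeated runs are bit-identical.
* Intermediate artifacts are not cached across runs; determinism given
  (inputs, config, seed) plus the provenance JSON written next to every
  output set is the reproducibility mechanism.

# Known limitations

* Point-set registration cannot see featureless interior motion (above);
  intensity-based refinement is deliberately out of scope.
* The lobe partition is a single surface per lung (upper vs lower group),
  not a five-lobe segmentation.
* The severity map inherits the linear model's additivity assumption;
  cluster-size effects on FEV1/FVC% are plainly non-linear in reality,
  which is exactly why size scales enter as separate terms.
* DICOM ingestion is not provided; inputs are HU-calibrated NIfTI volumes.
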