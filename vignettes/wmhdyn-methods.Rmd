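---
title: "Dynamic WMH progression in halfway space: models, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic WMH progression in halfway space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhdyn)
```

# The measurement problem

Serial MRI studies of white matter hyperintensities (WMH) conventionally
report one number per subject, the net volume change between baseline and
follow-up. Net change conflates three distinct spatial processes — lesion
regression, lesion growth, and a persistent core — which can be large and
opposite-signed at the same time, so cohorts can show a near-zero "change"
while individual lesion systems are highly dynamic. `wmhdyn` measures the
three components separately by comparing the binary lesion masks voxel by
voxel in a shared subject-specific space.

Two sources of systematic error dominate this kind of measurement, and the
design of the package is essentially a response to them:

* **Interpolation asymmetry.** Resampling the baseline scan onto the
  follow-up grid (or vice versa) degrades one timepoint and not the other,
  biasing the overlap toward the unresampled mask. The package therefore
  works in a *halfway* (intermediate) space reached by applying half of
  the between-scan motion to each scan.
* **Central atrophy.** Ventricular enlargement, ubiquitous in aging and
  dementia, engulfs periventricular lesion tissue. Without correction
  those voxels score as lesion "shrinkage" when they are in fact
  ventricular CSF expansion.

# The model

## Rigid alignment and the halfway transform

Within-subject serial alignment uses a 6-DOF rigid transform
$T = (R, t)$ estimated by intensity-based registration
(`register_rigid()`): correlation ratio between the fixed image and the
trilinearly resampled moving image (64 intensity bins), a three-level
coarse-to-fine pyramid built by block averaging (factors 4, 2, 1), and
derivative-free Nelder–Mead optimisation over three rotations (degrees)
and three translations (mm), parameterised about the fixed field-of-view
centre and initialised from the intensity centroids. Normalised mutual
information is available as an alternative metric. The procedure is
deterministic; the seed in `registration_options()` is recorded with every
run and guards any future stochastic extension. If the simplex degenerates
before meeting the relative tolerance ($10^{-10}$) it is restarted from
the incumbent; a run that still fails raises a typed error carrying the
best transform found, rather than silently returning it.

The halfway decomposition (`halfway_decompose()`) is the exact rigid
square root, computed in axis–angle form rather than by a general matrix
logarithm: the rotation axis is kept and the angle halved,
$R_h = \mathrm{rot}(\hat{n}, \theta/2)$, and the half translation solves
$(I + R_h)\,t_h = t$, which makes $H \circ H = T$ hold to machine
precision. $I + R_h$ is singular only at $\theta = 180^\circ$, where the
square-root direction is genuinely ambiguous; such transforms are rejected
(serial same-subject scans are orders of magnitude below this). The
backward half is $H \circ T^{-1}$.

## The intermediate sampling grid

The halfway construction fixes the intermediate *space* but not its
sampling lattice. `wmhdyn` samples it on the *baseline lattice carried by the
forward half-transform*: same shape and voxel dimensions as baseline, with
the affine pre-composed with $H$. Two consequences motivated this choice:

* The forward half already places the baseline field of view midway
  between the two native fields of view, so no additional re-centering is
  needed.
* The baseline-to-intermediate resampling map becomes the identity on
  voxel indices. Baseline masks transfer with zero interpolation error,
  and in the degenerate identity case (both timepoints identical) the
  estimated motion is sub-voxel everywhere, nearest-neighbour transport
  reduces to the identity, and shrink and grow are *exactly* zero — a
  strong self-consistency anchor that a symmetric-but-rotated grid would
  blur into "approximately zero".

The cost is a mild asymmetry (the grid is baseline-lattice-aligned); the
scan-order symmetry results below show the effect on volumes is below 1%.

## Overlap decomposition and conservation

Masks are resampled nearest-neighbour only, so they remain strictly
binary, and the three compartments are pure set algebra on the
intermediate grid: shrink $= B \setminus F$, grow $= F \setminus B$,
stable $= B \cap F$. The conservation identities
$|{\rm stable}| + |{\rm shrink}| = |B|$ and
$|{\rm stable}| + |{\rm grow}| = |F|$ are exact by construction and are
asserted exactly (not within tolerance) in the tests. Trilinear
resampling of masks would yield fractional voxels and break these
identities; this is why the interpolation mode is not user-selectable for
masks.

## Ventricular-expansion correction

The correction region is the set of voxels whose ventricular membership
changed between the timepoints — the symmetric difference of the two
intermediate-space vCSF masks. When ventricles only enlarge (the
clinically relevant direction, and true by construction in the phantoms)
this equals the vCSF growth region, follow-up minus baseline. The
direction-free formulation was chosen deliberately: a one-sided "growth
region" makes the correction depend on which scan is called baseline, and
measurably breaks the shrink↔grow exchange under scan-order reversal by
exactly the engulfed volume. With the symmetric region, swapping the two
timepoints swaps shrink and grow exactly in lattice-aligned settings.

Engulfed WMH voxels are removed from *all* compartments (shrink, grow,
stable, and both timepoint masks), not only from shrink: the conservation
identities then continue to hold after correction. The removed volume is
reported separately (`vcsf_removed_cc`) so the correction is auditable —
whether engulfed periventricular WMH should count as a distinct
compartment is an open scientific question, and reporting it separately
lets users make either choice downstream.

## Net change in two spaces

Net change is reported twice: from native-space volumes
(follow-up − baseline, the conventional measure) and from the
intermediate-space decomposition (grow − shrink, after correction). The
two differ by interpolation effects and by the removed engulfed volume
(the post-correction spatial net exceeds the native net by exactly
`vcsf_removed_cc` in lattice-aligned settings); both are kept because
they answer different questions and neither convention is canonical.

# Tissue volumetrics

`volume_cc()` converts voxel counts with the affine determinant (not the
product of voxel dimensions), so sheared acquisition geometries are
measured correctly. TIC is the volume of the union of the supplied
tissue/CSF masks (overlaps counted once); BPF is
$(GM + WM + WMH)/TIC$. SVD burden splits at 3.5 cc of baseline WMH
(low strictly below, high at or above); the threshold is a
cohort-derived median split, so it is a parameter, not a constant.
Cohort tables report mean (SD) per group with the *population* SD
convention, chosen so that duplicating a cohort leaves the table
invariant. WMH change volumes are right-skewed, so the summary adds
$\log(v + 0.01\,\mathrm{cc})$ columns for shrink/grow/stable (the offset
admits zero-change subjects and is recorded in the output) and a
log-modulus transform $\mathrm{sgn}(v)\log(1 + |v|/0.01)$ for the signed
net change, which is continuous and odd. No inferential statistics are
computed; the emitted CSV is designed to feed standard tools.

# The synthetic phantom and what it does (and does not) show

`generate_phantom()` renders paired scenes on one generating lattice:
an ellipsoidal brain (semi-axes 40 × 44 × 30 mm) with a GM shell and WM
core, two ellipsoidal lateral ventricles (~12 cc combined), spherical
white-matter lesions, T1-like tissue intensities with WMH rendered
hyperintense to WM and CSF dark, and additive Gaussian noise (default SD
2% of the WM mean). The default lattice is 96 × 96 × 72 voxels at 1 mm
isotropic for fast tests; `phantom_spec_study()` provides an anisotropic
0.86 × 0.86 × 1.4 mm preset echoing a 1.5 T SPGR acquisition. The default
study conditions mirror a ~2-year serial dementia protocol: a few cc of
lesion load per subject with simultaneous shrinkage, growth, and a stable
core; ventricular semi-axes enlarged by 10% (~4 cc vCSF increase); and
small rigid inter-scan motion (degrees / few mm).

Three generator design choices matter for interpretation:

* **Exact truth volumes.** Lesions are realised as the target *number of
  lattice voxels* nearest the lesion centre within eligible white matter
  (nested for the two timepoints), so target volumes are hit to within
  one voxel and truth volumes are exact lattice counts, independent of
  any resampling. Follow-up ventricles are enlarged by scaling their
  semi-axes; baseline WMH voxels newly inside them are relabelled vCSF
  and tallied as `engulfed_cc` — reproducing the engulfment confound by
  construction.
* **Truth is measured on the undistorted lattice.** The follow-up native
  space is produced by resampling the follow-up scene through the true
  rigid motion (trilinear for images, nearest-neighbour for masks); all
  truth volumes are counted before that step.
* **Translation-only motion in the oracle suite.** Rounding a pure
  translation is an exact bijection of the integer lattice, so
  nearest-neighbour mask transport conserves voxel counts *exactly* under
  translational motion (away from half-voxel rounding ties). The
  oracle-validation suite (`default_phantom_suite()`) therefore uses
  translational inter-scan motion: with the true transform injected, any
  volume discrepancy isolates a logic defect in the overlap/correction
  machinery rather than interpolation noise, and the suite passes at
  zero error. Under rotations no such exactness exists for any
  interpolation scheme — nearest-neighbour transport fluctuates at mask
  boundaries by tens of voxels on ~10 cc masks — so rotational motion is
  assessed with *relative* tolerances in the 20-phantom full-recovery
  study (motion up to 5°/5 mm, 2% noise, lesion burden spanning the low
  to high SVD range), where median per-compartment errors are a few
  percent and registration errors ~0.04°/0.015 mm.

What passing phantoms does not show: the phantom has no cortical folding,
bias fields, partial-volume intensity mixing, segmentation error, or
non-rigid anatomy change. It validates the geometry and bookkeeping of
the pipeline — registration, the halfway construction, mask transport,
set algebra, and the correction — not the upstream segmentation, which
this package deliberately treats as input.

# Numerical choices and degenerate inputs

* Rotation matrices are re-orthonormalised by polar decomposition at
  construction, so long composition chains cannot drift.
* Masks must be exactly binary; nonzero non-unit values (255, label
  codes) are accepted only under an explicit `binarize` flag, with a
  warning reporting the number of recoded voxels.
* Out-of-field voxels resample to zero (background), for images and
  masks alike.
* Subjects with empty baseline WMH are processed normally (shrink =
  stable = 0); incident lesions appear entirely as growth.
* Grid mismatches error out naming both grids; pipeline stage failures
  are re-raised with the subject id and stage name attached.
* Problem sizes in the test and acceptance suites (96³-scale lattices,
  1000 random transforms, 20-phantom recovery study) were chosen so the
  full validation runs in minutes on a single core while keeping every
  mask comfortably above the resolution at which boundary effects would
  dominate the quantities under test.

# Known limitations

* Only rigid (6-DOF) alignment: no affine or diffeomorphic registration,
  no bias-field correction, no slice-to-volume handling.
* Periventricular vs deep WMH subdivision and lesion-level
  connected-component tracking are out of scope; compartments are global.
* The engulfment correction addresses ventricular *expansion*; WMH voxels
  inside stable ventricular CSF at both timepoints are assumed already
  excluded by the input segmentation.
* 4D series and DICOM ingestion are not supported; inputs are 3D NIfTI-1
  volumes with valid s-form/q-form affines.
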