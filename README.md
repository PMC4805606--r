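# wmhdyn — dynamic white matter hyperintensity progression volumetrics

White matter hyperintensities (WMH) are bright lesions in cerebral white
matter on T2/FLAIR MRI and a radiological hallmark of small vessel disease
(SVD). Serial studies usually summarise their evolution as a single net
volume change, `ΔWMH = V_followup − V_baseline`. That one number hides the
biology: lesions simultaneously shrink in some places, grow in others, and
persist in a stable core, and the opposing components largely cancel in the
net. `wmhdyn` implements a *spatial* progression analysis for serial
structural MRI that separates those components at the individual-subject
level, for imaging researchers studying aging, dementia, and vascular
co-pathology.

## Method

For each subject with baseline and follow-up T1 volumes plus binary WMH and
ventricular-CSF (vCSF) masks in their native spaces:

1. **Rigid registration.** The baseline T1 is registered to the follow-up
   T1 with a 6-DOF transform `T` (correlation-ratio metric, three-level
   multiresolution pyramid, derivative-free optimisation).
2. **Halfway decomposition.** `T` is split into its rigid square root:
   a forward half `H` with `H ∘ H = T` (same rotation axis, half the
   angle, translation solved exactly) and a backward half `H ∘ T⁻¹`.
   Each scan is moved only half-way, so interpolation burden is shared
   symmetrically and neither timepoint is privileged.
3. **Intermediate space.** Both scans and all masks are carried into this
   halfway ("intermediate") space; masks use nearest-neighbour transport
   and stay strictly binary.
4. **Overlap decomposition.** With baseline mask `B` and follow-up mask
   `F` on the intermediate grid:
   `shrink = B ∖ F`, `grow = F ∖ B`, `stable = B ∩ F`.
   By construction `|stable| + |shrink| = |B|` and
   `|stable| + |grow| = |F|`, exactly.
5. **Ventricular-expansion correction.** Enlarging ventricles can engulf
   periventricular WMH; those voxels would otherwise masquerade as lesion
   shrinkage. WMH voxels inside the region where ventricular membership
   changed between timepoints are masked out of every compartment and
   reported separately (`vcsf_removed_cc`), so central atrophy is not
   mistaken for lesion regression.

Supporting volumetrics: total intracranial capacity (TIC, union of all
supratentorial tissue and CSF masks), brain parenchymal fraction
`BPF = (GM + WM + WMH) / TIC`, SVD burden classification (low if baseline
WMH < 3.5 cc), and cohort mean (SD) tables with log-transformed change
volumes.

Because no study data ship with the package, validation rests on a built-in
synthetic longitudinal brain phantom: an ellipsoidal brain with GM shell,
WM core, enlarging lateral ventricles, spherical lesions realised to exact
target volumes, rigid inter-scan motion, and Gaussian noise — with every
shrink/grow/stable/engulfed volume known exactly on the generating lattice.

## Worked example

```r
library(wmhdyn)

# a synthetic subject: 96x96x72 lattice at 1 mm, four lesions, 10%
# ventricular semi-axis enlargement, 1.5/-1/2 deg + 2/-1.5/1 mm motion
ph <- generate_phantom(phantom_spec())
ph
#> <phantom_truth> 96x96x72 voxels; WMH 10.500 -> 10.218 cc
#>   (shrink 1.500, grow 1.691, stable 8.527, engulfed 0.473)

res <- run_subject(ph$baseline_t1, ph$followup_t1,
                   ph$baseline_wmh, ph$followup_wmh,
                   ph$baseline_vcsf, ph$followup_vcsf,
                   subject_id = "phantom-01")
res
#> <progression_result> phantom-01
#>   WMH baseline 10.5000 cc, follow-up 10.2210 cc, net -0.2790 cc
#>   shrink 1.5170, grow 1.7090, stable 8.5100, engulfed 0.4730 cc
```

The net change (−0.28 cc) would suggest a nearly static lesion load; the
spatial decomposition shows ~1.5 cc of regression and ~1.7 cc of growth
happening at the same time, plus 0.47 cc of baseline lesion engulfed by
ventricular enlargement — recovered here within ~1–2% of the generator's
ground truth (the registration itself is recovered to ~0.03° / 0.02 mm).

Batch processing and phantom generation are also available from the shell
via the script in `inst/exec/`:

```sh
wmhdyn phantom --out phantom01/ --seed 42
wmhdyn run --manifest subjects.csv --out results/ --seed 1
wmhdyn summarize --cohort results/cohort.csv
```

`subjects.csv` needs columns `subject_id`, `baseline_t1`, `followup_t1`,
`baseline_wmh`, `followup_wmh`, `baseline_vcsf`, `followup_vcsf` (NIfTI
paths, relative to the manifest) and optionally `isi_years`. Each run
writes per-subject transforms and masks, a cohort CSV, a provenance JSON,
and a log; completed subjects are skipped on re-run unless `--force`.

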