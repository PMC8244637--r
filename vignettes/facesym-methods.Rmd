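---
title: "Quantifying facial and brain asymmetry with dense surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial and brain asymmetry with dense surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

facesym measures how asymmetric a face is, whether that asymmetry differs
between cohort groups, and whether it can be predicted from hemispheric
asymmetries of regional brain measures. This vignette is the package's own
account of the methods: the models, the tunable parameters and their
defaults, the synthetic data the pipeline is validated on, and the numerical
and design choices behind the implementation.

## The shape model

Every analysis starts from landmarked 3D face surfaces: triangulated meshes
in millimetres (x lateral, y vertical, z depth) with 22 named anthropometric
landmarks (8 midline points and 7 left/right pairs; see
`canonical_landmark_names()`). Faces are first brought into a common frame
by rigid Procrustes alignment of the landmarks — rotation and translation
only, never scaling, so absolute lengths survive for anthropometry
(`procrustes_align()`).

A *dense correspondence* then re-expresses every face as the same ordered
set of M surface points: the base-mesh vertices are warped by a thin-plate
spline interpolating the 22 landmark pairs exactly, and each warped point is
projected to the closest point of the target mesh (`densify()`). Point i on
any corresponded face denotes the same anatomical location on every other
face. Warped points whose projection exceeds a distance cap (10x the
target's median edge length) keep their unprojected position and are
flagged; more than 5% of such points is treated as a correspondence failure.
The one-pass landmark-anchored scheme is deterministic and adequate for
desk-scale studies; the interface leaves room for iterative refinement
engines, which are deliberately out of scope.

The *dense surface model* (`fit_dsm()`) is a PCA of the corresponded shape
vectors: mean shape, orthonormal displacement modes sorted by decreasing
variance, and the smallest leading subset covering a target fraction of
total variance (default 0.99). The PCA is a plain SVD of the centred data
matrix with divisor n − 1; per-coordinate centring is used. Mode signs are
fixed (largest-magnitude coordinate positive) so that score correlations are
reproducible. When the training set contains every face *and its mirror
image*, the model mean is symmetric by construction — a property the test
suite checks to 1e-6 mm.

## Asymmetry: signatures, SAI, asymmetry PCs

The *signature* of a face against a reference population is the field of
per-point, per-axis differences from the matched-control mean, divided by
the matched-control standard deviation — coordinate z-scores
(`compute_signature()`). Its *weight*,

  w = sqrt( sum_i sum_axis z[i, axis]^2 ),

is a scalar summary of deviation from normality. Controls are matched on
gender and an age window of ±10 years, widened in 5-year steps until at
least 20 controls match; per-point SDs are floored at 0.01 mm so that
degenerate low-variance points cannot dominate. "Variation in controls" is
interpreted per axis (not per displacement magnitude) because the heat-map
visualizations are axis-wise; this interpretation is a documented choice,
not forced by the method's definition.

The *raw asymmetry* of a face is the difference between the DSM
representations (retained-mode reconstructions) of the face and of its
reflected, landmark-relabelled mirror image (`raw_asymmetry()`). Working in
the retained-mode representation, rather than subtracting raw meshes,
suppresses correspondence noise outside the model space. The *signature
asymmetry index* (SAI) scores this raw-asymmetry field as a signature
against the raw-asymmetry fields of matched controls and takes the natural
logarithm of the weight (`sai_cohort()`): the log weight is approximately
normal, and all cohort statistics run on that scale. A subject exactly at
the control mean field has weight 0; its SAI is undefined and the record is
flagged rather than imputed. A control subject is never matched against
itself when its own reference is built.

Shape modes that *encode* asymmetry are found through the reflection trick:
for a mode unaffected by mirroring, original and mirrored faces get the
same score; for an asymmetry-encoding mode the score flips sign. Across
subjects, the Pearson correlation between original-face and mirrored-face
scores is therefore near +1 for symmetric modes and near −1 for asymmetry
modes. `asymmetry_pcs()` computes this correlation per retained PC, sorts
ascending, and flags entries below a threshold (default −0.9). Zero-variance
PCs have undefined correlation and are excluded. Named anthropometric
constructs for the classic asymmetry modes (nose deflection, nose–mouth
rotation, eye depth, orbit–mouth displacement) are exposed through
`pc_asymmetry_measures()` together with the unitless lateral asymmetry
measure (R − L)/(R + L).

## Brain asymmetry

Regional brain measures arrive as a long table (subject, region, hemisphere,
measure kind, value) emulating FreeSurfer-style output, with per-subject
covariates (intracranial volume, age, sex, scanner). `adjust_measures()`
fits value ~ icv + age + sex + scanner per (region, hemisphere, measure) by
least squares and re-centres residuals at the covariate-mean fitted value,
keeping adjusted values on the original positive scale — necessary because
the asymmetry index divides by the left/right average. Adjustment precedes
asymmetry computation. `qc_outliers()` applies the ENIGMA-style rule:
within each region cell, values with |z| at or beyond 4.7 (inclusive,
either direction) are flagged for review and excluded downstream.

The brain asymmetry index of a paired region is

  BASI = (left − right) / ((left + right) / 2),

unitless, antisymmetric under hemisphere swap, and scale-invariant
(`compute_basi()`). `basi_table()` assembles the subject x region matrix
over a 51-pair region manifest (31 cortical thickness regions, 8
subcortical volumes, 12 hippocampal-subfield volumes). The atlas literature
does not pin down a unique 51-pair composition, so the packaged manifest is
an explicit, overridable choice. "Total average cortical thickness" BASI is
computed as the BASI of the hemispheric average thickness (the alternative —
the mean of regional BASIs — is exposed alongside as
`mean_regional_thickness_basi`). Pearson correlations of illness duration
with the thickness and area summary BASIs come from
`duration_correlations()`.

## Cohort statistics

`compare_sai_groups()` runs pairwise two-sample t-tests (Welch by default;
the pooled-variance test is an option and is the variant whose two-group
ANOVA-F identity the tests verify) plus a one-way ANOVA, with Bonferroni
correction multiplying pairwise p-values by the number of comparisons,
capped at 1. `sai_regression()` is OLS of SAI on age, gender and
epilepsy-type dummies with controls as the reference level, reporting
coefficients, SEs, t, p and 95% CIs; an optional univariate screen
(p < 0.05) can gate predictors into the multivariate model, since which
variables clear that gate is data-dependent. `discrimination_rates()`
estimates baseline separability of groups in retained PC space by
stratified k-fold cross-validation (default 10 folds) for three classifiers:
closest mean (native), linear-kernel SVM and LDA.

## The repeated LASSO protocol

`run_protocol()` predicts SAI from BASI features with L1-penalized *linear*
regression. The outcome is continuous and scored with MSE and Spearman
correlation, so a linear model is the coherent reading even though
regularized classification terminology is sometimes attached to this
protocol; the package states this choice openly. Features are normalized at
the dataset level — column mean subtracted, then divided by the centred
column's Euclidean norm (`normalize_features()`). Because normalization
precedes splitting, a mild train/test leak is inherent to the protocol; it
is reproduced deliberately and can be avoided by normalizing per split
upstream.

Each of the (default 1000) repetitions draws a fresh random 80/20
train/test split; 10-fold cross-validation on the training set selects the
penalty alpha from 13 consecutive powers of two, 2^-16 … 2^-4, and the
model is refit on the full training set at the chosen alpha; test-set
Spearman rho (exactly 0 for intercept-only or otherwise constant
predictions) and MSE are recorded, along with the nonzero-coefficient
feature set. Selection frequencies are simple percentages over repetitions.
One master seed spawns per-repetition streams, making the whole protocol
bit-reproducible. Lesion laterality (left −1, right +1, none 0) and
epilepsy-type dummies can be appended as clinical features
(`augment_features()`).

The CV selection criterion deserves care, and `run_protocol()` offers two.
The default, `cv_criterion = "mse"`, picks the alpha minimizing the mean
squared error of the pooled CV predictions, with ties broken toward the
larger (sparser) alpha. The alternative, `"correlation"`, maximizes the
Pearson correlation between CV predictions and the measured outcome, with
an alpha whose folds all fit the bare intercept assigned correlation 0 so
that a fully sparse model remains selectable. The two criteria diverge
sharply on weak data, for an instructive reason: correlation is blind to
calibration, and the CV predictions of overfit small-alpha models — though
terrible in squared error — still track whatever *sample-level* chance
correlations the fixed dataset happens to contain, because every fold of
every split shares them. Correlation-based selection therefore almost never
returns the intercept-only model (measured on null data with n = 100,
p = 51: ~1-12% of repetitions, with positively biased test rho), whereas
MSE-based selection charges overfit models for their variance and returns
the intercept-only model in the majority of null repetitions (~50-93%
across datasets, mean ≈ 2/3) with mean test rho near 0 — the protocol
behaviour this analysis family actually reports, where most repetitions of
a weak-signal model select nothing beyond the intercept. MSE is therefore
the default, and the same reasoning explains why a repeated-split protocol
on one fixed dataset can never be a fully unbiased null: its chance
correlations are shared between the training and test sides of every
split.

## The synthetic cohort generator

No clinical data ship with the package; every stage is validated on
synthetic cohorts whose statistical structure mirrors the study design the
pipeline targets.

`make_template()` builds an exactly symmetric face-like height-field mesh
(nasal ridge, eye sockets, brow, lips, chin) on an odd-column grid, with the
22 landmarks snapped to grid vertices at mirrored positions. Snapping means
simulated displacement fields move landmarks and vertices coherently; real
data need no such constraint. The grid is exact in vertex count whenever M
has an odd divisor near the natural aspect ratio (M = 2000 is the 25 x 80
grid), otherwise the nearest feasible grid is used.

`simulate_faces()` deforms the template by shared shape modes built from
smoothed random bump fields, symmetrized or antisymmetrized under
reflect-and-relabel so that symmetric modes are exactly invariant and
asymmetric modes exactly negate. Mode coefficients are Gaussian; each
group's asymmetric-mode SD is inflated by its delta (mm), so a positive
delta plants a group asymmetry effect. Defaults encode the study
conditions: cohort sizes at one third of the clinical cohort
(CTRL 68, FS 61, FC 48, IGE 17), ages uniform on 18-77, 55% female,
symmetric mode SDs (3, 2, 1) mm, asymmetric mode SDs (0.4, 0.25) mm,
delta_FS = 2 mm with all other deltas 0, sensor noise 0.2 mm per coordinate
(typical stereophotogrammetry repeatability, comfortably below the ~1.5 mm
landmark error bound reported for such systems), and a small random rigid
pose per face so the alignment step does real work. Epilepsy durations are
uniform within what the subject's age allows and can optionally be coupled
to the subject's asymmetry amplitude.

`simulate_brain()` generates strictly positive left/right measures for the
51 manifest regions plus two hemispheric summary regions. The planted
asymmetry of each region has SD 0.02 on the BASI scale; the thickness
summary carries a planted duration correlation (default −0.2, thinning with
longer illness); chosen regions can carry a planted link to the SAI at a
configured signal-to-noise ratio (the linked column's correlation with SAI
is sqrt(snr/(1+snr))). By default no SAI link is planted — facial and brain
asymmetry are uncoupled, which is the study's own null finding — and
recovery tests override this explicitly. Covariate effects (ICV, age, sex,
scanner) enter both hemispheres identically, so they perturb raw values but
cancel in the true asymmetry; the adjustment step is what removes them from
the measured values. Injected outliers are placed by solving for the value
whose *post-injection* cohort z-score equals the requested z.

What the generator does *not* emulate: real correspondence error from
varying mesh topology and expression, non-Gaussian shape variation, scanner
interactions beyond additive offsets, and any anatomical asymmetry
direction. Passing tests therefore demonstrate the pipeline's internal
correctness and statistical calibration under its own assumptions, not
clinical reproduction; the clinical cohort is not distributed, and its
effect sizes are not reproduction targets.

## Numerical choices and edge cases

* Thin-plate splines use the 3D polyharmonic kernel U(r) = r with an affine
  part; the bordered linear system is solved directly (22 anchors) and a
  singular system (coincident landmarks) is an explicit error.
* Closest-point projection is exact (region-based point-triangle tests) and
  accelerated by a uniform spatial grid over triangles; correctness is
  checked in tests against an independent plane-projection/edge-clamping
  oracle.
* `fit_dsm()` requires at least 3 surfaces and errors on exactly zero total
  variance; rank is cut at 1e-10 of the largest singular value.
* Welch is the default t-test variant; the pooled-variance option exists for
  the classical ANOVA identity.
* Degenerate LASSO repetitions (constant test predictions) record rho = 0
  with the intercept-only flag; constant feature columns are flagged and
  left centred with a unit divisor.
* Pearson is used for CV alpha selection (Spearman only for test scoring),
  with the convention and tie-break described above.

## Worked example

```{r example}
library(facesym)

study <- run_study(face_cfg = face_sim_config(seed = 1), lasso_reps = 200)

dplyr::group_by(study$sai, group) |>
  dplyr::summarise(mean_sai = mean(sai), sd_sai = sd(sai))
study$group_tests
tidy(study$regression)
study$asymmetry_pcs
study$duration_correlations
glance(study$lasso)
```

The problem sizes used throughout the examples and tests (template
resolutions of 600-2000 vertices, cohorts of tens to two hundred subjects,
100-200 protocol repetitions) are the package's choice of desk-scale study
conditions: large enough for every statistical property to be measurable,
small enough to iterate on.

## Known limitations

* The dense correspondence is one-pass landmark-anchored TPS + projection;
  it does not iterate toward a group-wise optimum and is not claimed
  equivalent to any particular historical DSM implementation.
* Whether control variation should be normalized per axis or per
  displacement magnitude is ambiguous in the method's verbal definition;
  per-axis is implemented and documented.
* The 51-pair BASI manifest is a package choice; analyses that depend on a
  specific atlas composition should supply their own manifest.
* The anatomical *direction* of cohort asymmetry is out of scope by design:
  the SAI quantifies magnitude, not side.
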