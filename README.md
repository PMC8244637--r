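# facesym

Quantitative analysis of **facial asymmetry** from landmarked 3D face
surfaces, and of its relation to **brain asymmetry** — for
morphometrists, neuroimaging researchers and statisticians studying
conditions (such as focal epilepsy) in which subtle lateralized
dysmorphism is hypothesized.

The package implements, end to end:

* **Dense surface models (DSM).** Faces are rigidly aligned on 22
  anthropometric landmarks (no scaling, so millimetre lengths survive),
  placed in dense point-wise correspondence with a base mesh via a
  landmark-anchored thin-plate-spline warp plus closest-point projection,
  and decomposed by PCA over originals *and their mirror images*, retaining
  enough modes to cover 99% of shape variance.
* **Signatures and the SAI.** A face's *signature* is its per-point
  displacement from the mean of age/gender-matched controls in units of the
  control SD; the *signature weight* is
  `w = sqrt( Σ_points Σ_axes z² )`. The *signature asymmetry index* is the
  natural log of the weight of the face's **raw asymmetry** — the difference
  between the DSM representations of the face and of its mirror — scored
  against matched controls' raw asymmetries:
  `SAI = ln w_asym`. Group statistics (Welch t-tests, ANOVA with
  Bonferroni correction, multivariate OLS with controls as reference) run
  on this log scale.
* **Asymmetry-encoding principal components.** A mode that encodes
  asymmetry has scores that flip sign under reflection, so the Pearson
  correlation between original-face and mirrored-face scores across
  subjects is near −1; `asymmetry_pcs()` builds the league table and flags
  entries below −0.9. Classic constructs (nose deflection, nose–mouth,
  eye depth, orbit–mouth) are measured as paired left/right distances with
  the unitless `(R − L)/(R + L)` asymmetry.
* **Brain asymmetry (BASI).** Regional measures (FreeSurfer-style long
  tables) are adjusted for ICV, age, sex and scanner by linear regression,
  QC'd by the |z| ≥ 4.7 outlier rule, and summarized per paired region as
  `BASI = (left − right) / ((left + right)/2)` over a documented 51-region
  manifest, with Pearson correlations of illness duration against the
  hemispheric thickness/area summary BASIs.
* **The repeated LASSO protocol.** SAI is predicted from the 51 BASI
  features (plus optional lesion laterality and epilepsy-type dummies):
  features are dataset-normalized (mean 0, Euclidean norm 1), and each of
  1000 repetitions draws a fresh 80/20 split, selects the L1 penalty from
  2^−16 … 2^−4 by 10-fold cross-validation, refits, and scores the test
  set by Spearman rho and MSE; per-feature selection frequencies summarize
  which regions drive the prediction.
* **A synthetic cohort generator** with planted effects (group asymmetry
  amplitudes, duration–thickness correlation, sparse BASI→SAI links,
  injected QC outliers), so the entire pipeline is testable without any
  clinical data.

## Worked example

```r
library(facesym)

# simulate, align, correspond, fit the DSM, score SAI, build BASI, run LASSO
study <- run_study(face_cfg = face_sim_config(seed = 1), lasso_reps = 200)

dplyr::group_by(study$sai, group) |>
  dplyr::summarise(mean_sai = mean(sai), sd_sai = sd(sai))
#> # A tibble: 4 x 3
#>   group mean_sai sd_sai
#>   <chr>    <dbl>  <dbl>
#> 1 CTRL      3.91  0.413
#> 2 FC        3.88  0.426
#> 3 FS        5.59  0.701
#> 4 IGE       4.04  0.364
```

The default configuration plants a 2 mm asymmetry amplitude in the FS
(focal symptomatic) group only: FS sits about 1.7 log-units above controls
(the Welch test in `study$group_tests` gives t ≈ 16.4,
p ≈ 2e−29 at n = 61 vs 68), while FC and IGE are indistinguishable from
controls — the planted structure, recovered. The asymmetry-PC league table
(`study$asymmetry_pcs`) flags the modes whose original/mirrored score
correlation is below −0.9: the two planted antisymmetric shape modes plus
the antisymmetric components of sensor noise, all with r ≈ −1.

On the brain side, `study$duration_correlations` recovers the planted
negative duration–thickness-asymmetry correlation
(r ≈ −0.15 at n = 126; planted −0.2 before sampling attenuation) and a
null area correlation. The repeated LASSO (`glance(study$lasso)`,
`tidy(study$lasso)`) tells a coherent story: by default no BASI→SAI link
is planted, so the brain regions carry no signal — but the appended
epilepsy-type dummy does (it encodes the planted FS facial effect) and is
selected in 100% of repetitions with mean test rho ≈ 0.68, while BASI
regions appear only at background rates. On BASI features alone with no
signal, the protocol returns intercept-only models in the large majority
of repetitions with mean rho ≈ 0 (the calibration arm of
`scripts/acceptance.R` measures exactly this), and with a planted
3-region link it ranks exactly those regions top.

Each result type has tidy accessors (`tidy()`, `glance()`) and plots
(`plot_sai_groups()`, `autoplot()` on models, heat maps and LASSO
results). Signature heat maps export as per-vertex CSV or colored PLY
(`write_heat_map()`). A thin CLI covers the two shell-level entry points:

```sh
Rscript scripts/facesym.R simulate --out sim/ --m 1000 --seed 1
Rscript scripts/facesym.R study --out results/ --seed 1 --reps 200
```

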