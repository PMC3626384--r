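# heliovent

Semiautomatic segmentation of ventilated airspaces in hyperpolarized-gas
(HP ³He) lung ventilation MRI, with quantification against manual
segmentation and spirometry, and a synthetic phantom generator for testing
the pipeline without clinical data.

## The problem and the method

HP ³He MRI shows where inhaled gas reaches in the lung: ventilated tissue is
bright, obstructed regions (ventilation defects, characteristic of asthma)
are dark. Reducing a stack of coronal slices to a **ventilated lung volume
(VLV)** requires separating signal from noise, deciding which faint signal
is negligible, and excluding the trachea and main-stem bronchi — anatomic
dead space that holds the densest gas but exchanges none. `heliovent`
implements the three-step pipeline:

1. **Statistical noise subtraction.** Background noise is sampled from an
   automated 25 × 50 pixel box at the bottom centre of each slice and fitted
   with an adjusted Rayleigh curve
   *r(f) = (αf + δ) e^−(αf+δ)²/2σ² / σ²*; an optimal integer threshold τ
   minimizes the error term ε_τ = Σ_{f<τ} g(f) + Σ_{f≥τ} r(f) with
   g(f) = r(f) − h(f), giving the initial binary mask.
2. **Fuzzy C-means ventilation clustering.** Masked intensities are
   partitioned into four classes (negligible, low, intermediate, high
   ventilation) with memberships u_ik = [Σ_j (D_ik/D_jk)^{2/(m−1)}]⁻¹,
   m = 2; the negligible class is returned to the background.
3. **Seeded region-growing airway removal.** From a user-chosen seed inside
   a bounding box, the Adams–Bischof rule repeatedly admits the frontier
   pixel closest to the region's running mean; the grown airway is
   subtracted, and a templated erosion → 50-pixel area filter → dilation
   (disk element, box of half-extents W/4 × H/2 about the mask centroid)
   removes weakly connected residue.

Quantification: VLV (pixels × voxel volume; 42.12 mm³ at 1.8 mm in-plane /
13 mm slices), Dice overlap 2|A∩B|/(|A|+|B|), Bland–Altman limits of
agreement (mean ± 1.96 SD), Pearson/OLS regression against FEV₁ and FVC,
paired and pooled t tests.

## Worked example

Generate a realistic phantom (known ground truth), run the pipeline, and
compare:

```r
library(heliovent)

fx  <- end_to_end_fixture("realistic", seed = 7)
res <- run_pipeline(fx$image, seeds = fx$seeds)
res
#> <pipeline_result>
#>   thresholds: 38 39 43 41 41 41 39 38 38 42
#>   cluster centres: 54.87, 100.2, 150.1, 210.2
#>   VLV: 4.405 L
#>   stage noise_subtraction: 0.02s
#>   stage ventilation_clustering: 0.43s
#>   stage airway_removal: 0.53s

dice_coefficient(res$mask, fx$truth)
#> [1] 0.999
```

The per-slice thresholds sit just above the sampled noise (background σ = 10
for this preset), the four cluster centres recover the phantom's class
levels (55, 100, 150, 210), and the final mask agrees with the ground truth
at Dice 0.999 with the airway fully removed. `res$vlv` holds per-slice
volumes in mL; `write_mask(res$mask, "final.nii.gz")` exports the result.

Subject-level agreement on the bundled ten-subject evaluation cohort:

```r
vlv <- study_vlv()
agreement_report(vlv$vlv_semi_L, vlv$vlv_manual_L, dice = vlv$dice)
#> <agreement_report> n=10
#>   Bland-Altman: mean diff -0.018 +/- 0.0704, LoA [-0.156, 0.12]
#>   regression: r=0.998 slope=0.963 p=8.24e-11
#>   paired t: t=-0.809 p=0.439
#>   Dice: 0.961 +/- 0.006
```

The semiautomatic and manual VLVs differ by −18 mL on average (not
significant, p = 0.44) with a mean Dice of 0.96.

A thin command-line front end ships at `inst/cli/heliovent`
(subcommands `run`, `phantom`, `fit-noise`; YAML config via
`read_pipeline_config()`).

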