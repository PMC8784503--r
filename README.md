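# cardpet

Quantification of left-ventricular myocardial glucose metabolism from
[18F]FDG PET/CT, for monitoring chemotherapy-related cardiotoxicity.

Anthracycline regimens (R-CHOP, ABVD and relatives) can injure the
myocardium, and metabolic changes on FDG PET precede functional decline.
Lymphoma patients already undergo staging, interim and end-of-treatment
(EOT) PET/CT scans, so those scans can be mined for cardiac metabolism at
no extra dose. cardpet implements the full image-processing chain from a
PET/CT study to an AHA 17-segment polar map and scalar LV metrics, plus
the longitudinal statistics to compare the three scans.

**Pipeline:** activity → body-weight SUV
(`SUV = C / (D·2^(−Δt/T½) / 1000·w)`) → Anscombe variance-stabilized
Poisson denoising → CT-based LV localization (always manually overridable)
→ ellipsoidal VOI (excludes para-cardiac tumour masses) → two-step
reorientation to the cardiac axes (HLA, then VLA; automatic principal-axis
initializer) → per-slice Otsu myocardial masks → radial maximum-SUV ring
extraction (1° rays, sub-pixel bilinear sampling, per-slice centre
recalculation) → Michigan-style polar map (equal septal/lateral basal
limits, apex-cap ray fill) → AHA-17 segmental SUVmean/SUVmax.

**Metrics:** global SUVmean (count-weighted, apex excluded), septal
(segments 2,3,8,9) and lateral (5,6,11,12) SUVmax, vascular-territory
ratios LAD/LCX and RCA/LCX (percent), and the **septal–lateral uptake
ratio**

SLUR = 100 · SUVmean(septal 2,3,8,9) / SUVmean(lateral 5,6,11,12) [%],

whose literature-normal value is about 80% (the healthy septum takes up
~20% less FDG than the lateral wall).

**Cohort statistics:** Friedman rank test across the three stages (tie
corrected, optional exact permutation p), Wilcoxon signed-rank post-hoc
pairs with Bonferroni adjustment, point-biserial correlations per scan
transition, and mean ± SD tables per regimen and combined.

Because no patient images can ship with the package, a first-class
synthetic phantom module (`phantom_spec()` / `generate_phantom()`)
produces PET+CT volumes of an ellipsoidal LV shell with analytic ground
truth (per-wall or per-segment uptake multipliers, blood pool, lungs,
optional tumour sphere, Poisson noise, arbitrary initial rotation) at the
clinical acquisition geometry (168×168 matrix, 4.0728 mm voxels, 5 mm
slices).

## Worked example

```r
library(cardpet)

# A phantom whose septum takes up 20% less than the lateral wall,
# with Poisson noise at 50 counts per SUV unit:
ph  <- generate_phantom(phantom_spec(matrix_size = c(96, 96), n_slices = 36,
                                     septal = 0.8, noise_scale = 50, seed = 1))
res <- process_scan(ph$pet, ph$ct)
round(res$metrics[, c("global_suvmean", "septal_suvmax", "lateral_suvmax",
                      "lad_lcx_pct", "rca_lcx_pct", "slur_pct")], 2)
#>   global_suvmean septal_suvmax lateral_suvmax lad_lcx_pct rca_lcx_pct slur_pct
#> 1           4.44          4.69           5.34       91.48       92.08    81.32
```

The recovered SLUR (81.3%) matches the phantom's ground truth of 80%
within the method's phantom-validated tolerance; the territory ratios sit
below 100% because the septal segments belong to the LAD and RCA
territories. `res$polar_map` holds the bullseye (`plot_polar_map()` renders
it; `export_polar_map()` writes a tidy CSV), `res$segments` the 17-segment
table, and `res$provenance` a log of every default and override that
influenced the numbers.

Longitudinal analysis over a cohort of per-scan metric rows
(`patient_id`, `regimen`, `stage` ∈ staging/interim/eot, metrics):

```r
rep <- run_cohort(records, metrics = c("slur_pct", "lad_lcx_pct"))
rep$tests          # Friedman chi-square and p per group x metric
rep$posthoc        # Bonferroni-adjusted signed-rank pairs
rep$correlations   # point-biserial r per scan transition
```

A thin command-line front end with subcommands `process`, `phantom`,
`cohort` and `demo` lives at `inst/cli/cardpet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cardpet.R", package = "cardpet"))')" \
    phantom --septal 0.8 --noise 50 --seed 42 --out phantom_dir
```

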