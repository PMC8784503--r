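---
title: "Quantifying myocardial FDG uptake with cardpet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial FDG uptake with cardpet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anthracycline chemotherapy can damage the myocardium, and metabolic
alterations visible in [18F]FDG PET precede functional decline. Lymphoma
patients already receive staging, interim and end-of-treatment (EOT) PET/CT
scans as part of response monitoring, so those scans are an opportunity to
quantify myocardial glucose metabolism at no extra cost or dose. cardpet
turns a PET/CT study into an AHA 17-segment polar map of left-ventricular
(LV) SUV, and from it a handful of scalar metrics: the global myocardial
SUVmean, septal and lateral regional SUVmax, vascular-territory uptake
ratios (LAD/LCX, RCA/LCX) and the septal–lateral uptake ratio (SLUR).
Healthy myocardium shows roughly 20% lower septal than lateral uptake, so a
SLUR near 80% is the literature-normal reference point; departures from
that pattern, tracked over the three scans, are the quantity of interest.

```{r, eval = FALSE}
library(cardpet)
ph  <- generate_phantom(phantom_spec(septal = 0.8, noise_scale = 50))
res <- process_scan(ph$pet, ph$ct)
res$metrics$slur_pct
```

## Pipeline and models

**SUV.** Activity concentration (Bq/mL) is converted to body-weight SUV,
`SUV = C / (D * 2^(-dt/T_half) / (1000 * w))`, with injected dose `D` (Bq)
decay-corrected over the uptake interval `dt` (s), patient weight `w` (kg),
F-18 half-life 6586.2 s, and the standard 1 g/mL tissue-density convention.
Which reference time the scanner vendor used for decay correction is rarely
recorded; cardpet declares decay correction *to acquisition start* and
documents it rather than guessing per scan. Input is NIfTI plus a JSON
sidecar holding the acquisition metadata; a missing field is a hard error
naming the field, because silently defaulting any of them corrupts every
downstream number.

**Denoising.** PET noise is Poisson. The Anscombe transform
`f(x) = 2*sqrt(x + 3/8)` makes it approximately unit-variance Gaussian, so
the filter is: transform, Gaussian smoothing at a physical scale, algebraic
inverse with a non-negativity clamp. The smoothing scale defaults to
**2 mm** (sigma; FWHM about 4.7 mm, comparable to scanner PSF). We
originally considered a heavier 6 mm default, but on phantoms with known
septal contrast it biases SLUR upward by about +6 points through angular
blending along the myocardial ring, while 2 mm keeps the bias under 2
points and still halves voxelwise noise variance; heavier smoothing is
available via `smoothing_mm` when count density is very low.

**Localization.** The LV is found from the co-registered CT by a
deliberately simple heuristic: threshold air below −400 HU, label 2-D
components per slice, discard border-connected ambient air, and collect
soft-tissue voxels lying medially between two lung fields; their centroid
seeds the VOI. CT localization of the heart is genuinely hard in
pathological anatomy, so the result is *advisory*: every entry point
accepts a manual `center` override, mirroring clinical practice where the
operator corrects the localization before segmentation.

**VOI.** An ellipsoid (not a box) bounds the LV, because it matches the LV
shape and excludes para-cardiac hot structures — notably tumour masses in a
lymphoma population — from everything downstream. Voxels outside the
ellipsoid are *marked excluded*, not zeroed, so exclusion is
distinguishable from true zero uptake.

**Reorientation.** The LV is rotated to the standard cardiac axes in two
steps — about the horizontal long axis until the septum is vertical, then
about the vertical long axis until the inferior wall is horizontal — after
which short-axis slices are the axial planes. The two angles can be given
explicitly (the analogue of drawing auxiliary lines on screen) or estimated
automatically: the principal axis (PCA) of the myocardium-like voxels is
aligned with z. Myocardium-like means reaching 40% of the volume's
99th-percentile uptake; an Otsu split is *not* used here because a severe
regional defect (e.g. an apical half-intensity region) would be dropped,
leaving an open tube whose principal axis is transverse, not longitudinal.
Resampling is mask-weighted trilinear onto an isotropic grid at the finest
input spacing (nearest-neighbour for the exclusion mask).

**Ring extraction.** On each short-axis slice a myocardial mask is taken by
Otsu's method over the VOI-restricted histogram, and the wall is sampled by
casting a ray per integer degree (0–359) from the slice centre, recording
the maximum-SUV sample within the masked radial support. Sampling is
bilinear at 0.5-pixel steps; ties break toward the smaller radius so an
adjacent hot structure further out cannot capture a ray. The centre is then
recalculated once per slice as the centroid of the 360 maximizing points
and propagated to the next slice (the apex slice starts from the mask
centroid). Manual per-slice masks (`override_mask`) replace the automatic
one for the three classic failure modes: tumour tissue adjacent to the
wall, uptake too low for Otsu to separate from blood pool, and segmented
papillary muscles.

**Slice admission and basal limit.** Per-slice Otsu will happily "find"
structure in a slice containing only background, so a slice enters the map
only if at least 8 VOI voxels reach 40% of the volume's near-maximum
uptake — blood pool sits near 30% of myocardium in FDG studies, while even
a half-intensity defect sits at 50%. Within the admitted range, the first
and last rings are the first and last slices with nonzero mask elements.
The basal limit is then tightened twice: (1) rings stop at the first slice
where either the septal or the lateral wall opens, so both walls end on
the same slice (the septum anatomically extends further basally); (2)
trailing rings whose median sample falls below 75% of the best ring's
median are discarded as partial-volume remnants of the open base — the
same count-threshold idea perfusion polar-map software uses for the valve
plane.

**Polar map and apex.** Ring k of K occupies normalized radius
`(A + k - 0.5) / (A + K)`, where `A = round(K/3)` apex-cap bins fill the
map centre (placing the cap boundary at one quarter of the map radius, the
conventional bullseye layout). The cap is sampled by rays fanning from a
point on the long axis one voxel inside the cavity, from straight-down
(the tip) to in-plane, taking the masked maximum per ray — so the tip value
is a transmural maximum rather than the partial-volume-suppressed tip
voxel. Ring values are sampled from the *source* volume through the
composed rigid transform (one interpolation stage); resampling the rotated
volume and then interpolating it again was measured to dilute segment
means by several percent. Zones are thirds of the apex-to-base extent;
angular origin is the anterior wall, increasing toward the septum, giving
the standard AHA numbering (basal/mid: 6 x 60 degrees; apical: 4 x 90
degrees; segment 17 = apex disc). Degrees with no masked support are
invalid cells and are excluded from all statistics, never zero-filled.

**Metrics.** Global SUVmean is the count-weighted mean over segments 1–16
(the apex is excluded because its construction differs). Septal SUVmax is
the maximum over segments {2,3,8,9}, lateral over {5,6,11,12}. Territory
values are count-weighted means of segmental SUVmean over LAD =
{1,2,7,8,13,14,17}, RCA = {3,4,9,10,15}, LCX = {5,6,11,12,16}; ratios are
reported in percent. SUVmean (not SUVmax) is the default territory metric,
consistent with SLUR's definition; a `territory_metric = "max"` switch
exists. The apex is assigned to LAD by default (`apex_in_lad = TRUE`, the
standard AHA map) but can be excluded: at 4 mm voxels the dome tip cannot
carry a well-defined *angular* territory assignment, so validation of
territory recovery is done with the apex excluded. SLUR is
`100 * weighted mean SUVmean(septal) / weighted mean SUVmean(lateral)`;
whether the septal/lateral means should be count-weighted or plain segment
averages is undocumented in common practice — cardpet uses count-weighted
throughout for internal consistency (with equal-width sectors the two
differ only through invalid cells).

**Cohort statistics.** Longitudinal change across staging/interim/EOT is
tested per metric with the Friedman rank test (mid-ranks, Conover tie
correction; chi-square p with k−1 df, or an exact within-row permutation p
built by column-sum convolution for small n). Post-hoc pairs use the
Wilcoxon signed-rank test — the standard paired companion to Friedman;
the original analysis does not name its pairwise test, so this is a
declared choice — with exact sign-flip distributions up to m = 50 and
Bonferroni factor 3. Directionality is summarized by the point-biserial
correlation between metric values and a 0/1 stage coding (later scan = 1,
so positive r means the metric rose). Summaries are mean ± sample SD per
metric, stage, and regimen group plus a combined group.

## The phantom: what it emulates, and what it does not

No patient images accompany this method, so validation rests on a
synthetic phantom with analytic ground truth. It is a half-ellipsoidal
myocardial shell (outer semi-axes 30 x 30 x 55 mm, wall 11 mm, open base
cut at 0.35 of the long semi-axis — a normal-sized LV), blood pool (SUV
1.5) filling the cavity, soft-tissue body background (SUV 0.5), two
air-density lungs flanking the heart in the CT, an optional para-cardiac
hot sphere, optional Poisson count noise (`noise_scale` counts per SUV
unit; 50 corresponds to a reasonably counted clinical frame), and an
arbitrary initial rotation applied analytically (voxels are classified in
the rotated frame, so no resampling error enters the ground truth). Wall
sector multipliers use exactly the polar-map angular conventions (anterior
60, septal 120, inferior 60, lateral 120 degrees), making true SLUR =
`100 * septal/lateral` by construction; per-segment multipliers are also
supported, with zone thirds matching the map. The grid default is the
clinical acquisition geometry (168 x 168 matrix, 4.0728 mm in-plane, 5 mm
slices); tests and the acceptance script use a 96 x 96 x 36 cardiac-centred
crop of the same geometry to keep runtimes reasonable.

What the phantom does **not** emulate: scanner PSF and reconstruction
artifacts, respiratory/cardiac motion, papillary muscles, anatomical wall
thickness variation, spillover from adjacent organs (liver, stomach), and
realistic CT texture. Passing phantom tests therefore demonstrates the
correctness of the geometry, sampling, segmentation and statistics — not
robustness to everything clinical data can present; the manual-override
pathways exist precisely because real data will sometimes defeat the
automatic steps.

## Numerical choices and degenerate inputs

* Radial sampling step 0.5 px; tie-break toward the smaller radius.
* Trilinear interpolation for values (mask-weighted so excluded voxels do
  not dilute edges), nearest-neighbour for masks; isotropic target grid at
  the finest input spacing.
* Otsu thresholds computed on 256-bin histograms of the VOI-restricted
  values (via EBImage); constant slices are an error, which is the signal
  to supply a manual mask.
* Apex side detection compares the mask spread (mean distance from the
  mask centroid) of the two end slices: the apical cap is compact, the
  open base is a wide annulus.
* Rays with no masked support yield invalid cells; segments left with zero
  valid cells are flagged `NA`, never zero, and metrics that need them
  error with the segment id.
* All-tied Friedman rows give Q = 0, p = 1; all-zero signed-rank
  differences give p = 1 with a `degenerate` flag.
* Validation problem sizes: phantom pipeline checks at 96 x 96 x 36; the
  Friedman null calibration uses 2000 replicates of a 24-patient cohort;
  the sign-pattern check uses 100 replicates.

## Synthetic cohort generator

`simulate_cohort()` draws patient baselines N(80, 8^2) with independent
per-scan noise N(0, 5^2) — a combined cross-sectional spread of about 9.4
points around the literature-normal SLUR of 80% — and applies
multiplicative stage effects (`c(1, 1, 1)` is the null). The interim
uplift scenario uses `c(1, 1.25, 1)`, a 25% transient rise, which
reproduces the qualitative longitudinal signature of interest: positive
staging-to-interim and negative interim-to-EOT point-biserial
correlations.

## Known limitations

* Ingestion is NIfTI + JSON sidecar; DICOM series must be converted
  upstream (e.g. dcm2niix), as is common in research pipelines.
* The basal count-threshold stop (75%) can trim genuinely hypometabolic
  basal rings in severe basal disease; the manual mask path is the
  fallback.
* The apex cap construction is one of several reasonable conventions; its
  absolute segment-17 value depends on it, which is another reason the
  apex is excluded from the global mean and (optionally) from LAD.
* Ring centre recalculation is a single pass per slice; a pathologically
  eccentric starting centre converges over slices rather than instantly.
* The CT localizer assumes two lung fields flank the heart; post-surgical
  or single-lung anatomy requires a manual centre.
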