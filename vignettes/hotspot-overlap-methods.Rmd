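---
title: "Multimodal hotspot overlap in glioma imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal hotspot overlap in glioma imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliohotspot)
```

## The analysis model

`gliohotspot` operates on three co-registered 3D parameter maps of a glioma
patient — APTw (amide proton transfer–weighted MRI, in % magnetization-
transfer asymmetry), FET PET activity, and DSC-perfusion CBV — together
with binary masks of the two standard tumor compartments: contrast-
enhancing tumor (CET) and FLAIR-hyperintense tumor (FHT), constructed to be
mutually exclusive (FHT excludes every CET voxel, and an optional
necrosis/cyst mask is removed from both; `prepare_compartments()`).

The pipeline assumes the inputs are already spatially aligned. Rigid or
deformable registration is deliberately out of scope — it is an upstream,
well-solved step — and the package only verifies grid compatibility
(affines equal element-wise within 10⁻³ mm) and offers explicit resampling
onto a common grid (`resample_to_grid()`). A 2 mm isotropic analysis grid
is the convention the defaults are built around.

Three voxelwise quantities are thresholded:

| map  | thresholdable quantity | cutoff | units |
|------|------------------------|--------|-------|
| APTw | the map itself         | > 1.79 | % asymmetry |
| FET  | TBR = SUV / background mean | > 1.6 | ratio |
| CBV  | rCBV, white matter scaled to 2.5 | > 5.6 | % blood volume |

All comparisons are strictly greater-than; a voxel exactly at the cutoff is
not a hotspot voxel. The cutoffs are literature conventions for vital-tumor
delineation, not fitted parameters, and are held in a `cutoff_set()` object
so a study can substitute its own.

Per compartment and modality the package reports the hotspot voxel count,
absolute volume (count × voxel volume, mm³) and relative volume (fraction
of the compartment), and per modality pair the Dice overlap
D = 2|X∩Y|/(|X|+|Y|). Additionally, APTw and CBV are summarised inside the
FET-positive and FET-negative portions of each compartment (median and
25th/75th percentiles with linear interpolation) with a two-sided Wilcoxon
rank-sum comparison of the two voxel-value samples.

## Normalization choices

**SUV.** `compute_suv_scale()` multiplies a decay-corrected activity
concentration (Bq/mL) by body weight in grams over injected activity (Bq),
the conventional 1 g/mL density assumption. Decay correction itself is
assumed done by the scanner pipeline.

**TBR.** The background reference is the arithmetic mean of a contralateral
gray/white-matter ROI (`background_reference()`; the median is available
for contaminated ROIs, and a minimum ROI size of 10 voxels is enforced).
When separate GM and WM ROIs are supplied they are averaged with equal
weight — the placement convention says only that both tissues contribute.

**rCBV.** Two readings of the 5.6 cutoff circulate: a plain ratio to the WM
mean, or an absolute percent scale on which healthy WM is set to 2.5 %. The
package defaults to the absolute-percent mode (`rcbv_map(mode =
"absolute_percent")`): on that scale typical FHT values sit near 2–3 and
enhancing-tumor values near 5–9, which is the regime in which a 5.6 cutoff
(≈ 2.24 × WM) produces plausibly sized perfusion hotspots; a ratio cutoff
of 5.6 × WM would be far stricter. The ratio mode remains one argument
away, because the underlying convention is genuinely ambiguous in the
literature.

Both ratio maps are scale-invariant: multiplying the raw map and its
reference ROI values by any k > 0 leaves TBR/rCBV, and everything
downstream of them, unchanged.

## Statistics

`rank_sum_test()` applies a fixed policy on top of the standard Wilcoxon
rank-sum machinery: exact enumeration of the rank-sum distribution when the
combined sample size is ≤ 20 and the pooled values are untied, otherwise
the normal approximation with tie and continuity correction. Fully tied
pooled data (zero rank variance) are reported as p = 1, since every rank
assignment is then equivalent. Tests are two-sided throughout, and no
multiplicity correction is applied by default, so that individual p-values
remain interpretable per comparison; the caller can adjust with
`p.adjust()` if desired.

`spearman_cor()` computes rho as the Pearson correlation of midranks. For
n < 10 the two-sided p-value is an exact permutation enumeration over all
n! assignments; from n = 10 the t approximation
t = rho·√((n−2)/(1−rho²)) on n − 2 df is used. Zero rank variance leaves
rho undefined (reported missing rather than 0).

Dice of two empty masks is likewise reported missing, not 1: in this
pipeline emptiness signals a degenerate compartment (e.g. a non-enhancing
tumor), and claiming perfect overlap there would silently distort cohort
medians. Empty compartments are skipped entirely, which is also how
non-enhancing lower-grade cases are handled: only their FHT is analyzed.

## The phantom generator

`phantom_spec()` describes a piecewise-constant digital tumor: a CET
ellipsoid strictly inside an FHT ellipsoid (the FHT compartment is the
shell between them), one hotspot sub-ellipsoid per modality whose intensity
delta is added to the compartment baseline, additive Gaussian noise per
modality (Rician available for PET-like magnitude data), and a spherical
background ROI in "contralateral" tissue. Ellipsoid membership is decided
by the voxel-center coordinate (quadratic form ≤ 1) with no partial-volume
weighting, matching the discrete mask arithmetic of the analysis.

The defaults are one fixed, documented condition set rather than dials:

- 64³ voxels at 2 mm (128 mm field of view), tumor centered at the origin;
- CET semi-axes 20/17/14 mm inside FHT 38/33/28 mm (FHT volume ≈ 1.3·10⁵
  mm³, the order of magnitude of a large glioblastoma FLAIR envelope);
- concentric nested hotspots offset 10 mm from the tumor center so each
  straddles the CET/FHT boundary: APTw 28/24/20 ⊃ FET 23/20/17 ⊃ CBV
  18/15/13 mm. With the baselines (APTw 3.0 in CET, 1.5 in FHT, 0.5
  outside; FET-TBR 1.4/1.2/1.0; rCBV 4.5/2.2/2.5 %) this reproduces the
  qualitative fingerprint of multiparametric glioblastoma data: the entire
  CET is APTw-positive, FET and CBV cover roughly 0.8 and 0.5 of it, the
  APTw/FET Dice (≈ 0.89 in CET) exceeds APTw/CBV, and FHT hotspot
  fractions are smaller throughout;
- noise SDs 0.2 (APTw %), 0.08 (TBR units), 0.3 (rCBV %), roughly a tenth
  of the respective hotspot contrasts;
- raw FET and CBV maps are the pattern times 2.0 (background SUV) and 1.7
  (raw units per %), so the normalization stage has real work to undo.

`phantom_truth()` enumerates the ground truth — compartment sizes, hotspot
counts/volumes/relative volumes, pairwise Dice — directly from the spec by
an independent voxel-coordinate sweep that shares no code with either the
rendering or the analysis path. On noiseless phantoms the pipeline must
reproduce these numbers *exactly* (bit-identical ratios), which is the
backbone of the test suite.

### Biopsy emulation

`generate_biopsies()` places sites uniformly over CET ∪ FHT and reads the
local imaging context as the median of the noiseless map inside the 1-cm
spherical VOI at the site — the same support a real biopsy's imaging
correlate has. Histology is then generated through monotone links:

- cellularity (cells per ¼ high-power field, mean of three counted
  regions) ~ negative binomial with log-mean linear in local APTw
  (`cell_base` 80 at APTw 2.0, `cell_slope` 0.45 per %-unit). The
  dispersion default (`cell_size` 0.4) is strongly overdispersed so that
  the population Spearman correlation between VOI-median APTw and
  cellularity lands near 0.36 — the weak-to-moderate regime reported for
  real stereotactic biopsy series, where histology varies far more than
  imaging predicts. `cell_size = Inf` gives deterministic counts, for
  which recovered rho is exactly 1;
- vascularity (ordinal 0/1/2) ~ ordered logit on local rCBV with
  cutpoints 3.5 and 6.5 % and slope 1.0, so high grades concentrate where
  perfusion hotspots are.

`biopsy_rho_target()` estimates the population rho implied by a phantom and
effect spec from one large Monte-Carlo draw (default 2·10⁵ sites) through
the generative link; replicate simulations must recover it within
Monte-Carlo error, which is verified over 500 replicates of n = 200 in the
test suite.

### What the phantom does not emulate

Piecewise-constant compartments plus i.i.d. noise contain no intratumoral
texture, no gradual infiltration gradients, no partial-volume mixing at
boundaries, no spatially correlated noise, and no registration error.
Passing the phantom suite therefore certifies the *arithmetic* of the
pipeline — thresholding, set algebra, normalization, VOI extraction,
statistics — not the biological realism of any particular cutoff. Likewise
the phantom's CET is APTw-enriched in its FET-positive part by
construction; in real enhancing tumor the two modalities can be so
congruent that no within-CET difference is detectable.

## Numerical conventions and degenerate inputs

- Voxel indices are 0-based against the NIfTI affine; all world
  coordinates are in mm, volumes in mm³. Masks are strictly {0,1}; values
  > 0.5 are mapped to 1 on load to guard against interpolated masks.
- Map resampling is trilinear, mask resampling nearest-neighbor; reference
  voxels outside the source field of view become NA (maps) or 0 (masks),
  and fully disjoint fields of view are an error.
- Non-finite map voxels (e.g. outside the PET field of view) never enter a
  hotspot and are dropped from subregion statistics; their count is kept
  as a QC attribute rather than silently discarded.
- Empty compartment → relative volume and subregion statistics reported
  missing (never 0); empty `within` mask → empty hotspot plus warning.
- The 1-cm VOI uses the voxel-center-in-sphere rule (≤ radius), making the
  voxel set translation-invariant on the lattice; an optional dilation
  (up to the ~3 mm stereotactic accuracy) absorbs targeting error.

## Problem sizes

The default phantom is 64³ voxels; brute-force oracles in the tests run on
≤ 32³ grids, the ground-truth recovery sweep uses 25 varied noiseless
phantoms, the rank-sum size check 10⁴ null simulations at n = 15 + 15, and
the biopsy-effect recovery 500 replicates of 200 biopsies against a 10⁶-
draw Monte-Carlo target. These sizes keep the full suite under a minute on
one core while leaving every estimate's Monte-Carlo error well below the
tolerances being checked.

## Known limitations

- The rCBV cutoff convention (ratio vs absolute percent) is ambiguous in
  the field; the default follows the absolute-percent reading and is
  configurable.
- VOI extraction offers median (default) and mean; published biopsy series
  rarely state which was used, so cross-study comparisons should fix this
  explicitly.
- Between-cohort comparisons operate on patient-level summary values;
  voxel-level p-values within a patient ignore spatial autocorrelation and
  should be read as descriptive, not as independent-sample inference.
- The phantom cannot certify cutoff validity on real data; it certifies
  the pipeline that applies them.
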