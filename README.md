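# gliohotspot

Gliomas are spatially heterogeneous, and three quantitative imaging
modalities each claim to mark the "active" part of the tumor: amide proton
transfer–weighted MRI (APTw, sensitive to mobile protein content and hence
cellularity), O-(2-[¹⁸F]fluoroethyl)-L-tyrosine PET (FET, amino-acid
uptake), and DSC-perfusion cerebral blood volume (CBV, neovascularization).
`gliohotspot` quantifies how well the hotspots delineated by these
modalities actually agree in space, separately within the two standard tumor
compartments — contrast-enhancing tumor (CET) and the mutually exclusive
FLAIR-hyperintense tumor (FHT) — and relates the imaging values to
histology from stereotactic biopsies. It is aimed at neuro-imaging
researchers running multiparametric glioma protocols.

## What it computes

For co-registered maps on a common grid, hotspots are defined by fixed
cutoffs with strict inequality:

- APTw > 1.79 (% asymmetry),
- FET tumor-to-background ratio TBR > 1.6, with TBR = SUV / mean SUV of a
  contralateral gray/white-matter ROI,
- rCBV > 5.6, on the scale where the CBV map is normalized so that
  contralateral normal white matter equals 2.5 %.

Within each compartment *C* the package reports the hot-spot volume
HSV = |H| · v (mm³, with v the voxel volume), the relative hotspot volume
|H| / |C|, and for each modality pair the Dice overlap

    D(X, Y) = 2 |X ∩ Y| / (|X| + |Y|)  ∈ [0, 1].

It further summarises APTw and CBV inside FET-positive vs FET-negative
portions of each compartment (median, IQR, two-sided Wilcoxon rank-sum p),
and correlates 1-cm spherical-VOI medians at biopsy coordinates with
cellularity (Spearman, midrank ties) and neovascularization grade (0/1/2).

Because the underlying patient data are not public, the package ships a
synthetic multiparametric phantom generator (`phantom_spec()`,
`generate_phantom()`) with exhaustively enumerated ground truth — hotspot
voxel counts, volumes, Dice scores, and biopsy-level effect sizes — so that
every stage of the pipeline is verifiable end to end.

## Worked example

```r
library(gliohotspot)

ph <- generate_phantom(phantom_spec(), seed = 7)   # synthetic GB-like patient
bg_fet <- background_reference(ph$maps$fet, ph$masks$background_roi)
bg_cbv <- background_reference(ph$maps$cbv, ph$masks$background_roi)
maps <- list(aptw = ph$maps$aptw,
             fet  = tbr_map(ph$maps$fet, bg_fet),
             cbv  = rcbv_map(ph$maps$cbv, bg_cbv))
res <- run_overlap_analysis(maps, ph$masks[c("cet", "fht")],
                            patient_id = "example")
res$hotspots[, c("compartment", "modality", "volume_mm3", "relative_volume")]
#>  compartment modality volume_mm3 relative_volume
#>          CET     aptw      19776          1.0000
#>          CET      fet      16024          0.8103
#>          CET      cbv      10336          0.5227
#>          FHT     aptw      43344          0.3403
#>          FHT      fet      16704          0.1312
#>          FHT      cbv       4128          0.0324
res$dice[, c("compartment", "pair", "dice")]
#>  compartment     pair  dice
#>          CET aptw_fet 0.895
#>          CET aptw_cbv 0.687
#>          CET  fet_cbv 0.784
#>          FHT aptw_fet 0.556
#>          FHT aptw_cbv 0.174
#>          FHT  fet_cbv 0.396
```

Reading: in this phantom the whole enhancing compartment is APTw-positive
(relative volume 1.0) while FET and CBV hotspots cover 81 % and 52 % of it;
APTw and FET overlap most closely (Dice 0.895 in CET), mirroring the nested
hotspot geometry the phantom was built with. The FET-positive part of FHT is
APTw-enriched (median 2.71 vs 1.56 % outside, rank-sum p < 1e-6 at voxel
level):

```r
res$subregions[res$subregions$modality == "aptw",
               c("compartment", "median_pos", "median_neg", "p_value")]
#>  compartment median_pos median_neg  p_value
#>          CET       4.20       4.15 1.58e-06
#>          FHT       2.71       1.56 0.00e+00
```

## Cohort workflow

The numbered drivers under `analysis/` run the full study-style sequence on
a simulated cohort (12 glioblastoma-like and 8 lower-grade-like patients,
the latter analyzed in FHT only):

```sh
Rscript analysis/01_generate_cohort.R     # phantoms with per-patient geometry
Rscript analysis/02_hotspot_overlap.R     # normalization, hotspots, Dice
Rscript analysis/03_subregion_stats.R     # FET-positive vs FET-negative stats
Rscript analysis/04_biopsy_correlation.R  # 34 biopsies, Spearman vs histology
Rscript analysis/05_report.R              # boxplot-ready summaries + report
```

Outputs (CSV/JSON, plus cached phantoms) land under `results/`.

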