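#!/usr/bin/env Rscript
# Stage 2: normalization and hotspot-overlap analysis per patient.
# Raw FET and CBV maps are converted to TBR and WM-referenced rCBV using the
# contralateral background ROI, hotspots are thresholded (APTw > 1.79,
# TBR > 1.6, rCBV > 5.6) within CET and FHT, and hotspot volumes plus
# pairwise Dice scores are tabulated. LGG-like patients contribute FHT only.

suppressPackageStartupMessages(library(gliohotspot))
cohort <- readRDS("results/cohort/cohort.rds")

results <- list()
for (id in names(cohort)) {
  ph <- cohort[[id]]$phantom
  bg_fet <- background_reference(ph$maps$fet, ph$masks$background_roi)
  bg_cbv <- background_reference(ph$maps$cbv, ph$masks$background_roi)
  maps <- list(aptw = ph$maps$aptw,
               fet = tbr_map(ph$maps$fet, bg_fet),
               cbv = rcbv_map(ph$maps$cbv, bg_cbv))
  comps <- if (cohort[[id]]$use_cet) ph$masks[c("cet", "fht")]
           else ph$masks["fht"]
  results[[id]] <- run_overlap_analysis(maps, comps, patient_id = id)
}
saveRDS(results, "results/cohort/analysis.rds")

hot <- do.call(rbind, lapply(results, `[[`, "hotspots"))
dc <- do.call(rbind, lapply(results, `[[`, "dice"))
write.csv(hot, "results/hotspot_volumes.csv", row.names = FALSE)
write.csv(dc, "results/dice_scores.csv", row.names = FALSE)

entity <- sapply(cohort, `[[`, "entity")
cat(sprintf("analyzed %d patients; CET rows: %d, FHT rows: %d\n",
            length(results), sum(hot$compartment == "CET") / 3,
            sum(hot$compartment == "FHT") / 3))
for (cn in unique(hot$compartment)) for (m in c("aptw", "fet", "cbv")) {
  sel <- hot$compartment == cn & hot$modality == m
  gb <- sel & entity[hot$patient] == "GB"
  cat(sprintf("  %s %s: median relative volume %.3f (GB)\n",
              cn, m, median(hot$relative_volume[gb])))
}
cat(sprintf("  CET Dice APTw/FET (GB): %.3f\n",
            median(dc$dice[dc$compartment == "CET" &
                           dc$pair == "aptw_fet"])))
cat(sprintf("  FHT Dice APTw/FET: GB %.3f, LGG %.3f\n",
            median(dc$dice[dc$compartment == "FHT" & dc$pair == "aptw_fet" &
                           entity[dc$patient] == "GB"]),
            median(dc$dice[dc$compartment == "FHT" & dc$pair == "aptw_fet" &
                           entity[dc$patient] == "LGG"])))
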