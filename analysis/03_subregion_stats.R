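#!/usr/bin/env Rscript
# Stage 3: APTw and CBV statistics inside FET-positive vs FET-negative
# portions of each compartment (the Table-2-style view), with voxel-level
# rank-sum p per patient and a cohort-level comparison of patient medians.

suppressPackageStartupMessages(library(gliohotspot))
cohort <- readRDS("results/cohort/cohort.rds")
results <- readRDS("results/cohort/analysis.rds")

sub <- do.call(rbind, lapply(results, `[[`, "subregions"))
entity <- sapply(cohort, `[[`, "entity")
sub$entity <- entity[sub$patient]
write.csv(sub, "results/subregion_stats.csv", row.names = FALSE)

cat("patient-median map values in FET-positive vs FET-negative areas:\n")
for (ent in c("GB", "LGG")) for (cn in c("CET", "FHT")) {
  for (m in c("aptw", "cbv")) {
    sel <- sub$entity == ent & sub$compartment == cn & sub$modality == m
    if (!any(sel)) next
    pos <- sub$median_pos[sel]; neg <- sub$median_neg[sel]
    ok <- is.finite(pos) & is.finite(neg)
    if (sum(ok) < 2) next
    gc <- rank_sum_test(pos[ok], neg[ok],
                        labels = c("FET-positive", "FET-negative"))
    cat(sprintf("  %s %s %s: %.2f vs %.2f (patient-level p = %.3g)\n",
                ent, cn, toupper(m), median(pos[ok]), median(neg[ok]),
                gc$p_value))
  }
}
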