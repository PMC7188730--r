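#!/usr/bin/env Rscript
# Stage 5: cohort aggregation. Boxplot-ready summaries of relative hotspot
# volumes and Dice scores per entity and compartment, between-entity
# rank-sum comparisons, and the bundled JSON/CSV report.

suppressPackageStartupMessages(library(gliohotspot))
cohort <- readRDS("results/cohort/cohort.rds")
results <- readRDS("results/cohort/analysis.rds")

entity <- sapply(cohort, `[[`, "entity")
rep_bundle <- build_report(results, cohort = entity)
write_report(rep_bundle, "results/report")

cat("cohort summary (medians):\n")
s <- rep_bundle$cohort_summary
print(s[, c("cohort", "compartment", "measure", "item", "n", "median",
            "q25", "q75")], row.names = FALSE)
if (!is.null(rep_bundle$comparisons)) {
  cat("\nGB vs LGG comparisons (FHT):\n")
  cmp <- rep_bundle$comparisons
  print(cmp[cmp$compartment == "FHT",
            c("measure", "item", "median_a", "median_b", "p_value",
              "significant")], row.names = FALSE)
}
cat("\nfull report written to results/report/\n")
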