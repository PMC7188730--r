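#!/usr/bin/env Rscript
# Simulates the study cohort: 12 glioblastoma-like phantoms (enhancing core
# plus FLAIR-hyperintense envelope, nested APTw > FET > CBV hotspots) and
# 8 lower-grade-glioma-like phantoms (no usable contrast enhancement, low
# APTw signal). Geometry is jittered per patient; per-modality noise is on.
# Phantom objects are cached under results/cohort/ for the later stages.

suppressPackageStartupMessages(library(gliohotspot))
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
set.seed(20260901)
seeds <- sample.int(2^31 - 2, 40)

jitter_spec <- function(sp, seed) {
  set.seed(seed)
  sc <- function(x) x * runif(1, 0.92, 1.08)
  sp$cet$semiaxes <- sc(sp$cet$semiaxes)
  sp$fht$semiaxes <- sp$fht$semiaxes * runif(1, 0.95, 1.05)
  for (m in names(sp$hotspots)) {
    sp$hotspots[[m]]$semiaxes <- sc(sp$hotspots[[m]]$semiaxes)
    sp$hotspots[[m]]$center <- sp$hotspots[[m]]$center + runif(3, -2, 2)
  }
  sp
}

# lower-grade profile: weak APTw (small hotspot barely above cutoff), more
# modest FET and CBV, enhancement absent downstream (CET mask dropped)
lgg_base <- phantom_spec(
  hotspots = list(
    aptw = list(center = c(8, 0, 0), semiaxes = c(18, 15, 13), delta = 0.7),
    fet  = list(center = c(8, 0, 0), semiaxes = c(20, 17, 14), delta = 0.9),
    cbv  = list(center = c(8, 0, 0), semiaxes = c(12, 10, 8),  delta = 3.8)),
  baseline = list(aptw = c(background = 0.5, cet = 1.4, fht = 1.2),
                  fet  = c(background = 1.0, cet = 1.3, fht = 1.15),
                  cbv  = c(background = 2.5, cet = 3.2, fht = 2.0)))

cohort <- list()
for (i in 1:12) {
  id <- sprintf("gb%02d", i)
  sp <- jitter_spec(phantom_spec(), seeds[i])
  cohort[[id]] <- list(phantom = generate_phantom(sp, seed = seeds[i]),
                       entity = "GB", use_cet = TRUE)
}
for (i in 1:8) {
  id <- sprintf("lgg%02d", i)
  sp <- jitter_spec(lgg_base, seeds[20 + i])
  cohort[[id]] <- list(phantom = generate_phantom(sp, seed = seeds[20 + i]),
                       entity = "LGG", use_cet = FALSE)
}
saveRDS(cohort, "results/cohort/cohort.rds")
cat("generated", length(cohort), "phantom patients:",
    sum(sapply(cohort, `[[`, "entity") == "GB"), "GB,",
    sum(sapply(cohort, `[[`, "entity") == "LGG"), "LGG\n")
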