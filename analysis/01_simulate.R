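#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates a QIDS-like longitudinal cohort: 82 persons, 16 raw items on the
# 0-3 scale, 9 weekly measurements, with three person archetypes (quick
# recovery / persistent somatic-affective / increasing), two symptom domains,
# an early-vs-late time phase split, and a shared downward treatment trend.
# The raw 0-3 scale is emitted so the downstream recoding step is exercised
# on realistic input.

library(hetcube)

seed <- 1L
out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- generate_qids_like(scale = "raw", seed = seed)
write_records(sim$records, file.path(out_dir, "records_raw.csv"))
jsonlite::write_json(
  list(seed = seed,
       archetype = sim$truth$archetype,
       severity_class = sim$truth$severity_class,
       domains = sim$truth$domains,
       phases = sim$truth$phases,
       trend = sim$truth$trend),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

tab <- table(factor(sim$truth$archetype, levels = 1:3,
                    labels = c("quick recovery", "persistent somatic/affective",
                               "increasing")))
cat("Simulated cohort written to", out_dir, "\n")
cat(sprintf("  %d persons x 16 raw items x 9 weeks (%d records)\n",
            length(sim$truth$archetype), nrow(sim$records)))
for (nm in names(tab)) cat(sprintf("  archetype %-30s %d persons\n", nm, tab[[nm]]))
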