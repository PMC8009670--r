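#!/usr/bin/env Rscript
# Step 2: quality control and feature extraction.
#
# Regenerates the cohort of step 1 (same seed, bit-identical), applies the
# QC rules (RMP more depolarized than -50 mV, or unstable baseline), runs
# the voltage-clamp chain (limb split, leak fit, subtraction, PIC
# measures) and the current-clamp chain (dV/dt spike detection,
# recruitment, SPR/PR segmentation, gains) on every cell, and writes the
# 21-feature table.

suppressMessages(library(picquant))

seed <- 20210319
dir.create("results", showWarnings = FALSE)

cells <- sample_cohort(table1_cohort_spec(include_nonfiring = TRUE), seed = seed)
qc <- qc_filter(cells)
message(length(qc$kept), " cells pass QC; ", nrow(qc$excluded), " excluded")
if (nrow(qc$excluded)) print(qc$excluded)
write.csv(qc$excluded, "results/qc_excluded.csv", row.names = FALSE)

table <- suppressMessages(build_feature_table(qc$kept))
write_feature_table(table, "results/feature_table.csv")
message("wrote results/feature_table.csv: ", nrow(table), " cells x ",
        length(canonical_features()), " features")
message("firing classes: ",
        paste(names(table(table$firing_class)), table(table$firing_class),
              collapse = ", "))
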