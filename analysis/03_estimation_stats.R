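#!/usr/bin/env Rscript
# Step 3: estimation statistics on the feature table.
#
# For each feature and age group: Hedges' g (mSOD1 - WT) with a 5000-
# resample BCa bootstrap interval and Welch's t for information. Also:
# age regressions of the headline features per genotype, the ANCOVA of
# PIC amplitude on input conductance by genotype (interaction screen,
# then additive), firing vs non-firing comparisons, and the
# ascending/descending concordance.

suppressMessages(library(picquant))

seed <- 20210319
table <- read_feature_table("results/feature_table.csv")

effects <- suppressWarnings(compare_groups(table, n_boot = 5000, seed = seed))
write.csv(effects, "results/group_effects.csv", row.names = FALSE)
young <- effects[effects$age_group == "P30-P60", ]
message("largest P30-P60 effects (g, mSOD1 - WT):")
print(head(young[order(-abs(young$g)),
                 c("feature", "g", "ci_low", "ci_high", "n_wt", "n_msod1")], 6),
      row.names = FALSE)

wk <- age_weeks(table$age_days)
for (gt in c("WT", "mSOD1")) {
  i <- table$genotype == gt & is.finite(table$pic_amplitude_asc)
  r <- regress_with_ci(wk[i], table$pic_amplitude_asc[i])
  message(sprintf("PIC amplitude vs age, %s: slope %.2f nA/wk [%.2f, %.2f], r2 %.2f",
                  gt, r$slope, r$ci_low, r$ci_high, r$r2))
}

anc <- lapply(split(table, table$age_group), function(sub)
  tryCatch(ancova_pic_conductance(sub), picquant_error = function(e) NULL))
for (grp in names(anc)) if (!is.null(anc[[grp]]))
  message(sprintf("ANCOVA %s: interaction t(%d) = %.2f (p = %.2f); %s genotype effect %.2f [%.2f, %.2f]",
                  grp, anc[[grp]]$interaction$df, anc[[grp]]$interaction$t,
                  anc[[grp]]$interaction$p, anc[[grp]]$model,
                  anc[[grp]]$genotype_effect$estimate,
                  anc[[grp]]$genotype_effect$ci_low,
                  anc[[grp]]$genotype_effect$ci_high))

nf <- nonfiring_comparison(table, n_boot = 5000, seed = seed)
if (!is.null(nf$pic_amplitude))
  message(sprintf("non-firing PIC amplitude: g = %.2f [%.2f, %.2f]",
                  nf$pic_amplitude$g, nf$pic_amplitude$ci_low,
                  nf$pic_amplitude$ci_high))

conc <- asc_desc_concordance(table)
message("asc/desc r2: ",
        paste(names(conc), round(conc, 2), sep = " = ", collapse = ", "))

strip <- function(x) { if (inherits(x, "effect_size")) x$boot_g <- NULL
  if (is.list(x)) x <- lapply(x, strip); x }
jsonlite::write_json(
  list(effects = effects, ancova = anc, nonfiring = strip(nf),
       concordance = as.list(conc)),
  "results/stats.json", auto_unbox = TRUE, digits = NA, pretty = TRUE,
  force = TRUE)
message("wrote results/group_effects.csv and results/stats.json")
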