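#!/usr/bin/env Rscript
# Step 4: PCA of the standardized 21-feature table.
#
# Complete-case cells are z-scored per feature and projected onto five
# components; the per-feature correlation with each component (the
# loadings heatmap analogue) and the per-cell scores are written out, and
# the score-vs-age regressions per genotype are reported for the first
# three components.

suppressMessages(library(picquant))

table <- read_feature_table("results/feature_table.csv")
pca <- pca_features(table)

message(sprintf("explained variance: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% (first three: %.0f%%)",
                100 * pca$explained_variance_ratio[1],
                100 * pca$explained_variance_ratio[2],
                100 * pca$explained_variance_ratio[3],
                100 * sum(pca$explained_variance_ratio[1:3])))

write.csv(data.frame(component = seq_along(pca$explained_variance_ratio),
                     ratio = pca$explained_variance_ratio),
          "results/pca_variance.csv", row.names = FALSE)
write.csv(data.frame(feature = rownames(pca$loadings), pca$loadings),
          "results/pca_loadings.csv", row.names = FALSE)

scores <- data.frame(cell_id = rownames(pca$scores), pca$scores)
scores <- merge(scores, table[, c("cell_id", "genotype", "age_days")])
write.csv(scores, "results/pca_scores.csv", row.names = FALSE)

for (pc in c("PC1", "PC2", "PC3")) for (gt in c("WT", "mSOD1")) {
  i <- scores$genotype == gt
  r <- regress_with_ci(age_weeks(scores$age_days[i]), scores[[pc]][i])
  message(sprintf("%s vs age, %s: slope %.3f AU/wk [%.3f, %.3f], r2 %.3f",
                  pc, gt, r$slope, r$ci_low, r$ci_high, r$r2))
}
message("wrote results/pca_{variance,loadings,scores}.csv")
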