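#!/usr/bin/env Rscript
# Step 5: differential and structural summaries.
#
# Fold changes between low- and high-iron samples (both experiments
# combined) with Welch tests, the Spearman correlation matrix on log2
# counts (transcription-arrest samples excluded), squared correlations
# of the co-regulated probe pairs, and PCA sample scores.

library(ferrodecay)

out <- "results/summaries"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

m <- read_count_matrix("results/normalized/normalized_counts.csv",
                       "results/simulation/probes.csv",
                       "results/simulation/meta.csv")

fc <- fold_change_table(m)
write.csv(fc, file.path(out, "fold_changes.csv"), row.names = FALSE)
top <- head(fc[order(-fc$fold_change), ], 3)
cat("largest low/high fold changes:\n")
print(data.frame(gene = top$gene, fold_change = round(top$fold_change),
                 p_adjusted = signif(top$p_adjusted, 3)))

sp <- spearman_matrix(m)
write.csv(as.data.frame(sp$rho[sp$order, sp$order]),
          file.path(out, "spearman_clustered.csv"))
for (pair in list(c("ISIP1", "ISIP3"), c("FBA3", "FBA4"))) {
  r2 <- pair_r2(m, pair[1], pair[2])
  cat(sprintf("%s/%s: R2 (Pearson on log2) = %.3f, (Spearman) = %.3f\n",
              pair[1], pair[2], r2$r2_pearson, r2$r2_spearman))
}

pca <- pca_scores(m)
write.csv(data.frame(sample_id = pca$samples$sample_id,
                     treatment = pca$samples$treatment,
                     time_min = pca$samples$time_min, pca$scores),
          file.path(out, "pca_scores.csv"), row.names = FALSE)
cat(sprintf("PC1/PC2 explained variance: %.2f / %.2f\n",
            pca$explained_variance[1], pca$explained_variance[2]))
cat("wrote", out, "\n")
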