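#!/usr/bin/env Rscript
# Structure analyses: PCA of the filtered normalized matrix, feature
# co-occurrence, sterol-only sample subgrouping, and the statin
# contingency test on the cancer-sample subgroups.

library(ftmslipids)

mat <- as.matrix(read.delim("results/intensity_matrix.tsv", row.names = 1,
                            check.names = FALSE))
md <- read.delim("results/peaklists/metadata.tsv")
md <- md[match(colnames(mat), md$sample_id), ]
feats <- read.delim("results/corresponded_features.tsv")
logmat <- log2_transform(mat)

pca <- pca_scores(logmat, n_components = 3)
print(pca)
scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     class = md$class, instrument = md$instrument)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
# which component separates instrument vs class (point-biserial on scores)
for (j in 1:3) {
  cat(sprintf("PC%d (%4.1f%%): |cor| with instrument %.2f, with class %.2f\n",
              j, 100 * pca$var_explained[j],
              abs(cor(pca$scores[, j], md$instrument == "Fusion2")),
              abs(cor(pca$scores[, j], md$class == "cancer"))))
}

co <- cooccurrence_matrix(logmat)
cat(sprintf("mean off-diagonal co-occurrence: %.2f\n",
            mean(co[upper.tri(co)], na.rm = TRUE)))

# sterol-only subgrouping of cancer samples + statin association
cancer <- md$class == "cancer"
st_rows <- feats$category == "ST"
if (sum(st_rows) >= 2) {
  part <- subgroup_samples(logmat[st_rows, cancer, drop = FALSE], k = 2)
  tab <- table(subgroup = part, statin = md$statin[cancer])
  print(tab)
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    res <- suppressWarnings(chi_squared_2x2(tab))
    cat(sprintf("statin x sterol-subgroup chi-squared: %.3f (p = %.3f)\n",
                res$statistic, res$p_value))
  }
}
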