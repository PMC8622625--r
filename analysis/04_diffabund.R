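#!/usr/bin/env Rscript
# Differential abundance, unpaired: empirical-Bayes moderated linear model
# (disease + instrument) on the imputed log2 matrix, two-part
# presence/rank-sum test on the unimputed matrix, BH at 0.01, union of
# the two significant sets, and log2 fold changes.

library(ftmslipids)

mat <- as.matrix(read.delim("results/intensity_matrix.tsv", row.names = 1,
                            check.names = FALSE))
md <- read.delim("results/peaklists/metadata.tsv")
qc <- read.delim("results/qc_stats.tsv")
keep <- setdiff(colnames(mat), qc$sample_id[qc$remove])
mat <- mat[, keep]
md <- md[match(keep, md$sample_id), ]

logmat <- log2_transform(mat)
imputed <- impute_missing(logmat, md$class, q = 0.025)
cat(sprintf("imputation bounds (log2): %s\n",
            paste(sprintf("%s %.2f", names(attr(imputed, "thresholds")),
                          attr(imputed, "thresholds")), collapse = ", ")))

mod <- fit_moderated_linear_model(imputed, md$class, md$instrument)
tp <- two_part_test_all(logmat, md$class)
diff <- differential_features(mod, tp, alpha = 0.01)
fc <- log2_fold_changes(imputed, md$class)
diff$log2fc <- unname(fc[diff$feature_id])
diff$direction <- ifelse(diff$log2fc > 0, "more", "less")

write.table(diff, "results/differential_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("significant at BH 0.01: moderated %d, two-part %d, union %d (of %d)\n",
            sum(diff$sig_moderated), sum(diff$sig_two_part),
            sum(diff$significant), nrow(diff)))

# sample dendrogram on 1 - tau, leaves ordered smallest-first
d <- 1 - correlation_matrix(logmat, "samples")
d[!is.finite(d)] <- 1; diag(d) <- 0
cl <- cluster_samples(d)
writeLines(cl$order, "results/sample_leaf_order.txt")
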