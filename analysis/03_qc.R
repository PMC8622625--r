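#!/usr/bin/env Rscript
# Sample quality control: per-sample median within-class missing-aware
# Kendall-tau correlation and outlier-lipid fraction, with Tukey-fence
# removal (a sample must fail BOTH criteria to be dropped).

library(ftmslipids)

mat <- as.matrix(read.delim("results/intensity_matrix.tsv", row.names = 1,
                            check.names = FALSE))
md <- read.delim("results/peaklists/metadata.tsv")
md <- md[match(colnames(mat), md$sample_id), ]

logmat <- log2_transform(mat)
stats <- sample_outlier_stats(logmat, md$class)
flagged <- flag_outlier_samples(stats)
write.table(flagged, "results/qc_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

removed <- attr(flagged, "removed")
cat(sprintf("median within-class correlation: %.3f (range %.3f-%.3f)\n",
            median(stats$median_cor), min(stats$median_cor),
            max(stats$median_cor)))
if (length(removed)) {
  cat("removed samples:", paste(removed, collapse = ", "), "\n")
} else {
  cat("no samples flagged for removal\n")
}
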