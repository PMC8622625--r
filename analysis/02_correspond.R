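#!/usr/bin/env Rscript
# Cross-spectrum correspondence: median-normalize every spectrum, group
# peaks at 5 ppm, elect consensus formulas by EMF voting, and keep the
# features present in at least 25% of either disease class.

library(ftmslipids)

input <- read_peaklists("results/peaklists")
normalized <- median_normalize(input$peaklists)

corr <- build_corresponded_matrix(normalized, input$metadata, tol_ppm = 5)
filt <- filter_by_class_presence(corr, min_frac = 0.25)
cat(sprintf("corresponded peaks: %d; after the 25%% presence filter: %d\n",
            nrow(corr$intensity), nrow(filt$intensity)))
cat(sprintf("category breakdown of filtered features:\n"))
print(table(filt$features$category))

write.table(filt$features, "results/corresponded_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mat <- data.frame(feature_id = rownames(filt$intensity), filt$intensity,
                  check.names = FALSE)
write.table(mat, "results/intensity_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# voting accuracy against the generator's ground truth
tt <- read.delim("results/ground_truth.tsv")
ids <- sub("#.*$", "", corr$features$feature_id)
cat(sprintf("consensus formulas matching ground truth: %.1f%%\n",
            100 * mean(ids %in% tt$feature_id)))
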