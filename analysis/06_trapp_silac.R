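#!/usr/bin/env Rscript
# SILAC TRAPP time-course analysis: confidence and replicate-presence
# filtering, median aggregation, classification of >2-fold changes in RNA
# association at 16 min, and PCA over the complete-case protein set.

suppressPackageStartupMessages(library(stress5p))
out <- "results/trapp"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- utils::read.table("results/data/trapp_ratios.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
m <- build_silac_matrix(tab, min_peptides = 2)
cat(sprintf("quantified after the 2-peptide filter: %d proteins\n",
            length(unique(m$protein))))
m <- filter_presence(m, min_replicates = 2)
cat(sprintf("present in >=2 replicates at every time point: %d proteins\n",
            length(unique(m$protein))))

agg <- aggregate_replicates(m)
write_tsv(cbind(protein = rownames(agg), as.data.frame(agg)),
          file.path(out, "aggregated_medians.tsv"))

cls <- classify_changes(agg, "glucose", time_min = 16, fold_threshold = 2)
cat(sprintf("proteins with >2-fold change at 16 min: %d up, %d down\n",
            length(cls$increased), length(cls$decreased)))
write_stats_json(cls, file.path(out, "classified_changes.json"))

## PCA on the complete-case set, samples as observations
complete <- agg[stats::complete.cases(agg), , drop = FALSE]
pca <- run_pca(complete, orientation = "samples")
ev <- round(100 * pca$explained_variance, 1)
cat(sprintf("PCA over %d complete-case proteins: PC1 %.1f%%, PC2 %.1f%%\n",
            nrow(complete), ev[1], ev[2]))
write_tsv(data.frame(sample = rownames(pca$scores),
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2]),
          file.path(out, "pca_samples.tsv"))
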