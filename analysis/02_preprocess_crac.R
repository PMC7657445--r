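#!/usr/bin/env Rscript
# Preprocess the pooled CRAC libraries: demultiplex on the in-read barcode
# (after the 3-nt random tag), trim the 3' adapter and low-quality tails,
# collapse PCR duplicates on (UMI, insert) and drop low-complexity reads.
# Reports how many reads each stage removed, per sample.

suppressPackageStartupMessages(library(stress5p))
data_dir <- "results/data"
out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

barcodes <- c(control = "GTGAGC", mock = "TAGCAT", glucose30s = "CACTGT",
              glucose16m = "ACCTGA", heat16m = "ATTGCG")
adapter <- "TGGAATTCTCGGGTGCCAAGGC"

fastqs <- list.files(file.path(data_dir, "crac"), pattern = "\\.fastq$",
                     full.names = TRUE)
pool <- do.call(rbind, lapply(fastqs, read_fastq))
cat(sprintf("pooled input: %d reads from %d libraries\n", nrow(pool),
            length(fastqs)))

pp <- preprocess_reads(pool, barcodes, adapter)
print(pp$stats, row.names = FALSE)
write_stats_json(pp$stats, file.path(out, "preprocess_stats.json"))
for (s in names(pp$samples))
  write_fastq(pp$samples[[s]], file.path(out, paste0(s, ".fastq")))

surv <- sum(pp$stats$surviving)
cat(sprintf("surviving: %d reads (%.1f%% of assigned)\n", surv,
            100 * surv / sum(pp$stats$input_reads)))
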