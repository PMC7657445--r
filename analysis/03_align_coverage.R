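#!/usr/bin/env Rscript
# Place processed CRAC reads on the toy genome (exact matching, random
# assignment of multi-mappers), write BED alignments and strand-specific
# RPM-scaled bedGraph coverage, and call the major crosslink summit on the
# rRNA-like locus -- initiation-factor CRAC libraries are dominated by a
# few strong rRNA contacts, and the summit caller localises them.

suppressPackageStartupMessages(library(stress5p))
out <- "results/align"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bundle <- local({
  b <- build_toy_genome(n_study = 60, n_spike = 3, seed = 20201105L)
  b
})

for (fq in list.files("results/preprocess", pattern = "\\.fastq$",
                      full.names = TRUE)) {
  cond <- sub("\\.fastq$", "", basename(fq))
  reads <- read_fastq(fq)
  if (nrow(reads) == 0) next
  al <- align_reads(reads, bundle, seed = 42)
  cat(sprintf("%-12s mapped %6d  unmapped %4d  multimapped %5d\n",
              cond, nrow(al$alignments), al$unmapped,
              sum(al$alignments$multimapped)))
  write_alignments_bed(al$alignments, file.path(out, paste0(cond, ".bed")))
  cov <- compute_coverage(al$alignments, bundle, "rpm")
  write_coverage_bedgraph(cov, file.path(out, cond))
  if (cond == "control") {
    s <- find_summits(cov, "chrR", "+",
                      region = c(1, Biostrings::width(
                        bundle$chroms["chrR"])),
                      top_k = 3, min_separation = 50)
    cat("  rRNA summits (pos, RPM):\n")
    print(s, row.names = FALSE)
    write_tsv(s, file.path(out, "rrna_summits.tsv"))
  }
}
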