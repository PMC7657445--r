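#!/usr/bin/env Rscript
# Transcript-level CRAC quantification: total vs 5'-end binding per
# condition, fold changes on the top-bound transcript set, the
# stress-vs-mock significance test, start-codon metagene profiles, the
# pervasive-binding fraction, and ratio-sorted heatmaps.

suppressPackageStartupMessages(library(stress5p))
out <- "results/crac"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
bundle <- build_toy_genome(n_study = 60, n_spike = 3, seed = 20201105L)

conds <- c("control", "mock", "glucose30s", "glucose16m", "heat16m")
bt <- NULL
aln <- list()
for (cond in conds) {
  a <- read_alignments_bed(file.path("results/align",
                                     paste0(cond, ".bed")))
  aln[[cond]] <- a
  bt <- count_transcript_binding(a, bundle, cond, table = bt)
}
nb <- normalize_binding(bt, pseudocount = 3, library = "mapped")
write_tsv(as.data.frame(nb), file.path(out, "binding_table.tsv"))

## analyses restricted to the most strongly bound transcripts under
## non-stress conditions (control/mock average), as for a top-2,000 set
top <- select_top_transcripts(nb, c("control", "mock"), n = 50)

cat("median 5' log2 fold change vs control (top-bound transcripts):\n")
fc_tab <- list()
for (cond in c("mock", "glucose30s", "glucose16m", "heat16m")) {
  fc <- fold_changes(nb, cond, "control", metric = "fivep",
                     transcripts = top)
  fc_tab[[cond]] <- fc$log2fc
  cat(sprintf("  %-11s %+.2f\n", cond, median(fc$log2fc)))
  write_tsv(fc, file.path(out, paste0("fivep_log2fc_", cond, ".tsv")))
}

## stress vs mock: the binding loss is not protocol-induced
wt <- compare_distributions(fc_tab$glucose30s, fc_tab$mock)
cat(sprintf("glucose 30 s vs mock: Welch t = %.1f, p = %.3g\n",
            wt$statistic, wt$p_value))
write_stats_json(list(comparison = "glucose30s_vs_mock",
                      t = wt$statistic, p = wt$p_value),
                 file.path(out, "welch_test.json"))

## metagene profiles around the start codon
prof <- list()
for (cond in c("control", "glucose30s")) {
  p <- startcodon_profile(aln[[cond]], bundle, top)
  prof[[cond]] <- p
  write_tsv(data.frame(offset = p$offsets, density = p$density),
            file.path(out, paste0("metagene_", cond, ".tsv")))
}
m5 <- function(cond) {
  libsize <- nrow(aln[[cond]])
  pr <- startcodon_profile(aln[[cond]], bundle, top, scale = "rpm",
                           library_size = libsize)
  profile_mass(pr, -200, 150)
}
cat(sprintf("library-scaled 5' metagene signal: control %.1f, glucose 30 s %.1f (%.1f-fold drop)\n",
            m5("control"), m5("glucose30s"),
            m5("control") / m5("glucose30s")))

## pervasive (Ded1-like) binding statistics and heatmap
st <- fivep_pervasive_stats(nb, "control")
cat(sprintf("pervasive-binding transcripts under control: %.0f%%\n",
            100 * attr(st, "pervasive_fraction")))
write_tsv(st, file.path(out, "fivep_pervasive_control.tsv"))
hm <- heatmap_matrix(aln$control, bundle, top, nb, "control", bins = 50)
write_tsv(cbind(transcript = rownames(hm),
                ratio = attr(hm, "ratio"),
                as.data.frame(unclass(hm))),
          file.path(out, "heatmap_control.tsv"))
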