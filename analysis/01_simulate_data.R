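#!/usr/bin/env Rscript
# Build the synthetic study: a toy two-species genome, ground-truth binding
# occupancies with condition-specific 5'-retention kinetics (glucose: 5'
# binding collapses to 10% within 30 s and stays there; heat: progressive
# decline to 20% by 16 min), CRAC libraries for each condition, spike-in
# RNA-seq libraries, and a SILAC TRAPP ratio time course.
#
# Writes everything under results/data/.

suppressPackageStartupMessages(library(stress5p))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20201105L

## genome: 60 study mRNAs (10% RP, 15% RiBi regulons), 3 spike-species
## transcripts, one rRNA-like locus
bundle <- build_toy_genome(n_study = 60, n_spike = 3, seed = seed)
write_genome_bundle(bundle, out)
cat(sprintf("genome: %d chromosomes, %d transcripts (%d spike)\n",
            length(bundle$chroms), nrow(bundle$transcripts),
            sum(bundle$transcripts$species == "spike")))

## ground truth: eIF4B-like 5'-concentrated binding on most transcripts,
## a Ded1-like pervasive minority; stress retentions per condition
stress <- data.frame(
  condition = c("glucose30s", "glucose16m", "heat16m"),
  fivep_retention = c(0.1, 0.1, 0.2),
  pervasive_retention = c(1.0, 1.0, 0.5))
truth <- make_binding_truth(bundle,
  factor_profile = list(fivep_share = 0.9,
                        pervasive_transcript_fraction = 0.2),
  stress_model = stress, background_share = 0.9, seed = seed + 1)
write_tsv(truth$transcripts, file.path(out, "truth_weights.tsv"))
write_tsv(truth$conditions, file.path(out, "truth_conditions.tsv"))

## CRAC libraries: 100k reads each, PCR duplicates and low-complexity
## contaminants planted so preprocessing has real work to do
crac_cfg <- sim_config(
  n_reads = 100000, pcr_duplication_rate = 0.15, contaminant_rate = 0.03,
  barcode_table = c(control = "GTGAGC", mock = "TAGCAT",
                    glucose30s = "CACTGT", glucose16m = "ACCTGA",
                    heat16m = "ATTGCG"))
for (cond in names(crac_cfg$barcode_table)) {
  sim <- simulate_crac_reads(truth, bundle, cond, crac_cfg,
                             seed = seed + 10 +
                               match(cond, names(crac_cfg$barcode_table)),
                             out_dir = file.path(out, "crac"))
  cat(sprintf("CRAC %-10s %6d reads -> %s\n", cond, nrow(sim$reads),
              sim$fastq))
}

## RNA-seq libraries: 2% spike-in, regulon-specific decay at 16 min
rna_cfg <- sim_config(n_reads = 150000, decay_model = list(
  glucose16m = c(RP = 0.4, RiBi = 0.4, other = 0.97),
  heat16m = c(RP = 1 / 16, RiBi = 1 / 16, other = 1.0),
  heat16m_chx = c(RP = 1, RiBi = 1, other = 1)))
rna_truth <- make_binding_truth(bundle,
  stress_model = data.frame(condition = names(rna_cfg$decay_model),
                            fivep_retention = 1, pervasive_retention = 1),
  seed = seed + 1)
for (cond in c("control", names(rna_cfg$decay_model))) {
  sim <- simulate_rnaseq_reads(rna_truth, bundle, cond, rna_cfg,
                               seed = seed + 30 +
                                 match(cond, c("control",
                                               names(rna_cfg$decay_model))),
                               out_dir = file.path(out, "rnaseq"))
  cat(sprintf("RNA-seq %-12s %6d reads\n", cond, nrow(sim$reads)))
}

## TRAPP: 300 RBPs, 22 with a >2-fold change in RNA association at 16 min
planted <- data.frame(protein = sprintf("P%05d", 1:22),
                      condition = "glucose", time_min = 16,
                      effect = rep(c(1.5, -1.5), each = 11))
trapp <- simulate_trapp_ratios(300, planted, conditions = "glucose",
                               n_replicates = 4, noise_sd = 0.1,
                               missingness = 0.05, seed = seed + 50)
write_tsv(trapp, file.path(out, "trapp_ratios.tsv"))
cat(sprintf("TRAPP: %d measurements over %d proteins\n", nrow(trapp),
            length(unique(trapp$protein))))
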