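#' Simulate a two-species RNA-seq library for one condition
#'
#' Reads are sampled from transcripts proportionally to molar abundance, with
#' start positions uniform along the transcript. The spike species is fixed
#' at `config$spike_fraction` of the *control* study molar input and is the
#' same in every condition, so a global decline in study mRNA raises the
#' spike's share of reads -- the signal that spike-in normalization recovers.
#' Condition-specific regulon decay comes from `config$decay_model` unless
#' the truth object already carries decayed abundances.
#'
#' @param truth a `binding_truth` (supplies per-transcript abundances).
#' @param bundle the `genome_bundle`.
#' @param condition condition label.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param out_dir if non-NULL, write FASTQ and truth TSV there.
#' @return list with `reads`, `truth` and any paths written.
#' @export
simulate_rnaseq_reads <- function(truth, bundle, condition, config,
                                  seed = 1, out_dir = NULL) {
  n <- config$n_reads
  if (n < 1) stopf("n_reads must be >= 1")
  tx_all <- bundle$transcripts
  study <- tx_all[tx_all$species == "study", ]
  spike <- tx_all[tx_all$species == "spike", ]
  if (config$spike_fraction > 0 && nrow(spike) == 0)
    stopf("spike_fraction > 0 but the bundle has no spike transcripts")
  if (!condition %in% colnames(truth$abundance))
    stopf("unknown condition '%s'", condition)

  a_study <- truth$abundance[study$id, condition]
  ## apply regulon decay from the config when the truth itself is undecayed
  dm <- config$decay_model[[condition]]
  if (!is.null(dm)) {
    m <- unname(dm[match(study$regulon, names(dm))])
    m[is.na(m)] <- dm[["other"]] %||% 1
    a_study <- a_study * m
  }
  a_control <- truth$abundance[study$id, "control"]
  a_spike <- numeric(0)
  if (nrow(spike) > 0 && config$spike_fraction > 0) {
    total_spike <- config$spike_fraction / (1 - config$spike_fraction) *
      sum(a_control)
    a_spike <- rep(total_spike / nrow(spike), nrow(spike))
  }
  tx <- rbind(study, spike[seq_along(a_spike), , drop = FALSE])
  ab <- c(a_study, a_spike)
  rl <- config$read_length
  if (any(tx$length < rl))
    stopf("transcripts shorter than the read length cannot be simulated")

  with_rng(seed, {
    pick <- sample.int(nrow(tx), n, replace = TRUE, prob = ab)
    txpos <- 1L + floor(stats::runif(n) * (tx$length[pick] - rl + 1L))
    seqs <- as.character(transcript_seqs(bundle))[tx$id]
    sequences <- substr(seqs[pick], txpos, txpos + rl - 1L)
    ids <- sprintf("%s_q%07d", condition, seq_len(n))
    reads <- data.frame(id = ids, sequence = sequences,
                        qualities = strrep("I", rl),
                        stringsAsFactors = FALSE)
    truth_tab <- data.frame(
      read_id = ids, condition = condition,
      transcript = tx$id[pick], species = tx$species[pick],
      tx_pos = txpos,
      chrom = tx$chrom[pick],
      gpos = genomic_position(tx[pick, ], txpos),
      strand = tx$strand[pick],
      stringsAsFactors = FALSE)
    out <- list(reads = reads, truth = truth_tab)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fq <- file.path(out_dir, paste0("rnaseq_", condition, ".fastq"))
      tt <- file.path(out_dir, paste0("rnaseq_", condition, "_truth.tsv"))
      write_fastq(reads, fq)
      utils::write.table(truth_tab, tt, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$fastq <- fq
      out$truth_file <- tt
    }
    out
  })
}

#' Simulate a SILAC TRAPP ratio time course
#'
#' Generates protein-level log2(stress/control) SILAC ratios over a time
#' course (default 2, 4, 8, 12, 16 min) with replicates, Gaussian measurement
#' noise, independent missingness, and per-protein peptide-count metadata.
#' Proteins without a planted effect have true log2 ratio 0 at every time
#' point (RBP abundance is essentially constant under these stresses; only
#' RNA association changes).
#'
#' @param n_proteins number of proteins.
#' @param planted data.frame with columns `protein`, `condition`,
#'   `time_min`, `effect` giving true log2 ratios; omitted cells are 0.
#' @param conditions condition labels to simulate.
#' @param time_points time points, minutes.
#' @param n_replicates replicates per (condition, time); a single number or
#'   a vector named by condition.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param missingness probability each measurement is missing.
#' @param peptide_lambda peptide counts are drawn as 1 + Poisson(lambda),
#'   so a small fraction of proteins fall below the 2-peptide filter.
#' @param seed integer seed.
#' @return data.frame (`silac_tables`): protein, condition, time_min,
#'   replicate, log2_ratio, peptides -- one row per observed measurement.
#' @export
simulate_trapp_ratios <- function(n_proteins,
                                  planted = NULL,
                                  conditions = "glucose",
                                  time_points = c(2, 4, 8, 12, 16),
                                  n_replicates = 4,
                                  noise_sd = 0.1,
                                  missingness = 0,
                                  peptide_lambda = 4,
                                  seed = 1) {
  if (n_replicates[1] < 1) stopf("n_replicates must be >= 1")
  if (missingness < 0 || missingness > 1)
    stopf("missingness must be in [0, 1]")
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  reps <- if (length(n_replicates) == 1)
    stats::setNames(rep(n_replicates, length(conditions)), conditions)
  else n_replicates[conditions]

  with_rng(seed, {
    peptides <- 1L + stats::rpois(n_proteins, peptide_lambda)
    names(peptides) <- proteins
    grids <- lapply(conditions, function(cond) {
      expand.grid(protein = proteins, condition = cond,
                  time_min = time_points,
                  replicate = seq_len(reps[[cond]]),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    })
    grid <- do.call(rbind, grids)
    effect <- numeric(nrow(grid))
    if (!is.null(planted)) {
      key <- paste(grid$protein, grid$condition, grid$time_min)
      pkey <- paste(planted$protein, planted$condition, planted$time_min)
      hit <- match(key, pkey)
      effect[!is.na(hit)] <- planted$effect[hit[!is.na(hit)]]
    }
    grid$log2_ratio <- effect +
      if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
    grid$peptides <- peptides[grid$protein]
    keep <- stats::runif(nrow(grid)) >= missingness
    out <- grid[keep, c("protein", "condition", "time_min", "replicate",
                        "log2_ratio", "peptides")]
    rownames(out) <- NULL
    out
  })
}
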