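#' Simulation configuration
#'
#' Bundles the free parameters of the read simulators. Defaults follow the
#' study design being emulated: 75-nt single-end reads, a 3-nt random tag
#' (UMI) followed by a sample barcode at the read 5' end, the TruSeq small-RNA
#' 3' adapter `TGGAATTCTCGGGTGCCAAGGC`, and a spike-in species at 2% of molar
#' RNA input. Decay multipliers reproduce the regulon-specific mRNA losses:
#' glucose starvation depletes RP/RiBi mRNAs ~2.5-fold with near-stable bulk
#' mRNA; heat shock depletes them ~16-fold.
#'
#' @param n_reads reads to emit per library.
#' @param read_length read length, nt.
#' @param umi_length random-tag length, nt.
#' @param barcode_table named character vector, sample -> barcode.
#' @param adapter 3' adapter sequence.
#' @param pcr_duplication_rate fraction of emitted reads that are exact
#'   copies of earlier reads, in \[0, 1).
#' @param contaminant_rate fraction of emitted reads that are low-complexity
#'   contaminants, in \[0, 1).
#' @param spike_fraction spike-in molar fraction of RNA input.
#' @param decay_model per-condition regulon abundance multipliers.
#' @param insert_length `c(min, max)` CRAC insert length, nt.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_reads = 50000,
                       read_length = 75,
                       umi_length = 3,
                       barcode_table = c(control = "GTGAGC",
                                         mock = "TAGCAT",
                                         glucose = "CACTGT",
                                         heat = "ACCTGA"),
                       adapter = "TGGAATTCTCGGGTGCCAAGGC",
                       pcr_duplication_rate = 0,
                       contaminant_rate = 0,
                       spike_fraction = 0.02,
                       decay_model = list(
                         glucose = c(RP = 0.4, RiBi = 0.4, other = 0.97),
                         heat = c(RP = 1 / 16, RiBi = 1 / 16, other = 1.0)),
                       insert_length = c(20, 40)) {
  if (pcr_duplication_rate < 0 || pcr_duplication_rate >= 1)
    stopf("pcr_duplication_rate must be in [0, 1)")
  if (contaminant_rate < 0 || contaminant_rate >= 1)
    stopf("contaminant_rate must be in [0, 1)")
  if (spike_fraction < 0 || spike_fraction >= 1)
    stopf("spike_fraction must be in [0, 1)")
  if (anyDuplicated(barcode_table) || anyDuplicated(names(barcode_table)))
    stopf("barcodes and sample names must be distinct")
  if (length(unique(nchar(barcode_table))) != 1)
    stopf("all barcodes must have the same length")
  structure(list(n_reads = n_reads, read_length = read_length,
                 umi_length = umi_length, barcode_table = barcode_table,
                 adapter = adapter,
                 pcr_duplication_rate = pcr_duplication_rate,
                 contaminant_rate = contaminant_rate,
                 spike_fraction = spike_fraction,
                 decay_model = decay_model,
                 insert_length = insert_length),
            class = "sim_config")
}

#' Simulate a CRAC sequencing library for one condition
#'
#' Emits error-free reads of layout `[umi][barcode][insert][adapter][filler]`
#' truncated to `read_length`. Insert 5' ends are drawn from the ground-truth
#' mixture: per transcript, the 5'-region component places the crosslink-
#' proximal base uniformly in 5'UTR + first 150 nt of CDS, the pervasive
#' component uniformly over the rest of the transcript; the rRNA-like
#' background places reads uniformly on the rRNA locus. A configurable
#' fraction of reads are exact PCR copies of earlier reads, and another
#' fraction are low-complexity contaminants (homopolymers and dinucleotide
#' repeats).
#'
#' @param truth a `binding_truth`.
#' @param bundle the `genome_bundle` the truth refers to.
#' @param condition condition label present in `truth$conditions` and
#'   `config$barcode_table`.
#' @param config a [sim_config()].
#' @param seed integer seed; identical inputs give identical output.
#' @param out_dir if non-NULL, write `<condition>.fastq` and
#'   `<condition>_truth.tsv` there.
#' @return list with `reads` (data.frame id/sequence/qualities), `truth`
#'   (per-read truth table) and any file paths written.
#' @export
simulate_crac_reads <- function(truth, bundle, condition, config,
                                seed = 1, out_dir = NULL) {
  n <- config$n_reads
  if (n < 1) stopf("n_reads must be >= 1")
  min_len <- config$umi_length + nchar(config$barcode_table[[1]]) + 11L
  if (config$read_length < min_len)
    stopf("read_length must be >= umi + barcode + 11 nt (= %d)", min_len)
  barcode <- config$barcode_table[[condition]]
  if (is.null(barcode)) stopf("no barcode for condition '%s'", condition)
  probs <- crac_read_probs(truth, condition)
  tx <- bundle$transcripts[match(probs$tx$id, bundle$transcripts$id), ]
  seqs <- as.character(transcript_seqs(bundle))[probs$tx$id]

  with_rng(seed, {
    is_dup <- stats::runif(n) < config$pcr_duplication_rate
    is_dup[1] <- FALSE
    fresh <- which(!is_dup)
    m <- length(fresh)
    is_contam <- stats::runif(m) < config$contaminant_rate

    ## source category for fresh, non-contaminant reads
    n_real <- sum(!is_contam)
    p_f <- probs$tx$fivep_prob
    p_p <- probs$tx$pervasive_prob
    pool <- c(p_f, p_p, probs$background)
    pick <- sample.int(length(pool), n_real, replace = TRUE, prob = pool)
    ntx <- nrow(probs$tx)
    src_tx <- ifelse(pick <= 2 * ntx, ((pick - 1L) %% ntx) + 1L, NA_integer_)
    src_comp <- ifelse(pick > 2 * ntx, "background",
                       ifelse(pick <= ntx, "fivep", "pervasive"))

    ilen <- sample(seq(config$insert_length[1], config$insert_length[2]),
                   m, replace = TRUE)

    ## transcript-coordinate 5' base of each insert
    txpos <- integer(n_real)
    freg <- fivep_region_len(tx)
    for (what in c("fivep", "pervasive", "background")) {
      idx <- which(src_comp == what)
      if (length(idx) == 0) next
      if (what == "fivep") {
        txpos[idx] <- 1L + floor(stats::runif(length(idx)) * freg[src_tx[idx]])
      } else if (what == "pervasive") {
        body <- tx$length[src_tx[idx]] - freg[src_tx[idx]]
        txpos[idx] <- freg[src_tx[idx]] + 1L +
          floor(stats::runif(length(idx)) * body)
      } else {
        span <- bundle$rrna$end - bundle$rrna$start + 1L
        txpos[idx] <- 1L + floor(stats::runif(length(idx)) *
                                   (span - max(config$insert_length) + 1L))
      }
    }

    ## insert sequences
    real_len <- ilen[!is_contam]
    insert <- character(n_real)
    tx_rows <- !is.na(src_tx)
    if (any(tx_rows)) {
      iend <- pmin(txpos[tx_rows] + real_len[tx_rows] - 1L,
                   tx$length[src_tx[tx_rows]])
      insert[tx_rows] <- substr(seqs[src_tx[tx_rows]], txpos[tx_rows], iend)
    }
    bg <- src_comp == "background"
    if (any(bg)) {
      rseq <- as.character(bundle$chroms[[bundle$rrna$chrom]])
      gstart <- bundle$rrna$start + txpos[bg] - 1L
      insert[bg] <- substr(rep(rseq, sum(bg)), gstart,
                           gstart + real_len[bg] - 1L)
    }

    ## contaminants: homopolymers / dinucleotide repeats
    n_con <- sum(is_contam)
    con_seq <- character(0)
    if (n_con > 0) {
      unit <- ifelse(stats::runif(n_con) < 0.5,
                     sample(c("A", "C", "G", "T"), n_con, replace = TRUE),
                     sample(c("AC", "AG", "AT", "CG", "CT", "GT"),
                            n_con, replace = TRUE))
      con_len <- ilen[is_contam]
      con_seq <- substr(strrep(unit, ceiling(con_len / nchar(unit))),
                        1L, con_len)
    }

    ## assemble fresh reads
    all_insert <- character(m)
    all_insert[!is_contam] <- insert
    all_insert[is_contam] <- con_seq
    umi <- rand_dna(m, config$umi_length)
    core <- paste0(umi, barcode, all_insert, config$adapter)
    pad <- pmax(0L, config$read_length - nchar(core))
    filler <- rand_dna(m, pad)
    fresh_seq <- substr(paste0(core, filler), 1L, config$read_length)

    ## per-fresh-read annotation columns (NA for contaminants/background)
    categ <- character(m); txid <- rep(NA_character_, m)
    tpos <- rep(NA_integer_, m); gpos <- rep(NA_integer_, m)
    chrom <- rep(NA_character_, m); strand <- rep(NA_character_, m)
    categ[is_contam] <- "contaminant"
    categ[!is_contam] <- src_comp
    ridx <- which(!is_contam)
    tx_ok <- ridx[tx_rows]
    txid[tx_ok] <- tx$id[src_tx[tx_rows]]
    tpos[tx_ok] <- txpos[tx_rows]
    gpos[tx_ok] <- genomic_position(tx[src_tx[tx_rows], ], txpos[tx_rows])
    chrom[tx_ok] <- tx$chrom[src_tx[tx_rows]]
    strand[tx_ok] <- tx$strand[src_tx[tx_rows]]
    bg_ok <- ridx[bg]
    if (length(bg_ok) > 0) {
      chrom[bg_ok] <- bundle$rrna$chrom
      strand[bg_ok] <- "+"
      gpos[bg_ok] <- bundle$rrna$start + txpos[bg] - 1L
    }

    ## resolve PCR duplicates: each copies a uniformly chosen earlier read
    origin <- seq_len(n)
    src_slot <- integer(n)
    dup_idx <- which(is_dup)
    if (length(dup_idx) > 0) {
      pickearly <- 1L + floor(stats::runif(length(dup_idx)) *
                                (dup_idx - 1L))
      for (j in seq_along(dup_idx)) {
        i <- dup_idx[j]
        origin[i] <- origin[pickearly[j]]
      }
    }
    fresh_of_slot <- match(origin, fresh)  # index into fresh vectors

    ids <- sprintf("%s_r%07d", condition, seq_len(n))
    sequences <- fresh_seq[fresh_of_slot]
    reads <- data.frame(id = ids, sequence = sequences,
                        qualities = strrep("I", config$read_length),
                        stringsAsFactors = FALSE)
    truth_tab <- data.frame(
      read_id = ids,
      condition = condition,
      category = categ[fresh_of_slot],
      transcript = txid[fresh_of_slot],
      tx_pos = tpos[fresh_of_slot],
      chrom = chrom[fresh_of_slot],
      gpos = gpos[fresh_of_slot],
      strand = strand[fresh_of_slot],
      umi = umi[fresh_of_slot],
      duplicate_of = ifelse(is_dup, ids[origin], NA_character_),
      stringsAsFactors = FALSE)

    out <- list(reads = reads, truth = truth_tab)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fq <- file.path(out_dir, paste0(condition, ".fastq"))
      tt <- file.path(out_dir, paste0(condition, "_truth.tsv"))
      write_fastq(reads, fq)
      utils::write.table(truth_tab, tt, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$fastq <- fq
      out$truth_file <- tt
    }
    out
  })
}
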