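#' Build a toy two-species genome with annotated single-exon transcripts
#'
#' Constructs a small synthetic genome emulating an intron-removed budding
#' yeast transcriptome plus a second ("spike") species used as an exogenous
#' normalization standard for RNA-seq. Every transcript is single-exon with a
#' 5'UTR, a CDS (length a multiple of 3, starting ATG) and a 3'UTR, laid out
#' contiguously in transcription order. Study transcripts can carry a regulon
#' label: `RP` (ribosomal protein) or `RiBi` (ribosome biogenesis), the two
#' coordinately regulated mRNA classes most depleted after heat shock.
#'
#' A dedicated study chromosome (`chrR`) carries a single rRNA-like locus.
#' Initiation-factor CRAC libraries are dominated by stable rRNA binding, and
#' this locus provides the corresponding stress-invariant background in
#' simulations (see [make_binding_truth()]).
#'
#' @param n_study number of study-species mRNA transcripts (>= 1).
#' @param n_spike number of spike-species transcripts.
#' @param length_params list with `utr5`, `cds`, `utr3` elements, each a
#'   `c(min, max)` range in nucleotides. CDS lengths are drawn from the
#'   multiples of 3 inside the range; an empty range is an error.
#' @param regulon_fractions named fractions of study transcripts labelled
#'   `RP` and `RiBi` (defaults 10% and 15%).
#' @param intergenic `c(min, max)` gap between transcripts, nt.
#' @param rrna_length length of the rRNA-like background locus (0 disables).
#' @param seed integer seed; identical arguments give identical bundles.
#'
#' @return A `genome_bundle`: list with `chroms` (named
#'   [Biostrings::DNAStringSet]), `transcripts` (data.frame with 1-based
#'   inclusive genomic coordinates), `spike_chroms`, and `rrna`
#'   (data.frame or NULL).
#' @export
build_toy_genome <- function(n_study,
                             n_spike = 2,
                             length_params = list(utr5 = c(20, 120),
                                                  cds  = c(300, 1500),
                                                  utr3 = c(20, 200)),
                             regulon_fractions = c(RP = 0.10, RiBi = 0.15),
                             intergenic = c(60, 200),
                             rrna_length = 5000,
                             seed = 1) {
  if (n_study < 1) stopf("n_study must be >= 1")
  if (n_spike < 0) stopf("n_spike must be >= 0")
  lp <- length_params
  for (nm in c("utr5", "cds", "utr3")) {
    if (is.null(lp[[nm]]) || length(lp[[nm]]) != 2 || any(lp[[nm]] < 0))
      stopf("length_params$%s must be a non-negative c(min, max) range", nm)
  }
  cds_from <- max(3, ceiling(lp$cds[1] / 3) * 3)
  cds_choices <- if (cds_from > lp$cds[2]) numeric(0) else
    seq(cds_from, lp$cds[2], by = 3)
  if (length(cds_choices) == 0)
    stopf("no CDS length that is a multiple of 3 and >= 3 fits in [%d, %d]",
          lp$cds[1], lp$cds[2])

  with_rng(seed, {
    n_tot <- n_study + n_spike
    ids <- c(sprintf("ST%04d", seq_len(n_study)),
             if (n_spike > 0) sprintf("SP%04d", seq_len(n_spike)))
    species <- c(rep("study", n_study), rep("spike", n_spike))
    utr5 <- sample(seq(lp$utr5[1], lp$utr5[2]), n_tot, replace = TRUE)
    cds <- sample(cds_choices, n_tot, replace = TRUE)
    utr3 <- sample(seq(lp$utr3[1], lp$utr3[2]), n_tot, replace = TRUE)
    strand <- sample(c("+", "-"), n_tot, replace = TRUE)

    regulon <- rep("other", n_tot)
    n_rp <- round(regulon_fractions[["RP"]] * n_study)
    n_ribi <- round(regulon_fractions[["RiBi"]] * n_study)
    if (n_rp + n_ribi > n_study)
      stopf("regulon fractions exceed 1")
    lab <- sample(n_study, n_rp + n_ribi)
    regulon[lab[seq_len(n_rp)]] <- "RP"
    if (n_ribi > 0) regulon[lab[n_rp + seq_len(n_ribi)]] <- "RiBi"

    ## sense-strand transcript sequences; ATG planted at the CDS start
    tx_len <- utr5 + cds + utr3
    tx_seq <- rand_dna(n_tot, tx_len)
    substr(tx_seq, utr5 + 1L, utr5 + 3L) <- "ATG"

    ## lay transcripts onto chromosomes: two study chroms, one spike chrom
    chrom_of <- ifelse(species == "study",
                       c("chrS1", "chrS2")[(seq_len(n_tot) %% 2L) + 1L],
                       "chrP1")
    chroms <- list()
    rows <- vector("list", n_tot)
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      pieces <- character(0)
      cursor <- 0L
      for (i in idx) {
        gap <- sample(seq(intergenic[1], intergenic[2]), 1)
        genomic <- if (strand[i] == "+") tx_seq[i] else revcomp(tx_seq[i])
        pieces <- c(pieces, rand_dna(1, gap), genomic)
        start <- cursor + gap + 1L
        end <- start + tx_len[i] - 1L
        cursor <- end
        rows[[i]] <- data.frame(
          id = ids[i], species = species[i], chrom = ch, strand = strand[i],
          start = start, end = end,
          utr5_len = utr5[i], cds_len = cds[i], utr3_len = utr3[i],
          length = tx_len[i], regulon = regulon[i],
          stringsAsFactors = FALSE)
      }
      tail_gap <- sample(seq(intergenic[1], intergenic[2]), 1)
      chroms[[ch]] <- paste(c(pieces, rand_dna(1, tail_gap)), collapse = "")
    }

    rrna <- NULL
    if (rrna_length > 0) {
      pad <- 200L
      chroms[["chrR"]] <- paste(rand_dna(1, rrna_length + 2L * pad),
                                collapse = "")
      rrna <- data.frame(chrom = "chrR", strand = "+",
                         start = pad + 1L, end = pad + rrna_length,
                         stringsAsFactors = FALSE)
    }

    bundle <- structure(list(
      chroms = Biostrings::DNAStringSet(unlist(chroms)),
      transcripts = do.call(rbind, rows),
      spike_chroms = if (n_spike > 0) "chrP1" else character(0),
      rrna = rrna), class = "genome_bundle")
    validate_bundle(bundle)
    bundle
  })
}

## Internal invariant checks for a genome_bundle.
validate_bundle <- function(bundle) {
  tx <- bundle$transcripts
  if (anyDuplicated(tx$id)) stopf("transcript ids must be unique")
  if (!all(tx$chrom %in% names(bundle$chroms)))
    stopf("transcript on unknown chromosome")
  lens <- Biostrings::width(bundle$chroms)[match(tx$chrom,
                                                 names(bundle$chroms))]
  if (any(tx$start < 1) || any(tx$end > lens) || any(tx$start > tx$end))
    stopf("transcript interval outside chromosome bounds")
  if (any(tx$cds_len < 3) || any(tx$cds_len %% 3 != 0))
    stopf("CDS length must be >= 3 and a multiple of 3")
  if (any(tx$utr5_len + tx$cds_len + tx$utr3_len != tx$length))
    stopf("UTR/CDS segments must tile the transcript")
  spike_tx <- tx$chrom[tx$species == "spike"]
  study_tx <- tx$chrom[tx$species == "study"]
  if (length(intersect(spike_tx, study_tx)) > 0)
    stopf("study and spike transcripts must not share a chromosome")
  invisible(TRUE)
}

#' Sense-strand sequences of all transcripts in a bundle
#'
#' @param bundle a `genome_bundle`.
#' @return named [Biostrings::DNAStringSet], one entry per transcript.
#' @export
transcript_seqs <- function(bundle) {
  tx <- bundle$transcripts
  segs <- Biostrings::DNAStringSet(bundle$chroms[tx$chrom],
                                   start = tx$start, end = tx$end)
  minus <- tx$strand == "-"
  if (any(minus))
    segs[minus] <- Biostrings::reverseComplement(segs[minus])
  names(segs) <- tx$id
  segs
}

## Transcript-coordinate position (1 = TSS) of a genomic base, vectorised.
## `tx` is a transcripts row subset aligned with `gpos`.
tx_position <- function(tx, gpos) {
  ifelse(tx$strand == "+", gpos - tx$start + 1L, tx$end - gpos + 1L)
}

## Genomic position of a transcript-coordinate base, vectorised.
genomic_position <- function(tx, txpos) {
  ifelse(tx$strand == "+", tx$start + txpos - 1L, tx$end - txpos + 1L)
}

## Length of the 5' region: 5'UTR plus first 150 nt of CDS (whole CDS when
## shorter).
fivep_region_len <- function(tx, cds_window = 150L) {
  tx$utr5_len + pmin(cds_window, tx$cds_len)
}

## GRanges of full transcript spans (strand-aware), on the bundle's full
## set of sequence levels so overlap queries never mix seqinfo.
transcript_ranges <- function(bundle) {
  tx <- bundle$transcripts
  GenomicRanges::GRanges(factor(tx$chrom, levels = names(bundle$chroms)),
                         IRanges::IRanges(tx$start, tx$end),
                         strand = tx$strand, id = tx$id)
}

#' Write a genome bundle as FASTA and GFF3
#'
#' GFF3 features use 1-based inclusive coordinates with
#' `five_prime_UTR`/`CDS`/`three_prime_UTR` children per mRNA and an `rRNA`
#' feature for the background locus.
#'
#' @param bundle a `genome_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`fasta`, `gff3`).
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "transcripts.gff3")
  Biostrings::writeXStringSet(bundle$chroms, fasta)

  tx <- bundle$transcripts
  feat <- function(kind, off0, len) {
    ## feature occupying transcript coordinates [off0+1, off0+len]
    s <- genomic_position(tx, off0 + 1L)
    e <- genomic_position(tx, off0 + len)
    data.frame(chrom = tx$chrom,
               start = pmin(s, e), end = pmax(s, e),
               strand = tx$strand, type = kind,
               ID = paste0(tx$id, ":", kind),
               Parent = tx$id, keep = len > 0,
               stringsAsFactors = FALSE)
  }
  parts <- rbind(
    data.frame(chrom = tx$chrom, start = tx$start, end = tx$end,
               strand = tx$strand, type = "mRNA", ID = tx$id,
               Parent = NA_character_, keep = TRUE,
               stringsAsFactors = FALSE),
    feat("five_prime_UTR", 0L, tx$utr5_len),
    feat("CDS", tx$utr5_len, tx$cds_len),
    feat("three_prime_UTR", tx$utr5_len + tx$cds_len, tx$utr3_len))
  parts <- parts[parts$keep, ]
  gr <- GenomicRanges::GRanges(factor(parts$chrom,
                                      levels = names(bundle$chroms)),
                               IRanges::IRanges(parts$start, parts$end),
                               strand = parts$strand)
  S4Vectors::mcols(gr)$type <- parts$type
  S4Vectors::mcols(gr)$ID <- parts$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(parts$Parent), "", parts$Parent)
  S4Vectors::mcols(gr)$phase <- ifelse(parts$type == "CDS", 0L, NA_integer_)
  if (!is.null(bundle$rrna)) {
    rg <- GenomicRanges::GRanges(factor(bundle$rrna$chrom,
                                        levels = names(bundle$chroms)),
                                 IRanges::IRanges(bundle$rrna$start,
                                                  bundle$rrna$end),
                                 strand = bundle$rrna$strand)
    S4Vectors::mcols(rg)$type <- "rRNA"
    S4Vectors::mcols(rg)$ID <- "rRNA_background"
    S4Vectors::mcols(rg)$Parent <- ""
    S4Vectors::mcols(rg)$phase <- NA_integer_
    gr <- c(gr, rg)
  }
  gr <- sort(gr, ignore.strand = TRUE)
  rtracklayer::export.gff3(gr, gff3)
  invisible(list(fasta = fasta, gff3 = gff3))
}
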