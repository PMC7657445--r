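# Spike-in-anchored RNA-seq quantification. RPM/RPKM normalization only sees
# relative composition; the exogenous spike-in species (constant molar input
# across samples) anchors the scale so that global changes in study mRNA
# abundance become measurable.

## Count reads per transcript (crosslink/5'-base rule or any-overlap) and
## split mapped reads into study vs spike by chromosome.
rnaseq_counts <- function(alignments, bundle, seed = 1) {
  hit <- assign_to_transcripts(alignments, bundle, seed = seed)
  tx <- bundle$transcripts
  counts <- tabulate(hit$tx, nbins = nrow(tx))
  spike_mask <- alignments$chrom %in% bundle$spike_chroms
  list(counts = counts,
       spike_mapped = sum(spike_mask),
       study_mapped = sum(!spike_mask &
                            alignments$chrom %in% tx$chrom[tx$species ==
                                                             "study"]))
}

#' Spike-in scale factors across samples
#'
#' `scale_factor(s) = (spike_share(ref) / study_share(ref)) /
#' (spike_share(s) / study_share(s))`, where shares are spike- and
#' study-mapped read counts. The reference sample has factor 1 by
#' construction; a sample whose spike share doubled (because its study mRNA
#' halved) gets factor 0.5. Share-based factors are invariant to sequencing
#' depth.
#'
#' @param aln_list named list (sample -> alignment data.frame).
#' @param bundle a `genome_bundle` with spike chromosomes.
#' @param reference reference sample name.
#' @return named numeric vector of scale factors.
#' @export
spike_scale_factors <- function(aln_list, bundle, reference) {
  if (!reference %in% names(aln_list))
    stopf("reference sample '%s' missing", reference)
  ratio <- vapply(names(aln_list), function(s) {
    a <- aln_list[[s]]
    spike <- sum(a$chrom %in% bundle$spike_chroms)
    study <- sum(a$chrom %in%
                   bundle$transcripts$chrom[bundle$transcripts$species ==
                                              "study"])
    if (spike == 0) stopf("sample '%s' has zero spike-in reads", s)
    spike / study
  }, numeric(1))
  ratio[reference] / ratio
}

#' Per-transcript abundance (raw counts, RPKM, spike-adjusted RPKM)
#'
#' Counts reads by the 5'-base assignment rule, computes
#' `rpkm = count * 1e9 / (length_nt * study_mapped_reads)` for study
#' transcripts (spike transcripts are normalized against spike-mapped
#' reads), and multiplies by the sample's spike scale factor.
#'
#' @param aln_list named list (sample -> alignment data.frame).
#' @param bundle a `genome_bundle`.
#' @param reference reference sample for the spike factors.
#' @return an `abundance_table` data.frame (transcript, sample, raw_count,
#'   rpkm, adjusted_rpkm) with a `scale_factors` attribute.
#' @export
transcript_abundance <- function(aln_list, bundle, reference) {
  sf <- spike_scale_factors(aln_list, bundle, reference)
  tx <- bundle$transcripts
  rows <- lapply(names(aln_list), function(s) {
    cc <- rnaseq_counts(aln_list[[s]], bundle)
    if (cc$study_mapped == 0) stopf("sample '%s' has zero mapped reads", s)
    denom <- ifelse(tx$species == "study", cc$study_mapped,
                    max(cc$spike_mapped, 1))
    rpkm <- cc$counts * 1e9 / (tx$length * denom)
    data.frame(transcript = tx$id, sample = s,
               raw_count = cc$counts, rpkm = rpkm,
               adjusted_rpkm = rpkm * sf[[s]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale_factors") <- sf
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Select the most-expressed transcripts
#'
#' Ranks study transcripts by mean spike-adjusted RPKM across all samples
#' (descending, ties by id) -- the analog of restricting analyses to the
#' 5,000 most-abundant mRNAs.
#'
#' @param table an `abundance_table`.
#' @param n number of transcripts.
#' @return character vector of transcript ids.
#' @export
select_expressed <- function(table, n = 5000) {
  means <- tapply(table$adjusted_rpkm, table$transcript, mean)
  ord <- order(-means, names(means))
  head(names(means)[ord], n)
}

#' Total mRNA abundance change between two samples
#'
#' Ratio of summed spike-adjusted RPKM over a transcript list -- the
#' spike-anchored estimate of the global change in mRNA content.
#'
#' @param table an `abundance_table`.
#' @param transcripts transcript ids to sum over (non-empty).
#' @param stress,reference sample names.
#' @param adjusted use spike-adjusted values (set FALSE for the
#'   composition-only RPKM ratio).
#' @return the abundance ratio (stress / reference).
#' @export
total_mrna_change <- function(table, transcripts, stress, reference,
                              adjusted = TRUE) {
  if (length(transcripts) == 0) stopf("empty transcript list")
  col <- if (adjusted) "adjusted_rpkm" else "rpkm"
  pick <- function(smp) {
    sub <- table[table$sample == smp, ]
    v <- sub[[col]][match(transcripts, sub$transcript)]
    if (anyNA(v)) stopf("transcript missing from sample '%s'", smp)
    sum(v)
  }
  denom <- pick(reference)
  if (denom == 0) stopf("zero reference abundance")
  pick(stress) / denom
}

#' Per-regulon summaries of transcript-level abundance changes
#'
#' Computes per-transcript `log2((adjusted_rpkm_stress + eps) /
#' (adjusted_rpkm_ref + eps))` with a pseudo-RPKM `eps` guarding lowly
#' expressed transcripts, then summarises (median and quartiles) per
#' regulon (`RP`, `RiBi`, `other`).
#'
#' @param table an `abundance_table`.
#' @param bundle the `genome_bundle` carrying regulon labels.
#' @param stress,reference sample names.
#' @param transcripts optional transcript subset.
#' @param eps pseudo-RPKM (default 0.1).
#' @return list with `per_transcript` (transcript, regulon, log2fc) and
#'   `summary` (regulon, n, q25, median, q75).
#' @export
regulon_summary <- function(table, bundle, stress, reference,
                            transcripts = NULL, eps = 0.1) {
  tx <- bundle$transcripts[bundle$transcripts$species == "study", ]
  ids <- transcripts %||% tx$id
  reg <- tx$regulon[match(ids, tx$id)]
  if (all(is.na(reg))) stopf("no regulon labels among transcripts")
  s <- table[table$sample == stress, ]
  r <- table[table$sample == reference, ]
  lf <- log2((s$adjusted_rpkm[match(ids, s$transcript)] + eps) /
               (r$adjusted_rpkm[match(ids, r$transcript)] + eps))
  per <- data.frame(transcript = ids, regulon = reg, log2fc = lf,
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per, per$regulon), function(g) {
    if (nrow(g) == 0) stopf("empty regulon")
    q <- stats::quantile(g$log2fc, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(regulon = g$regulon[1], n = nrow(g),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_transcript = per, summary = summ)
}
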