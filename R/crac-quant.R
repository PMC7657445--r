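# Transcript-level CRAC binding quantification: total binding (reads whose
# crosslink-proximal base falls anywhere in the transcript) and 5'-end
# binding (reads whose crosslink-proximal base falls in the 5'UTR or the
# first 150 nt of CDS), with pseudocounted reads-per-million normalization,
# top-N target selection, fold changes and the stress-vs-mock t test.

## Crosslink-proximal (5'-most) genomic base of each alignment.
crosslink_base <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end)
}

## Assign each alignment to the transcript containing its crosslink-proximal
## base (sense only); overlaps between transcripts resolve uniformly at
## random under `seed`. Returns data.frame(aln = row index, tx = tx row).
assign_to_transcripts <- function(alignments, bundle, seed = 1) {
  tx <- bundle$transcripts
  base <- crosslink_base(alignments)
  q <- GenomicRanges::GRanges(factor(alignments$chrom,
                                     levels = names(bundle$chroms)),
                              IRanges::IRanges(base, base),
                              strand = alignments$strand)
  s <- transcript_ranges(bundle)
  ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (length(qh) == 0)
    return(data.frame(aln = integer(0), tx = integer(0)))
  n_per <- tabulate(qh, nbins = nrow(alignments))
  multi <- unique(qh[n_per[qh] > 1L])
  if (length(multi) > 0) {
    keep_rows <- which(n_per[qh] == 1L)
    extra <- with_rng(seed, {
      vapply(multi, function(qi) {
        rows <- which(qh == qi)
        rows[sample.int(length(rows), 1L)]
      }, integer(1))
    })
    sel <- sort(c(keep_rows, extra))
  } else {
    sel <- seq_along(qh)
  }
  data.frame(aln = qh[sel], tx = sh[sel])
}

#' Count total and 5'-end binding per transcript for one condition
#'
#' A read is assigned to the transcript whose span contains its
#' crosslink-proximal base (alignment start on `+`, end on `-`, sense
#' strand only). It increments `total_count`, and additionally
#' `fivep_count` iff that base lies in the 5'UTR or the first
#' `fivep_cds_window` nt of the CDS (the whole CDS when shorter). Reads
#' landing in no transcript (e.g. rRNA background) are uncounted but remain
#' part of the mapped library.
#'
#' @param alignments alignment data.frame for one library.
#' @param bundle a `genome_bundle`.
#' @param condition condition label for the new rows.
#' @param table optional existing `binding_table` to append to; reusing a
#'   condition label is an error.
#' @param fivep_cds_window CDS prefix counted as 5' region, nt.
#' @param seed seed for resolving transcript-overlap ties.
#' @return a `binding_table` data.frame (transcript, condition, total_count,
#'   fivep_count) with a `libraries` attribute recording per-condition
#'   mapped and transcript-assigned read counts.
#' @export
count_transcript_binding <- function(alignments, bundle, condition,
                                     table = NULL, fivep_cds_window = 150,
                                     seed = 1) {
  libs <- attr(table, "libraries")
  if (!is.null(table) && condition %in% table$condition)
    stopf("condition '%s' already present in the binding table", condition)
  tx <- bundle$transcripts
  hit <- assign_to_transcripts(alignments, bundle, seed = seed)
  base <- crosslink_base(alignments)[hit$aln]
  txrows <- tx[hit$tx, ]
  txpos <- tx_position(txrows, base)
  in5 <- txpos <= fivep_region_len(txrows, fivep_cds_window)
  total <- tabulate(hit$tx, nbins = nrow(tx))
  fivep <- tabulate(hit$tx[in5], nbins = nrow(tx))
  rows <- data.frame(transcript = tx$id, condition = condition,
                     total_count = total, fivep_count = fivep,
                     stringsAsFactors = FALSE)
  out <- if (is.null(table)) rows else
    rbind(as.data.frame(table)[, names(rows)], rows)
  lib <- data.frame(condition = condition,
                    mapped = nrow(alignments),
                    assigned = nrow(hit),
                    stringsAsFactors = FALSE)
  attr(out, "libraries") <- rbind(libs, lib)
  class(out) <- c("binding_table", "data.frame")
  out
}

#' Pseudocounted reads-per-million normalization of a binding table
#'
#' Adds `total_rpm` and `fivep_rpm`:
#' `(count + pseudocount) * 1e6 / library_size`. The default library size is
#' the total mapped reads of the condition's library (the convention used
#' for the coverage tracks); `library = "assigned"` restricts it to
#' transcript-assigned reads.
#'
#' @param table a `binding_table` with counts.
#' @param pseudocount added to both metrics before scaling (default 3).
#' @param library `"mapped"` or `"assigned"`.
#' @return the table with RPM columns filled.
#' @export
normalize_binding <- function(table, pseudocount = 3,
                              library = c("mapped", "assigned")) {
  library <- match.arg(library)
  libs <- attr(table, "libraries")
  if (is.null(libs)) stopf("binding table lacks library metadata")
  size <- libs[[library]][match(table$condition, libs$condition)]
  if (any(size == 0)) stopf("zero library size")
  table$total_rpm <- (table$total_count + pseudocount) * 1e6 / size
  table$fivep_rpm <- (table$fivep_count + pseudocount) * 1e6 / size
  attr(table, "pseudocount") <- pseudocount
  table
}

#' Select the transcripts most strongly bound in reference conditions
#'
#' Ranks transcripts by the mean `total_rpm` over the reference conditions
#' (descending; ties broken by transcript id) and returns the top `n` -- the
#' analog of restricting analyses to the 2,000 strongest-bound mRNAs under
#' non-stress conditions.
#'
#' @param table a normalized `binding_table`.
#' @param ref_conditions conditions averaged for the ranking.
#' @param n number of transcripts to keep.
#' @return character vector of transcript ids, strongest first.
#' @export
select_top_transcripts <- function(table, ref_conditions = c("control",
                                                             "mock"),
                                   n = 2000) {
  if (!all(ref_conditions %in% table$condition))
    stopf("reference condition missing from the binding table")
  if (is.null(table$total_rpm)) stopf("normalize the table first")
  sub <- table[table$condition %in% ref_conditions, ]
  means <- tapply(sub$total_rpm, sub$transcript, mean)
  ord <- order(-means, names(means))
  head(names(means)[ord], n)
}

#' Per-transcript log2 binding fold changes between two conditions
#'
#' `log2(rpm[stress] / rpm[reference])` for the chosen metric; pseudocounts
#' are already inside the RPM values.
#'
#' @param table a normalized `binding_table`.
#' @param stress,reference condition labels.
#' @param metric `"fivep"` or `"total"`.
#' @param transcripts optional transcript subset (order preserved).
#' @return data.frame with `transcript` and `log2fc`.
#' @export
fold_changes <- function(table, stress, reference,
                         metric = c("fivep", "total"),
                         transcripts = NULL) {
  metric <- match.arg(metric)
  for (cond in c(stress, reference))
    if (!cond %in% table$condition)
      stopf("condition '%s' missing from the binding table", cond)
  col <- paste0(metric, "_rpm")
  if (is.null(table[[col]])) stopf("normalize the table first")
  s <- table[table$condition == stress, ]
  r <- table[table$condition == reference, ]
  ids <- transcripts %||% sort(unique(table$transcript))
  lf <- log2(s[[col]][match(ids, s$transcript)] /
               r[[col]][match(ids, r$transcript)])
  data.frame(transcript = ids, log2fc = lf, stringsAsFactors = FALSE)
}

#' Welch t test comparing two sets of binding fold changes
#'
#' Unpaired, unequal-variance t test on two log2 fold-change samples (the
#' stress-vs-mock comparison). When both samples have zero variance and
#' equal means the result is t = 0, p = 1 by convention.
#'
#' @param fc_stress,fc_mock numeric vectors (length >= 2, finite).
#' @return list with `statistic` and `p_value`.
#' @export
compare_distributions <- function(fc_stress, fc_mock) {
  if (length(fc_stress) < 2 || length(fc_mock) < 2)
    stopf("each sample needs at least two values")
  if (!all(is.finite(fc_stress)) || !all(is.finite(fc_mock)))
    stopf("fold changes must be finite")
  if (stats::var(fc_stress) == 0 && stats::var(fc_mock) == 0) {
    if (mean(fc_stress) == mean(fc_mock))
      return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(fc_stress) - mean(fc_mock)) * Inf,
                p_value = 0))
  }
  tt <- stats::t.test(fc_stress, fc_mock, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}
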