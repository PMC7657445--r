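# Start-codon-anchored metagene profiles, per-transcript binned heatmaps
# sorted by the 5'-versus-pervasive binding ratio, and the pervasive-binding
# fraction statistic.

## Crosslink-proximal bases of alignments in transcript coordinates, for a
## chosen transcript subset. Returns data.frame(tx_idx, txpos) with tx_idx
## indexing `ids`.
crosslink_tx_positions <- function(alignments, bundle, ids, seed = 1) {
  hit <- assign_to_transcripts(alignments, bundle, seed = seed)
  tx <- bundle$transcripts
  keep <- tx$id[hit$tx] %in% ids
  hit <- hit[keep, , drop = FALSE]
  txrows <- tx[hit$tx, ]
  data.frame(tx_idx = match(txrows$id, ids),
             txpos = tx_position(txrows,
                                 crosslink_base(alignments)[hit$aln]))
}

#' Start-codon-anchored metagene binding profile
#'
#' Tallies crosslink-proximal bases at offsets relative to the first CDS
#' base (offset 0 = A of AUG) over a transcript set. With
#' `scale = "transcript"` (the default, standard metagene convention) each
#' transcript's in-window vector is normalised to sum 1, transcripts with
#' no in-window reads are excluded, vectors are averaged with equal weight
#' and the average renormalised -- so highly bound transcripts do not
#' dominate. With `scale = "rpm"` the pooled per-offset counts are scaled
#' by `1e6 / library_size`, which preserves between-condition differences
#' in absolute binding (used to measure stress-induced loss of 5' signal).
#'
#' @param alignments alignment data.frame.
#' @param bundle a `genome_bundle`.
#' @param transcripts transcript ids to include (non-empty).
#' @param upstream,downstream window around the start codon, nt; offsets
#'   run from `-upstream` to `downstream - 1`.
#' @param scale `"transcript"` or `"rpm"`.
#' @param library_size mapped reads for `scale = "rpm"`.
#' @param seed tie-break seed for transcript assignment.
#' @return a `metagene_profile`: list with `offsets`, `density`,
#'   `n_transcripts`.
#' @export
startcodon_profile <- function(alignments, bundle, transcripts,
                               upstream = 200, downstream = 500,
                               scale = c("transcript", "rpm"),
                               library_size = NULL, seed = 1) {
  scale <- match.arg(scale)
  if (length(transcripts) == 0) stopf("empty transcript list")
  tx <- bundle$transcripts[match(transcripts, bundle$transcripts$id), ]
  if (anyNA(tx$id)) stopf("unknown transcript in list")
  pos <- crosslink_tx_positions(alignments, bundle, transcripts, seed)
  offsets <- seq(-upstream, downstream - 1L)
  ## offset of a transcript-coordinate base: txpos - (utr5_len + 1)
  off <- pos$txpos - (tx$utr5_len[pos$tx_idx] + 1L)
  inwin <- off >= -upstream & off < downstream
  pos <- pos[inwin, , drop = FALSE]
  off <- off[inwin]
  if (nrow(pos) == 0)
    return(structure(list(offsets = offsets,
                          density = rep(0, length(offsets)),
                          n_transcripts = 0L),
                     class = "metagene_profile"))
  n_tx_all <- length(transcripts)
  lin <- (off + upstream) * n_tx_all + pos$tx_idx
  counts <- matrix(tabulate(lin, nbins = n_tx_all * length(offsets)),
                   nrow = n_tx_all)
  if (scale == "transcript") {
    rs <- rowSums(counts)
    use <- rs > 0
    dens <- colMeans(counts[use, , drop = FALSE] / rs[use])
    dens <- dens / sum(dens)
    n_tx <- sum(use)
  } else {
    if (is.null(library_size)) stopf("library_size required for rpm scale")
    dens <- colSums(counts) * 1e6 / library_size
    n_tx <- sum(rowSums(counts) > 0)
  }
  structure(list(offsets = offsets, density = dens, n_transcripts = n_tx),
            class = "metagene_profile")
}

#' Mass of a metagene profile inside an offset interval
#'
#' @param profile a `metagene_profile`.
#' @param from,to offset bounds, half-open `[from, to)`.
#' @return the summed density.
#' @export
profile_mass <- function(profile, from, to) {
  sel <- profile$offsets >= from & profile$offsets < to
  sum(profile$density[sel])
}

#' 5'-versus-pervasive binding statistics
#'
#' From raw counts (no pseudocounts): `downstream = total - fivep`,
#' `ratio = fivep / max(downstream, 1)`. A transcript is "pervasive"
#' (Ded1-like) iff it has at least as many downstream as 5' reads;
#' `pervasive_fraction` is the pervasive share of transcripts with at least
#' one read.
#'
#' @param table a `binding_table`.
#' @param condition condition label.
#' @return data.frame (transcript, fivep, downstream, ratio, pervasive)
#'   with attribute `pervasive_fraction`.
#' @export
fivep_pervasive_stats <- function(table, condition) {
  if (!condition %in% table$condition)
    stopf("condition '%s' missing from the binding table", condition)
  sub <- table[table$condition == condition, ]
  down <- sub$total_count - sub$fivep_count
  out <- data.frame(transcript = sub$transcript,
                    fivep = sub$fivep_count,
                    downstream = down,
                    ratio = sub$fivep_count / pmax(down, 1),
                    pervasive = down >= sub$fivep_count,
                    stringsAsFactors = FALSE)
  bound <- sub$total_count >= 1
  attr(out, "pervasive_fraction") <-
    if (any(bound)) mean(out$pervasive[bound]) else NA_real_
  out
}

#' Binned per-transcript binding heatmap sorted by 5'/pervasive ratio
#'
#' Divides each transcript into `bins` equal-length bins, tallies
#' crosslink-proximal bases per bin, row-normalises to sum 1, and orders
#' rows by descending 5'/pervasive ratio (ties by id). Transcripts shorter
#' than `bins` get one bin per base, with a warning.
#'
#' @param alignments alignment data.frame.
#' @param bundle a `genome_bundle`.
#' @param transcripts transcript ids (rows).
#' @param table a `binding_table` used for the row-ordering ratio.
#' @param condition condition label in `table`.
#' @param bins number of bins (>= 2).
#' @param seed tie-break seed for transcript assignment.
#' @return matrix (transcripts x bins) with a `ratio` attribute aligned to
#'   its rows.
#' @export
heatmap_matrix <- function(alignments, bundle, transcripts, table,
                           condition, bins = 50, seed = 1) {
  if (bins < 2) stopf("bins must be >= 2")
  tx <- bundle$transcripts[match(transcripts, bundle$transcripts$id), ]
  if (any(tx$length < bins))
    warning("transcripts shorter than the bin count; bins clipped")
  pos <- crosslink_tx_positions(alignments, bundle, transcripts, seed)
  mat <- matrix(0, nrow = length(transcripts), ncol = bins,
                dimnames = list(transcripts, NULL))
  if (nrow(pos) > 0) {
    b <- pmin(ceiling(pos$txpos / tx$length[pos$tx_idx] * bins), bins)
    b <- pmax(b, 1L)
    lin <- (b - 1L) * length(transcripts) + pos$tx_idx
    mat[] <- tabulate(lin, nbins = length(transcripts) * bins)
  }
  rs <- rowSums(mat)
  mat[rs > 0, ] <- mat[rs > 0, , drop = FALSE] / rs[rs > 0]
  stats <- fivep_pervasive_stats(table, condition)
  ratio <- stats$ratio[match(transcripts, stats$transcript)]
  ord <- order(-ratio, transcripts)
  mat <- mat[ord, , drop = FALSE]
  attr(mat, "ratio") <- ratio[ord]
  mat
}
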