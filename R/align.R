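# Exact-match read placement on the toy genome. The simulator emits
# error-free reads, so a seed-and-verify exact matcher is a faithful stand-in
# for a short-read aligner here; multi-mappers follow the random-assignment
# policy (one location chosen uniformly at random, flagged). Coordinates are
# 1-based inclusive throughout; BED/bedGraph output converts via rtracklayer.

#' Align reads to a genome bundle by exact matching
#'
#' A read maps at every genomic position where it matches the forward or
#' reverse-complement strand exactly (seeded on its first 11 bases, then
#' verified over the full length). Reads matching more than one location get
#' exactly one, chosen uniformly at random from a seeded generator, and are
#' flagged `multimapped`; reads matching nowhere are unmapped.
#'
#' @param reads data.frame with id, sequence (all at least 11 nt).
#' @param bundle a `genome_bundle`.
#' @param seed integer seed for multi-mapper assignment.
#' @return list with `alignments` (data.frame read_id, chrom, strand, start,
#'   end, multimapped; 1-based inclusive) and `unmapped` (count).
#' @export
align_reads <- function(reads, bundle, seed = 1) {
  if (length(bundle$chroms) == 0 || sum(Biostrings::width(bundle$chroms)) == 0)
    stopf("empty genome")
  seed_len <- 11L
  if (any(nchar(reads$sequence) < seed_len))
    stopf("all reads must be at least %d nt for the exact-match engine",
          seed_len)
  idx <- genome_seed_index(bundle, seed_len)
  chrom_seq <- stats::setNames(as.character(bundle$chroms),
                               names(bundle$chroms))

  q <- data.table::data.table(
    ridx = rep(seq_len(nrow(reads)), 2L),
    dir = rep(c("+", "-"), each = nrow(reads)),
    query = c(reads$sequence, revcomp(reads$sequence)))
  q[, kmer := substr(query, 1L, seed_len)]
  hits <- idx[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) > 0) {
    hits[, w := nchar(query)]
    hits[, end := pos + w - 1L]
    hits <- hits[end <= chromlen]
    hits <- hits[substr(chrom_seq[chrom], pos, end) == query]
  }
  aligned <- data.frame(read_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), multimapped = logical(0),
                        stringsAsFactors = FALSE)
  n_mapped <- 0L
  if (nrow(hits) > 0) {
    data.table::setorder(hits, ridx, chrom, pos, dir)
    nh <- hits[, .N, by = ridx]
    chosen <- with_rng(seed, {
      offs <- c(0L, cumsum(nh$N))
      pickrel <- ifelse(nh$N == 1L, 1L,
                        1L + floor(stats::runif(nrow(nh)) * nh$N))
      offs[seq_len(nrow(nh))] + pickrel
    })
    sel <- hits[chosen]
    aligned <- data.frame(
      read_id = reads$id[sel$ridx],
      chrom = sel$chrom,
      strand = sel$dir,
      start = sel$pos,
      end = sel$end,
      multimapped = nh$N > 1L,
      stringsAsFactors = FALSE)
    n_mapped <- nrow(aligned)
  }
  list(alignments = aligned, unmapped = nrow(reads) - n_mapped)
}

## data.table of all forward-strand seed k-mers in the genome.
genome_seed_index <- function(bundle, seed_len) {
  tabs <- lapply(names(bundle$chroms), function(ch) {
    s <- as.character(bundle$chroms[[ch]])
    L <- nchar(s)
    if (L < seed_len) return(NULL)
    data.table::data.table(
      kmer = substring(s, 1:(L - seed_len + 1L), seed_len:L),
      chrom = ch, pos = 1:(L - seed_len + 1L), chromlen = L)
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  idx
}

#' Per-base read coverage with a scaling factor
#'
#' @param alignments alignment data.frame from [align_reads()].
#' @param bundle a `genome_bundle`.
#' @param normalization `"raw"`, `"rpm"` (reads per million aligned), or
#'   `"scaled"` with an externally supplied `scale_factor` (e.g. a spike-in
#'   factor).
#' @param scale_factor factor for `normalization = "scaled"`.
#' @return a `coverage_track`: list with `cov` (per-strand
#'   [S4Vectors::RleList] of raw counts), `scale_factor`, `units`,
#'   `n_alignments`.
#' @export
compute_coverage <- function(alignments, bundle,
                             normalization = c("raw", "rpm", "scaled"),
                             scale_factor = NULL) {
  normalization <- match.arg(normalization)
  if (!all(alignments$chrom %in% names(bundle$chroms)))
    stopf("alignment on unknown chromosome")
  if (normalization == "rpm" && nrow(alignments) == 0)
    stopf("RPM normalization requested with zero aligned reads")
  lens <- stats::setNames(Biostrings::width(bundle$chroms),
                          names(bundle$chroms))
  cov_strand <- function(str) {
    a <- alignments[alignments$strand == str, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      factor(a$chrom, levels = names(lens)),
      IRanges::IRanges(a$start, a$end))
    GenomicRanges::coverage(gr, width = as.list(lens))
  }
  sf <- switch(normalization,
               raw = 1,
               rpm = 1e6 / nrow(alignments),
               scaled = scale_factor %||%
                 stopf("scale_factor required for scaled coverage"))
  structure(list(cov = list("+" = cov_strand("+"), "-" = cov_strand("-")),
                 scale_factor = sf, units = normalization,
                 n_alignments = nrow(alignments)),
            class = "coverage_track")
}

#' Greedy summit calling on a coverage track
#'
#' Selects up to `top_k` highest-coverage positions in a region, suppressing
#' candidates within `min_separation` nt of an already selected summit. Ties
#' break toward the smaller coordinate. Heights are scaled by the track's
#' scale factor.
#'
#' @param track a `coverage_track`.
#' @param chrom,strand where to look.
#' @param region `c(start, end)`, 1-based inclusive; must be non-empty.
#' @param top_k maximum number of summits.
#' @param min_separation minimum distance between summits, nt.
#' @return data.frame with `position` and `height`.
#' @export
find_summits <- function(track, chrom, strand = "+", region, top_k = 1,
                         min_separation = 0) {
  if (length(region) != 2 || region[2] < region[1])
    stopf("empty region")
  rle <- track$cov[[strand]][[chrom]]
  if (is.null(rle)) stopf("no coverage on %s/%s", chrom, strand)
  v <- as.numeric(IRanges::Views(rle, region[1], region[2])[[1]]) *
    track$scale_factor
  pos <- seq(region[1], region[2])
  ord <- order(-v, pos)
  summits <- integer(0); heights <- numeric(0)
  for (i in ord) {
    if (v[i] <= 0) break
    if (length(summits) >= top_k) break
    if (all(abs(pos[i] - summits) >= min_separation)) {
      summits <- c(summits, pos[i])
      heights <- c(heights, v[i])
    }
  }
  data.frame(position = summits, height = heights)
}

#' Write alignments as BED6
#'
#' name = read id, score = 0; converts to BED's 0-based half-open interval
#' convention via rtracklayer.
#'
#' @param alignments alignment data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignments_bed <- function(alignments, path) {
  gr <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(alignments$start,
                                                alignments$end),
                               strand = alignments$strand)
  S4Vectors::mcols(gr)$name <- alignments$read_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a coverage track as bedGraph (one file per strand)
#'
#' Values are raw counts times the track's scale factor.
#'
#' @param track a `coverage_track`.
#' @param prefix output prefix; files are `<prefix>_plus.bedgraph` and
#'   `<prefix>_minus.bedgraph`.
#' @return invisibly, the two paths.
#' @export
write_coverage_bedgraph <- function(track, prefix) {
  out <- character(0)
  for (str in c("+", "-")) {
    suffix <- if (str == "+") "plus" else "minus"
    path <- paste0(prefix, "_", suffix, ".bedgraph")
    rl <- track$cov[[str]]
    gr <- GenomicRanges::bindAsGRanges(score = rl * track$scale_factor)
    gr <- gr[S4Vectors::mcols(gr)$score != 0]
    rtracklayer::export(gr, path, format = "bedGraph")
    out <- c(out, path)
  }
  invisible(out)
}

#' Import alignments from a SAM/BAM-style data.frame or BED file
#'
#' Provided so real aligner output can replace the exact-match engine:
#' accepts a BED6 file (as written by [write_alignments_bed()] or any
#' aligner post-processing) and returns the internal alignment data.frame.
#'
#' @param path BED file path.
#' @return alignment data.frame (multimapped set to NA).
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(read_id = S4Vectors::mcols(gr)$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             multimapped = NA,
             stringsAsFactors = FALSE)
}
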