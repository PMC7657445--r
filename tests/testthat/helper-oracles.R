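# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package: plain per-read loops
# written straight from the rule definitions.

## Trimming oracle: returns list(sequence, keep) applying, in order,
## uncalled-base filter, 3' quality-tail trim, right-end adapter removal
## (full internal match or read-suffix/adapter-prefix overlap >= min_overlap,
## zero mismatches, leftmost cut), and the minimum-length filter.
bf_trim_one <- function(seq, qual, adapter, min_overlap = 4,
                        max_uncalled = 2, min_length = 11,
                        qual_threshold = 20) {
  if (sum(strsplit(seq, "")[[1]] == "N") > max_uncalled)
    return(list(sequence = seq, keep = FALSE, reason = "uncalled"))
  phred <- utf8ToInt(qual) - 33L
  L <- nchar(seq)
  while (L > 0 && phred[L] < qual_threshold) L <- L - 1L
  seq <- substr(seq, 1, L)
  alen <- nchar(adapter)
  cut <- NA_integer_
  for (p in seq_len(L)) {
    ov <- min(alen, L - p + 1L)
    if (ov < min_overlap) break
    if (substr(seq, p, p + ov - 1L) == substr(adapter, 1, ov)) {
      cut <- p
      break
    }
  }
  if (!is.na(cut)) seq <- substr(seq, 1, cut - 1L)
  list(sequence = seq, keep = nchar(seq) >= min_length,
       reason = if (nchar(seq) >= min_length) NA else "short")
}

## Entropy oracle: literal windows-of-k-mers computation.
bf_entropy_one <- function(seq, window = 10, k = 6) {
  L <- nchar(seq)
  if (L < k) return(NA_real_)
  win <- min(window, L)
  wk <- win - k + 1L
  norm <- log(min(wk, 4^k))
  if (norm == 0) return(0)
  kmers <- vapply(1:(L - k + 1L), function(i) substr(seq, i, i + k - 1L),
                  character(1))
  best <- 0
  for (w in 1:(L - win + 1L)) {
    cnt <- table(kmers[w:(w + wk - 1L)])
    p <- cnt / sum(cnt)
    h <- -sum(p * log(p))
    best <- max(best, h)
  }
  best / norm
}

## Duplicate-collapsing oracle.
bf_collapse <- function(umis, seqs) {
  seen <- character(0)
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    key <- paste(umis[i], seqs[i], sep = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      keep[i] <- TRUE
    }
  }
  keep
}

## Counting oracle: loop over alignments, assign by the crosslink-proximal
## base, total + 5' counts per transcript. Overlapping transcripts are not
## present in the toy genomes, so assignment is unambiguous.
bf_count_binding <- function(alignments, transcripts, cds_window = 150) {
  total <- setNames(integer(nrow(transcripts)), transcripts$id)
  fivep <- total
  for (i in seq_len(nrow(alignments))) {
    b <- if (alignments$strand[i] == "+") alignments$start[i]
         else alignments$end[i]
    for (j in seq_len(nrow(transcripts))) {
      tx <- transcripts[j, ]
      if (tx$chrom == alignments$chrom[i] &&
          tx$strand == alignments$strand[i] &&
          b >= tx$start && b <= tx$end) {
        total[j] <- total[j] + 1L
        txpos <- if (tx$strand == "+") b - tx$start + 1L else tx$end - b + 1L
        if (txpos <= tx$utr5_len + min(cds_window, tx$cds_len))
          fivep[j] <- fivep[j] + 1L
        break
      }
    }
  }
  list(total = total, fivep = fivep)
}

## A small deterministic bundle + truth for reuse.
tiny_bundle <- function(n_study = 8, seed = 11, ...) {
  build_toy_genome(n_study = n_study, n_spike = 2, seed = seed, ...)
}

## Manually constructed single-transcript bundle with exact coordinates,
## for boundary tests: one 400-nt '+' transcript (utr5 50, cds 240, utr3
## 110) starting at position 101 on a 700-nt chromosome.
manual_bundle <- function() {
  set.seed(4242)
  chrom <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                 collapse = "")
  b <- structure(list(
    chroms = Biostrings::DNAStringSet(c(chr1 = chrom)),
    transcripts = data.frame(
      id = "TX1", species = "study", chrom = "chr1", strand = "+",
      start = 101L, end = 500L, utr5_len = 50L, cds_len = 240L,
      utr3_len = 110L, length = 400L, regulon = "other",
      stringsAsFactors = FALSE),
    spike_chroms = character(0),
    rrna = NULL), class = "genome_bundle")
  b
}

## Alignment rows for reads whose crosslink-proximal base sits at given
## transcript positions of a manual_bundle() transcript.
manual_alignments <- function(txpos, width = 20, strand = "+") {
  start <- 100L + txpos
  data.frame(read_id = sprintf("r%03d", seq_along(txpos)),
             chrom = "chr1", strand = strand,
             start = start, end = start + width - 1L,
             multimapped = FALSE, stringsAsFactors = FALSE)
}
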