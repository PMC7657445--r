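# CRAC read preprocessing: demultiplexing on in-read barcodes, adapter and
# quality trimming, UMI-based PCR-duplicate collapsing, and low-complexity
# (entropy) filtering. All steps operate on reads data.frames and are
# vectorised so multi-million-read libraries stay practical in R.

#' Demultiplex reads on an in-read sample barcode
#'
#' The read layout is `[umi][barcode][insert...]`. A read is assigned to a
#' sample iff the bases at positions `umi_length+1 .. umi_length+barcode
#' length` match that sample's barcode exactly. The UMI is recorded and the
#' `umi+barcode` prefix is removed from sequence and qualities.
#'
#' @param reads data.frame with id, sequence, qualities.
#' @param barcodes named character vector sample -> barcode; all the same
#'   length and pairwise distinct.
#' @param umi_length random-tag length preceding the barcode.
#' @return list with `samples` (named list of reads data.frames, each with a
#'   `umi` column), `unassigned` (reads data.frame) and `stats`.
#' @export
demultiplex <- function(reads, barcodes, umi_length = 3) {
  if (anyDuplicated(barcodes))
    stopf("duplicate barcode sequences")
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1) stopf("barcodes must all have the same length")
  field <- substr(reads$sequence, umi_length + 1L, umi_length + bl)
  hit <- match(field, barcodes)
  umi <- substr(reads$sequence, 1L, umi_length)
  stripped <- data.frame(
    id = reads$id,
    sequence = substr(reads$sequence, umi_length + bl + 1L,
                      nchar(reads$sequence)),
    qualities = substr(reads$qualities, umi_length + bl + 1L,
                       nchar(reads$qualities)),
    umi = umi,
    stringsAsFactors = FALSE)
  samples <- lapply(seq_along(barcodes), function(i) {
    out <- stripped[which(hit == i), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(samples) <- names(barcodes)
  unassigned <- reads[is.na(hit), , drop = FALSE]
  rownames(unassigned) <- NULL
  stats <- data.frame(sample = names(barcodes),
                      demux_assigned = vapply(samples, nrow, integer(1)),
                      stringsAsFactors = FALSE)
  list(samples = samples, unassigned = unassigned,
       stats = list(input_reads = nrow(reads), per_sample = stats,
                    unassigned = nrow(unassigned)))
}

#' Adapter and quality trimming
#'
#' Applies, in order: (1) discard reads with more than `max_uncalled` N
#' bases; (2) remove the maximal 3' suffix whose base qualities are all
#' below `qual_threshold`; (3) remove the 3' adapter at the right end --
#' truncate at the leftmost position where either the full adapter matches
#' internally or a prefix of the adapter of length >= `min_overlap` matches
#' the read suffix exactly (no mismatches); (4) discard reads shorter than
#' `min_length` after trimming.
#'
#' @param reads data.frame with id, sequence, qualities (and optionally umi).
#' @param adapter adapter sequence; must be at least `min_overlap` long.
#' @param min_overlap minimum adapter/read overlap at the read end.
#' @param max_uncalled maximum number of N bases tolerated.
#' @param min_length minimum surviving read length.
#' @param qual_threshold Phred score below which 3' tail bases are trimmed.
#' @return list with `reads` (trimmed survivors) and `stats`
#'   (`discarded_uncalled`, `discarded_short`, `surviving`).
#' @export
trim_reads <- function(reads, adapter, min_overlap = 4, max_uncalled = 2,
                       min_length = 11, qual_threshold = 20) {
  if (nchar(adapter) < min_overlap)
    stopf("adapter shorter than min_overlap")
  seqs <- reads$sequence
  quals <- reads$qualities

  ## (1) uncalled-base filter
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  bad_n <- n_count > max_uncalled
  n_uncalled <- sum(bad_n)
  keep <- !bad_n
  seqs <- seqs[keep]; quals <- quals[keep]
  kept <- reads[keep, , drop = FALSE]

  ## (2) 3' quality-tail trim: strip the maximal all-low-quality suffix
  if (length(seqs) > 0 && qual_threshold > 0) {
    hi <- intToUtf8(33L + qual_threshold)       # lowest "good" character
    ## characters strictly below threshold are ! .. (hi-1)
    lowclass <- sprintf("[\\x21-\\x%02x]+$", 32L + qual_threshold)
    tail_len <- nchar(quals) -
      nchar(sub(lowclass, "", quals, perl = TRUE))
    newlen <- nchar(seqs) - tail_len
    seqs <- substr(seqs, 1L, newlen)
    quals <- substr(quals, 1L, newlen)
  }

  ## (3) adapter removal at the RIGHT end
  if (length(seqs) > 0) {
    alen <- nchar(adapter)
    len <- nchar(seqs)
    cut <- ifelse(regexpr(adapter, seqs, fixed = TRUE) > 0,
                  regexpr(adapter, seqs, fixed = TRUE), NA_integer_)
    ## read-suffix vs adapter-prefix overlaps, longest (leftmost) first
    for (ov in seq(min(alen - 1L, max(len)), min_overlap)) {
      if (ov < min_overlap) break
      pref <- substr(adapter, 1L, ov)
      cand <- len - ov + 1L
      ok <- cand >= 1L & substr(seqs, cand, len) == pref
      cut <- ifelse(ok & (is.na(cut) | cand < cut), cand, cut)
    }
    trimmed <- !is.na(cut)
    seqs[trimmed] <- substr(seqs[trimmed], 1L, cut[trimmed] - 1L)
    quals[trimmed] <- substr(quals[trimmed], 1L, cut[trimmed] - 1L)
  }

  ## (4) length filter
  long_enough <- nchar(seqs) >= min_length
  n_short <- sum(!long_enough)
  kept <- kept[long_enough, , drop = FALSE]
  kept$sequence <- seqs[long_enough]
  kept$qualities <- quals[long_enough]
  rownames(kept) <- NULL
  list(reads = kept,
       stats = list(input = nrow(reads),
                    discarded_uncalled = n_uncalled,
                    discarded_short = n_short,
                    surviving = nrow(kept)))
}

#' Collapse PCR duplicates on (UMI, sequence)
#'
#' Keeps the first-encountered read of every distinct (umi, sequence) pair,
#' in first-occurrence order. Reads sharing an insert but carrying different
#' random tags are independent molecules and are both retained.
#'
#' @param reads data.frame with a `umi` column.
#' @return list with `reads` (survivors) and `removed` (count).
#' @export
collapse_duplicates <- function(reads) {
  if (is.null(reads$umi)) stopf("reads must carry a umi column")
  dup <- duplicated(paste(reads$umi, reads$sequence, sep = "\r"))
  out <- reads[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, removed = sum(dup))
}

## Entropy of a k-mer count vector, in nats.
.shannon <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}

## Normalised max-over-windows entropy score for one sequence (reference
## implementation; used for short reads and non-default window/k).
.entropy_one <- function(s, threshold, window, k) {
  L <- nchar(s)
  if (L < k) return(NA_real_)                 # too short to score: kept
  win <- min(window, L)
  kmers <- substring(s, 1:(L - k + 1L), k:L)
  wk <- win - k + 1L
  norm <- log(min(wk, 4^k))
  if (norm == 0) return(0)
  n_win <- L - win + 1L
  best <- 0
  for (w in seq_len(n_win)) {
    h <- .shannon(table(kmers[w:(w + wk - 1L)]))
    if (h > best) best <- h
    if (best / norm >= 1) break
  }
  best / norm
}

#' Score reads for sequence complexity (windowed k-mer entropy)
#'
#' For each window of `window` consecutive bases, the Shannon entropy of the
#' window's k-mer frequency distribution is computed and normalised by
#' `log(min(window - k + 1, 4^k))` so it lies in \[0, 1\]; a read's score is
#' the maximum over windows. Reads shorter than `window` are scored on the
#' full read; reads shorter than `k` cannot be scored and get `NA` (kept by
#' [entropy_filter()]). A window admitting a single k-mer scores 0.
#'
#' @param sequences character vector.
#' @param window window width, nt.
#' @param k k-mer size; `k > window` is an error.
#' @return numeric scores in \[0, 1\] (or NA).
#' @export
entropy_score <- function(sequences, window = 10, k = 6) {
  if (k > window) stopf("k must not exceed window")
  L <- nchar(sequences)
  scores <- rep(NA_real_, length(sequences))
  wk <- window - k + 1L

  full <- which(L >= window)
  if (wk == 5L && length(full) > 0) {
    ## fast path for the default geometry: 5 k-mers per window. The window
    ## entropy depends only on the multiset of k-mer counts, which for 5
    ## items is uniquely determined by the number of equal pairs.
    pair_h <- c(log(5), 1.33217904020185, 1.05492016798614,
                0.950270539233235, 0.673011667009257, NA, 0.500402423538188,
                NA, NA, NA, 0)        # entropy by equal-pair count 0..10
    for (Li in unique(L[full])) {
      idx <- full[L[full] == Li]
      nk <- Li - k + 1L
      km <- lapply(seq_len(nk), function(j)
        substr(sequences[idx], j, j + k - 1L))
      ## pairwise equality for all (i, j) with j - i <= 4
      eq <- list()
      for (d in 1:4) for (i in seq_len(nk - d))
        eq[[paste(i, i + d)]] <- km[[i]] == km[[i + d]]
      best <- rep(0, length(idx))
      for (w in seq_len(Li - window + 1L)) {
        p <- rep(0L, length(idx))
        for (d in 1:4) for (i in w:(w + 4L - d))
          p <- p + eq[[paste(i, i + d)]]
        best <- pmax(best, pair_h[p + 1L])
      }
      scores[idx] <- best / log(5)
    }
  } else if (length(full) > 0) {
    scores[full] <- vapply(sequences[full], .entropy_one, numeric(1),
                           threshold = 0, window = window, k = k,
                           USE.NAMES = FALSE)
  }
  short <- which(L < window & L >= k)
  if (length(short) > 0)
    scores[short] <- vapply(sequences[short], .entropy_one, numeric(1),
                            threshold = 0, window = window, k = k,
                            USE.NAMES = FALSE)
  scores
}

#' Remove low-complexity reads
#'
#' Keeps reads whose [entropy_score()] is at least `threshold`; reads too
#' short to score (shorter than `k`) are kept.
#'
#' @param reads data.frame of reads.
#' @param threshold minimum normalised entropy in \[0, 1\].
#' @param window window width, nt.
#' @param k k-mer size.
#' @return list with `reads` (kept), `removed` (count) and `scores`.
#' @export
entropy_filter <- function(reads, threshold = 0.5, window = 10, k = 6) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  scores <- entropy_score(reads$sequence, window = window, k = k)
  keep <- is.na(scores) | scores >= threshold
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, removed = sum(!keep), scores = scores)
}

#' Full CRAC preprocessing pipeline for one multiplexed library
#'
#' Demultiplexes, then per sample trims (uncalled-base filter, quality tail,
#' 3' adapter, length filter), collapses PCR duplicates on (UMI, sequence)
#' and removes low-complexity reads. Counts are conserved per sample:
#' input = unassigned + discarded + duplicates + entropy_removed + surviving.
#'
#' @param reads data.frame of raw reads.
#' @param barcodes named character vector sample -> barcode.
#' @param adapter 3' adapter sequence.
#' @param umi_length random-tag length.
#' @param min_overlap,max_uncalled,min_length,qual_threshold see
#'   [trim_reads()].
#' @param entropy,entropy_window,entropy_k see [entropy_filter()].
#' @return list with `samples` (named list of processed reads data.frames)
#'   and `stats` (per-sample data.frame of stage counts).
#' @export
preprocess_reads <- function(reads, barcodes, adapter,
                             umi_length = 3,
                             min_overlap = 4, max_uncalled = 2,
                             min_length = 11, qual_threshold = 20,
                             entropy = 0.5, entropy_window = 10,
                             entropy_k = 6) {
  dm <- demultiplex(reads, barcodes, umi_length)
  samples <- list()
  stats <- list()
  for (s in names(dm$samples)) {
    raw <- dm$samples[[s]]
    tr <- trim_reads(raw, adapter, min_overlap, max_uncalled,
                     min_length, qual_threshold)
    cd <- collapse_duplicates(tr$reads)
    ef <- entropy_filter(cd$reads, entropy, entropy_window, entropy_k)
    samples[[s]] <- ef$reads
    stats[[s]] <- data.frame(
      sample = s,
      input_reads = nrow(raw),
      discarded_uncalled = tr$stats$discarded_uncalled,
      discarded_short = tr$stats$discarded_short,
      duplicates_removed = cd$removed,
      entropy_removed = ef$removed,
      surviving = nrow(ef$reads),
      stringsAsFactors = FALSE)
  }
  list(samples = samples,
       unassigned = dm$unassigned,
       stats = do.call(rbind, c(stats, list(make.row.names = FALSE))))
}
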