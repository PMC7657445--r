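# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

.datatable.aware <- TRUE

## Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Vectorised random DNA strings.
rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  vapply(seq_len(n),
         function(i) paste(chars[starts[i]:ends[i]], collapse = ""),
         character(1))
}

## Reverse complement for plain character vectors (bulk-safe).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
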