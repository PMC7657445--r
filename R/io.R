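# FASTQ and table I/O. Standard formats go through Biostrings/rtracklayer;
# reads are represented in R as plain data.frames (id, sequence, qualities,
# optionally umi/sample) so the preprocessing steps can be vectorised.

#' Write reads to FASTQ (Phred+33)
#' @param reads data.frame with id, sequence, qualities.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$id
  q <- Biostrings::BStringSet(reads$qualities)
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a reads data.frame
#' @param path FASTQ path.
#' @return data.frame with id, sequence, qualities.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(s),
             sequence = as.character(s),
             qualities = as.character(S4Vectors::mcols(s)$qualities),
             stringsAsFactors = FALSE)
}

#' Read a sample barcode table (sample <TAB> barcode)
#' @param path TSV path, no header.
#' @return named character vector sample -> barcode.
#' @export
read_barcode_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write a list or data.frame as pretty JSON
#' @param x object to serialise.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stats_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
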