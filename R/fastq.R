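# FASTQ i/o for barcode reads, via Biostrings.

#' Read sequences from a FASTQ file
#'
#' Returns the read sequences of a (four-line-record) FASTQ file as a
#' character vector; qualities are ignored since barcode assignment uses
#' sequence only.
#'
#' @param path FASTQ file path (may be gzip-compressed).
#' @return Character vector of read sequences.
#' @export
read_barcode_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write reads to a FASTQ file
#'
#' Writes a character vector of reads as FASTQ with constant placeholder
#' qualities (the screen quantifier does not use quality scores).
#'
#' @param reads Character vector of read sequences.
#' @param path Output file path.
#' @param ids Optional read identifiers (default `read_1 ... read_n`).
#' @return `path`, invisibly.
#' @export
write_barcode_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% sprintf("read_%d", seq_along(reads))
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}
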