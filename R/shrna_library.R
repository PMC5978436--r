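#' Construct an shRNA library
#'
#' An shRNA library maps each short-hairpin construct to the unique DNA
#' barcode embedded in its cassette and to the gene symbol it silences.
#' Pooled screens of the kind this package analyses use libraries with
#' several hairpins per gene (the commercial module emulated here carries
#' 27,500 shRNAs against roughly 5,000 genes, i.e. ~5-6 hairpins/gene).
#'
#' @param shrna_id Character vector of unique construct identifiers.
#' @param barcode Character vector of barcode sequences; all the same length
#'   and drawn from the alphabet A/C/G/T; unique across the library.
#' @param gene Character vector of target gene symbols (many shRNAs may share
#'   a gene).
#' @return A `data.frame` of class `shrna_library` with columns `shrna_id`,
#'   `barcode`, `gene` and attribute `barcode_length`.
#' @export
#' @examples
#' shrna_library(c("sh1", "sh2"), c("ACGT", "TTTT"), c("TP53", "MDM2"))
shrna_library <- function(shrna_id, barcode, gene) {
  shrna_id <- as.character(shrna_id)
  barcode <- toupper(as.character(barcode))
  gene <- as.character(gene)
  n <- length(shrna_id)
  if (length(barcode) != n || length(gene) != n)
    stop("shrna_id, barcode and gene must have equal length")
  if (n == 0L) stop("library must contain at least one shRNA")
  if (anyDuplicated(shrna_id))
    stop("duplicate shrna_id in library")
  if (anyDuplicated(barcode))
    stop("duplicate barcodes in library")
  if (any(grepl("[^ACGT]", barcode)))
    stop("barcodes may only contain A, C, G, T")
  len <- unique(nchar(barcode))
  if (length(len) != 1L)
    stop("all barcodes must have the same length")
  structure(
    data.frame(shrna_id = shrna_id, barcode = barcode, gene = gene,
               stringsAsFactors = FALSE),
    barcode_length = as.integer(len),
    class = c("shrna_library", "data.frame")
  )
}

#' Read / write an shRNA library table
#'
#' Tab-separated file with header columns `shrna_id`, `barcode`, `gene`.
#'
#' @param path File path.
#' @return `read_shrna_library()` returns an [shrna_library()];
#'   `write_shrna_library()` returns `path` invisibly.
#' @export
read_shrna_library <- function(path) {
  tab <- read_tsv_file(path)
  need <- c("shrna_id", "barcode", "gene")
  if (!all(need %in% names(tab)))
    stop("library table must have columns: ", paste(need, collapse = ", "))
  shrna_library(tab$shrna_id, tab$barcode, tab$gene)
}

#' @param library An [shrna_library()].
#' @rdname read_shrna_library
#' @export
write_shrna_library <- function(library, path) {
  stopifnot(inherits(library, "shrna_library"))
  write_tsv_file(as.data.frame(library), path)
}

#' @export
print.shrna_library <- function(x, ...) {
  cat(sprintf("shRNA library: %d shRNAs, %d genes, barcode length %d\n",
              nrow(x), length(unique(x$gene)), attr(x, "barcode_length")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
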