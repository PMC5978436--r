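#' Screen configuration
#'
#' Thresholds and constants for quantifying a pooled shRNA screen. The
#' defaults follow the fold-change convention used throughout this package:
#' an shRNA whose treated/control barcode ratio reaches `up_threshold`
#' (default 1.75) marks its gene drug-*sensitive*, and a ratio at or below
#' `down_threshold` (default 1/1.75, printed as 0.57) marks it
#' drug-*resistant*. Both comparisons are inclusive, which keeps the two
#' calls symmetric under swapping the treated and control pools.
#'
#' @param up_threshold Enrichment call threshold (> 1).
#' @param down_threshold Depletion call threshold (< 1).
#' @param pseudocount Added to both normalized abundances before the ratio,
#'   so zero counts yield a finite fold change; 0 disables it.
#' @param max_mismatch Maximum Hamming distance allowed when assigning a read
#'   to a barcode; 0 means exact prefix match only.
#' @param normalization_scale Normalized abundances per condition sum to this
#'   value (default counts-per-million).
#' @return A list of class `screen_config`.
#' @export
#' @examples
#' screen_config()$down_threshold  # 1/1.75 = 0.57 at printed precision
screen_config <- function(up_threshold = 1.75,
                          down_threshold = 1 / 1.75,
                          pseudocount = 0.5,
                          max_mismatch = 0L,
                          normalization_scale = 1e6) {
  stopifnot(up_threshold > 1, down_threshold > 0, down_threshold < 1,
            pseudocount >= 0, max_mismatch >= 0, normalization_scale > 0)
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 pseudocount = pseudocount,
                 max_mismatch = as.integer(max_mismatch),
                 normalization_scale = normalization_scale),
            class = "screen_config")
}

#' Per-shRNA barcode counts for one condition
#'
#' Container enforcing the read-accounting invariant: counts assigned to
#' library shRNAs plus unassigned reads equal the total reads seen.
#'
#' @param counts Named non-negative integer vector, one entry per library
#'   shRNA (names are `shrna_id`s).
#' @param condition Condition label, `"treated"` or `"control"`.
#' @param total_reads Total reads in the sample (defaults to `sum(counts) +
#'   unassigned_reads`).
#' @param unassigned_reads Reads not assigned to any barcode.
#' @return A list of class `barcode_counts`.
#' @export
barcode_counts <- function(counts, condition = c("treated", "control"),
                           total_reads = NULL, unassigned_reads = 0L) {
  condition <- match.arg(condition)
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("counts must be uniquely named by shrna_id")
  if (any(counts < 0)) stop("counts must be non-negative")
  total_reads <- total_reads %||% (sum(counts) + unassigned_reads)
  if (sum(counts) + unassigned_reads != total_reads)
    stop("accounting violated: assigned + unassigned != total reads")
  structure(list(counts = counts, condition = condition,
                 total_reads = total_reads,
                 unassigned_reads = unassigned_reads),
            class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat(sprintf("barcode counts (%s): %d shRNAs, %s reads (%s unassigned)\n",
              x$condition, length(x$counts),
              format(x$total_reads, big.mark = ","),
              format(x$unassigned_reads, big.mark = ",")))
  invisible(x)
}

#' Count barcode reads against an shRNA library
#'
#' Assigns each sequencing read to at most one shRNA by matching the first
#' `barcode_length` bases of the read against the library barcodes. With
#' `max_mismatch = 0` the match must be exact; with `max_mismatch = m > 0` a
#' read is assigned to the *unique* barcode within Hamming distance `m` —
#' a read with two or more barcodes inside that distance (even if one
#' match is exact) is ambiguous and left unassigned. Reads shorter than
#' the barcode length are counted as unassigned, not an error.
#'
#' @param reads Character vector of read sequences (e.g. from
#'   [read_barcode_fastq()]).
#' @param library An [shrna_library()].
#' @param config A [screen_config()].
#' @param condition Condition label for the resulting counts.
#' @return A [barcode_counts()] object covering every library shRNA.
#' @export
#' @examples
#' lib <- shrna_library(c("B1", "B2"), c("ACGT", "TTTT"), c("g1", "g2"))
#' extract_barcodes(c("ACGTAA", "TTTTGG", "ACGTCC"), lib)$counts
extract_barcodes <- function(reads, library, config = screen_config(),
                             condition = c("treated", "control")) {
  condition <- match.arg(condition)
  stopifnot(inherits(library, "shrna_library"))
  if (anyDuplicated(library$barcode)) stop("duplicate barcodes in library")
  L <- attr(library, "barcode_length")
  reads <- as.character(reads)
  usable <- !is.na(reads) & nchar(reads) >= L
  prefix <- toupper(substr(reads[usable], 1L, L))
  m <- config$max_mismatch
  if (m == 0L) {
    idx <- match(prefix, library$barcode)
  } else {
    # a read is assigned iff exactly one barcode lies within distance m;
    # an exact match shadowed by a second near barcode is ambiguous
    todo <- unique(prefix)
    bmat <- matrix(unlist(strsplit(library$barcode, "", fixed = TRUE),
                          use.names = FALSE),
                   nrow = nrow(library), byrow = TRUE)
    resolved <- vapply(todo, function(p) {
      pc <- strsplit(p, "", fixed = TRUE)[[1L]]
      d <- rowSums(bmat != matrix(pc, nrow(bmat), L, byrow = TRUE))
      hit <- which(d <= m)
      if (length(hit) == 1L) hit else NA_integer_
    }, integer(1))
    idx <- resolved[match(prefix, todo)]
  }
  counts <- tabulate(idx, nbins = nrow(library))
  names(counts) <- library$shrna_id
  barcode_counts(counts, condition = condition,
                 total_reads = length(reads),
                 unassigned_reads = length(reads) - sum(counts))
}

#' Scale counts to a common library size
#'
#' Normalizes the assigned counts of one condition by total-count scaling so
#' that treated/control ratios are comparable: each shRNA's abundance is its
#' count divided by the condition's assigned total, times
#' `normalization_scale` (counts-per-million by default). Abundances always
#' sum to `normalization_scale`.
#'
#' @param counts A [barcode_counts()] object or a named numeric vector.
#' @param config A [screen_config()].
#' @return Named numeric vector of normalized abundances.
#' @export
normalize_counts <- function(counts, config = screen_config()) {
  x <- if (inherits(counts, "barcode_counts")) counts$counts else counts
  if (is.null(names(x))) stop("counts must be named by shrna_id")
  total <- sum(x)
  if (total <= 0) stop("all barcode counts are zero: empty sample")
  x / total * config$normalization_scale
}

#' Treated/control fold change per shRNA
#'
#' `FC_i = (treated_i + pseudocount) / (control_i + pseudocount)`, computed
#' on normalized abundances over the same shRNA universe.
#'
#' @param treated,control Named numeric vectors of normalized abundances
#'   covering the same shRNAs.
#' @param config A [screen_config()] supplying the pseudocount.
#' @return Named numeric vector of fold changes, in the order of `treated`.
#' @export
compute_fold_changes <- function(treated, control, config = screen_config()) {
  if (is.null(names(treated)) || is.null(names(control)))
    stop("abundance vectors must be named by shrna_id")
  if (!setequal(names(treated), names(control)) ||
      length(treated) != length(control))
    stop("treated and control cover different shRNA universes")
  control <- control[names(treated)]
  (treated + config$pseudocount) / (control + config$pseudocount)
}

#' Classify shRNAs by fold change
#'
#' `sensitive` iff `FC >= up_threshold`; `resistant` iff
#' `FC <= down_threshold`; otherwise `neutral`. The three classes partition
#' all shRNAs.
#'
#' @param fold_changes Named numeric vector from [compute_fold_changes()].
#' @param config A [screen_config()].
#' @return Named character vector of classes.
#' @export
classify_shrnas <- function(fold_changes, config = screen_config()) {
  if (any(!is.na(fold_changes) & fold_changes < 0))
    stop("fold changes must be positive")
  cls <- ifelse(fold_changes >= config$up_threshold, "sensitive",
         ifelse(fold_changes <= config$down_threshold, "resistant",
                "neutral"))
  stats::setNames(as.character(cls), names(fold_changes))
}

#' Aggregate shRNA classes to gene-level calls
#'
#' A gene is called `sensitive` if at least one of its shRNAs is sensitive
#' and none resistant, `resistant` if at least one is resistant and none
#' sensitive, `discordant` if it has shRNAs of both classes (excluded from
#' both hit lists), and `neutral` otherwise. Supporting shRNA ids are the
#' hairpins carrying the winning call (all non-neutral hairpins for a
#' discordant gene).
#'
#' @param shrna_classes Named character vector from [classify_shrnas()].
#' @param library The [shrna_library()] mapping shRNAs to genes.
#' @return `data.frame` with columns `gene`, `class`, `n_shrnas`,
#'   `supporting_shrnas` (comma-separated ids).
#' @export
aggregate_to_genes <- function(shrna_classes, library) {
  stopifnot(inherits(library, "shrna_library"))
  ids <- names(shrna_classes)
  gene <- library$gene[match(ids, library$shrna_id)]
  if (anyNA(gene))
    stop("shRNAs not present in library: ",
         paste(utils::head(ids[is.na(gene)]), collapse = ", "))
  by_gene <- split(seq_along(ids), gene)
  rows <- lapply(names(by_gene), function(g) {
    i <- by_gene[[g]]
    cls <- shrna_classes[i]
    has_s <- any(cls == "sensitive")
    has_r <- any(cls == "resistant")
    call <- if (has_s && has_r) "discordant"
            else if (has_s) "sensitive"
            else if (has_r) "resistant"
            else "neutral"
    support <- switch(call,
      sensitive = ids[i][cls == "sensitive"],
      resistant = ids[i][cls == "resistant"],
      discordant = ids[i][cls != "neutral"],
      character(0))
    data.frame(gene = g, class = call, n_shrnas = length(i),
               supporting_shrnas = paste(support, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify a pooled shRNA screen end to end
#'
#' Normalizes treated and control counts (averaging normalized abundances
#' over replicates, if lists of counts are given), computes per-shRNA fold
#' changes, classifies shRNAs, and aggregates to gene-level calls.
#'
#' @param library An [shrna_library()].
#' @param treated,control A [barcode_counts()] object, or a list of them
#'   (replicates).
#' @param config A [screen_config()].
#' @return A list of class `screen_result` with elements `shrna` (per-shRNA
#'   table: `shrna_id`, `gene`, `treated_norm`, `control_norm`, `fc`,
#'   `class`), `gene` (gene-level table from [aggregate_to_genes()]) and
#'   `config`.
#' @export
quantify_screen <- function(library, treated, control,
                            config = screen_config()) {
  stopifnot(inherits(library, "shrna_library"))
  norm_mean <- function(x) {
    if (inherits(x, "barcode_counts")) x <- list(x)
    mats <- vapply(x, function(ct) {
      v <- normalize_counts(ct, config)
      if (!setequal(names(v), library$shrna_id))
        stop("counts do not cover the library's shRNAs")
      v[library$shrna_id]
    }, numeric(nrow(library)))
    rowMeans(as.matrix(mats))
  }
  t_norm <- norm_mean(treated)
  c_norm <- norm_mean(control)
  fc <- compute_fold_changes(t_norm, c_norm, config)
  cls <- classify_shrnas(fc, config)
  shrna_tab <- data.frame(shrna_id = library$shrna_id, gene = library$gene,
                          treated_norm = unname(t_norm),
                          control_norm = unname(c_norm),
                          fc = unname(fc), class = unname(cls),
                          stringsAsFactors = FALSE)
  structure(list(shrna = shrna_tab,
                 gene = aggregate_to_genes(cls, library),
                 config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cs <- table(factor(x$shrna$class,
                     levels = c("sensitive", "neutral", "resistant")))
  cg <- table(factor(x$gene$class,
                     levels = c("sensitive", "neutral", "resistant",
                                "discordant")))
  cat(sprintf("screen result: %d shRNAs / %d genes\n",
              nrow(x$shrna), nrow(x$gene)))
  cat(sprintf("  shRNAs: %d sensitive (FC >= %.2f), %d resistant (FC <= %.2f), %d neutral\n",
              cs[["sensitive"]], x$config$up_threshold,
              cs[["resistant"]], x$config$down_threshold, cs[["neutral"]]))
  cat(sprintf("  genes : %d sensitive, %d resistant, %d discordant, %d neutral\n",
              cg[["sensitive"]], cg[["resistant"]], cg[["discordant"]],
              cg[["neutral"]]))
  invisible(x)
}

#' Read or write screen count / result tables
#'
#' `read_counts_table()` reads a two-column TSV (`shrna_id`, `count`);
#' shRNAs absent from the table get a zero count, unknown shRNAs are an
#' error. `write_screen_result()` writes the per-shRNA table of a
#' [quantify_screen()] result.
#'
#' @param path File path.
#' @param library An [shrna_library()].
#' @param condition Condition label for the counts.
#' @return `read_counts_table()`: a [barcode_counts()].
#' @export
read_counts_table <- function(path, library,
                              condition = c("treated", "control")) {
  condition <- match.arg(condition)
  stopifnot(inherits(library, "shrna_library"))
  tab <- read_tsv_file(path)
  if (!all(c("shrna_id", "count") %in% names(tab)))
    stop("counts table must have columns shrna_id, count")
  unknown <- setdiff(tab$shrna_id, library$shrna_id)
  if (length(unknown))
    stop("counted shRNAs not in library: ",
         paste(utils::head(unknown), collapse = ", "))
  counts <- stats::setNames(rep(0L, nrow(library)), library$shrna_id)
  counts[tab$shrna_id] <- as.integer(tab$count)
  barcode_counts(counts, condition = condition)
}

#' @param counts A [barcode_counts()] to serialize as `shrna_id`, `count`.
#' @rdname read_counts_table
#' @export
write_counts_table <- function(counts, path) {
  stopifnot(inherits(counts, "barcode_counts"))
  write_tsv_file(data.frame(shrna_id = names(counts$counts),
                            count = unname(counts$counts)), path)
}

#' @param result A `screen_result` from [quantify_screen()].
#' @rdname read_counts_table
#' @export
write_screen_result <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  write_tsv_file(result$shrna, path)
}
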