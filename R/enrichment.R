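# Gene-set over-representation by the hypergeometric upper tail.

#' Gene set collection
#'
#' @param sets Named list of character vectors; names are term ids, vectors
#'   are member gene symbols (deduplicated).
#' @param descriptions Optional named character vector of term names.
#' @return A list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("duplicate term ids")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  descriptions <- descriptions %||%
    stats::setNames(names(sets), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene set collection: %d terms, sizes %d-%d (median %g)\n",
              length(x$sets), min(sizes), max(sizes),
              stats::median(sizes)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' One tab-separated line per term: term id, description, then member gene
#' symbols.
#'
#' @param path File path.
#' @return `read_gmt()`: a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L])
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, stats::setNames(desc, ids))
}

#' @param gene_sets A [gene_set_collection()].
#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  lines <- vapply(names(gene_sets$sets), function(id) {
    paste(c(id, gene_sets$descriptions[[id]], gene_sets$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the selected genes overlap the term more
#' than expected when drawing `n` genes from a background of `N` containing
#' `K` term members: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`,
#' computed as the upper tail (`p = 1` when `k = 0`). The test universe is
#' the background restricted to genes annotated in at least one set; genes
#' absent from every set are dropped from both the background and the
#' selection and reported via the `dropped_genes` attribute (the
#' counterpart of genes missing from an annotation service). q-values are
#' Benjamini-Hochberg across the tested terms.
#'
#' @param genes Character vector of selected gene symbols.
#' @param gene_sets A [gene_set_collection()].
#' @param background Character vector: the gene universe (typically all
#'   genes tested in the survival scan, the defensible universe for a
#'   screen-derived selection).
#' @return `data.frame` sorted by p: `term_id`, `term_name`, `k` (overlap),
#'   `K` (term size in universe), `n` (selection size in universe), `N`
#'   (universe size), `p`, `q`. Attribute `dropped_genes` lists selected
#'   genes outside every set.
#' @export
#' @examples
#' gs <- gene_set_collection(list(T1 = c("a", "b", "c", "d")))
#' hypergeom_enrichment(c("a", "b", "c", "d", "e"), gs,
#'                      background = letters[1:10])
hypergeom_enrichment <- function(genes, gene_sets, background) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  genes <- unique(as.character(genes))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background universe")
  if (length(genes) == 0L) stop("empty gene selection")
  genes <- intersect(genes, background)
  if (length(genes) == 0L)
    stop("no selected gene is present in the background")
  annotated <- unique(unlist(gene_sets$sets, use.names = FALSE))
  universe <- intersect(background, annotated)
  sel <- intersect(genes, universe)
  dropped <- setdiff(genes, universe)
  if (length(universe) == 0L || length(sel) == 0L)
    stop("no selected gene is annotated in any gene set")
  N <- length(universe)
  n <- length(sel)
  rows <- lapply(names(gene_sets$sets), function(id) {
    members <- intersect(gene_sets$sets[[id]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, sel))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = gene_sets$descriptions[[id]],
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the background universe")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- dropped
  out
}
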