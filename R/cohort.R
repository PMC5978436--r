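# Cohort preparation: per-sample QC, log2 transform, median dichotomization.

QC_METRICS <- c("background", "rawq", "percent_present", "scaling_factor",
                "gapdh_ratio", "actin_ratio")

#' Per-sample microarray QC thresholds
#'
#' One bound per QC metric, applied to a precomputed per-sample metrics
#' table. The defaults reproduce a standard MAS 5.0 QC list: background
#' < 120, RawQ < 10, percent present calls < 55, scaling factor < 3,
#' GAPDH 3'/5' ratio < 5, beta-actin 3'/5' ratio < 5. Every comparison is
#' strict and, as printed in that list, an *upper* bound — including percent
#' present calls, where a lower bound would be conventional; the direction
#' is configurable per metric for that reason.
#'
#' @param background,rawq,percent_present,scaling_factor,gapdh_ratio,actin_ratio
#'   Finite numeric bounds.
#' @param directions Optional named character vector over the metric names
#'   with entries `"<"` (retain iff value strictly below the bound, the
#'   default) or `">"` (retain iff strictly above).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(background = 120, rawq = 10, percent_present = 55,
                          scaling_factor = 3, gapdh_ratio = 5,
                          actin_ratio = 5, directions = NULL) {
  bounds <- c(background = background, rawq = rawq,
              percent_present = percent_present,
              scaling_factor = scaling_factor,
              gapdh_ratio = gapdh_ratio, actin_ratio = actin_ratio)
  if (any(!is.finite(bounds))) stop("all QC bounds must be finite")
  dirs <- stats::setNames(rep("<", length(bounds)), names(bounds))
  if (!is.null(directions)) {
    bad <- setdiff(names(directions), names(bounds))
    if (length(bad)) stop("unknown QC metric: ", paste(bad, collapse = ", "))
    if (!all(directions %in% c("<", ">")))
      stop("directions must be '<' or '>'")
    dirs[names(directions)] <- directions
  }
  structure(list(bounds = bounds, directions = dirs),
            class = "qc_thresholds")
}

#' Apply per-sample QC
#'
#' Partitions a sample annotation table into retained and excluded samples.
#' A sample is retained iff every metric satisfies its bound (strictly, in
#' the configured direction); excluded samples are reported with the names
#' of the failing metrics.
#'
#' @param samples `data.frame` with one row per sample, a `sample_id` column
#'   and one numeric column per QC metric.
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_result`: `retained` and `excluded`
#'   (annotation subsets; `excluded` gains a `failed_metrics` column) and
#'   `thresholds`.
#' @export
apply_qc <- function(samples, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"), is.data.frame(samples))
  metrics <- names(thresholds$bounds)
  miss_col <- setdiff(metrics, names(samples))
  if (length(miss_col))
    stop("samples lack QC metric column(s): ",
         paste(miss_col, collapse = ", "))
  for (m in metrics) {
    bad <- which(!is.finite(samples[[m]]))
    if (length(bad))
      stop(sprintf("sample '%s' is missing QC metric '%s'",
                   samples$sample_id[bad[1L]], m))
  }
  pass <- vapply(metrics, function(m) {
    if (thresholds$directions[[m]] == "<") samples[[m]] < thresholds$bounds[[m]]
    else samples[[m]] > thresholds$bounds[[m]]
  }, logical(nrow(samples)))
  pass <- matrix(pass, nrow = nrow(samples),
                 dimnames = list(NULL, metrics))
  keep <- rowSums(!pass) == 0L
  excluded <- samples[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$failed_metrics <- apply(!pass[!keep, , drop = FALSE], 1L,
                                     function(f)
                                       paste(metrics[f], collapse = ","))
  } else {
    excluded$failed_metrics <- character(0)
  }
  rownames(excluded) <- NULL
  retained <- samples[keep, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained, excluded = excluded,
                 thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %d samples retained, %d excluded\n",
              nrow(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded))
    print(x$excluded[, c("sample_id", "failed_metrics")])
  invisible(x)
}

#' Log2-transform a raw expression matrix
#'
#' Converts raw probe intensities to log2. Any probe with a non-positive
#' (or non-finite) value in any sample is excluded as a whole and listed,
#' so downstream group sizes stay constant across probes.
#'
#' @param matrix Numeric probes-by-samples matrix of raw intensities
#'   (attribute `scale`, if present, must not already be `"log2"`).
#' @return A list: `matrix` (log2 scale, attribute `scale = "log2"`) and
#'   `excluded_probes` (character vector of dropped probe ids).
#' @export
log2_transform <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression must be a numeric matrix")
  if (nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("empty expression matrix")
  if (identical(attr(matrix, "scale"), "log2"))
    stop("matrix is already on the log2 scale")
  bad <- apply(matrix, 1L, function(v) any(!is.finite(v) | v <= 0))
  out <- log2(matrix[!bad, , drop = FALSE])
  attr(out, "scale") <- "log2"
  list(matrix = out,
       excluded_probes = rownames(matrix)[bad] %||% character(0))
}

#' Median split of one probe's expression values
#'
#' Dichotomizes per-sample intensities at the sample median (mean of the two
#' central order statistics for even n). With the default tie rule a sample
#' is `high` iff its value is strictly greater than the median, else `low`;
#' `tie = "ge"` moves values equal to the median into the high group.
#' Probes whose values are all identical cannot be split and are flagged
#' non-informative.
#'
#' @param values Numeric vector (length >= 2) of one probe's intensities.
#' @param tie `"gt"` (default) or `"ge"`.
#' @return A list: `labels` (character `"high"`/`"low"`, named like
#'   `values`; `NULL` when non-informative), `median`, and `informative`.
#' @export
#' @examples
#' median_split(c(1, 2, 3, 4))  # median 2.5; high = {3, 4}
median_split <- function(values, tie = c("gt", "ge")) {
  tie <- match.arg(tie)
  if (length(values) < 2L) stop("median split needs at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  med <- stats::median(values)
  if (all(values == values[1L]))
    return(list(labels = NULL, median = med, informative = FALSE))
  hi <- if (tie == "gt") values > med else values >= med
  labels <- stats::setNames(ifelse(hi, "high", "low"), names(values))
  list(labels = labels, median = med, informative = TRUE)
}

#' Assemble a prepared cohort
#'
#' Binds a log2 expression matrix, its retained sample annotations and a
#' probe-to-gene map into one object, enforcing the one-to-one
#' correspondence between expression columns and annotation rows.
#'
#' @param expression Log2 probes-by-samples matrix (attribute
#'   `scale = "log2"`).
#' @param samples Annotation `data.frame` with columns `sample_id`,
#'   `tp53_status` (`WT`/`Mut`/`unknown`), `os_time` (>= 0), `os_event`
#'   (0/1).
#' @param probe_map `data.frame` with columns `probe_id`, `gene`.
#' @param excluded_samples,excluded_probes Optional records of what QC and
#'   the log2 step removed (kept for reporting).
#' @return A list of class `cohort_table`.
#' @export
cohort_table <- function(expression, samples, probe_map,
                         excluded_samples = NULL, excluded_probes = NULL) {
  if (!identical(attr(expression, "scale"), "log2"))
    stop("cohort expression must be log2 (attribute scale = 'log2')")
  stopifnot(is.data.frame(samples), is.data.frame(probe_map))
  need <- c("sample_id", "tp53_status", "os_time", "os_event")
  if (!all(need %in% names(samples)))
    stop("sample annotations need columns: ", paste(need, collapse = ", "))
  if (!all(samples$tp53_status %in% c("WT", "Mut", "unknown")))
    stop("tp53_status must be WT, Mut or unknown")
  if (any(samples$os_time < 0)) stop("os_time must be non-negative")
  if (!all(samples$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  if (!setequal(colnames(expression), samples$sample_id) ||
      ncol(expression) != nrow(samples))
    stop("expression columns and sample annotations do not correspond")
  expression <- expression[, samples$sample_id, drop = FALSE]
  attr(expression, "scale") <- "log2"
  if (!all(c("probe_id", "gene") %in% names(probe_map)))
    stop("probe_map needs columns probe_id, gene")
  unmapped <- setdiff(rownames(expression), probe_map$probe_id)
  structure(list(expression = expression, samples = samples,
                 probe_map = probe_map,
                 unmapped_probes = unmapped,
                 excluded_samples = excluded_samples,
                 excluded_probes = excluded_probes %||% character(0)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  st <- table(factor(x$samples$tp53_status,
                     levels = c("WT", "Mut", "unknown")))
  cat(sprintf("cohort: %d probes x %d samples (WT %d, Mut %d, unknown %d)\n",
              nrow(x$expression), ncol(x$expression),
              st[["WT"]], st[["Mut"]], st[["unknown"]]))
  cat(sprintf("  excluded: %d samples (QC), %d probes (non-positive values)\n",
              if (is.null(x$excluded_samples)) 0L else nrow(x$excluded_samples),
              length(x$excluded_probes)))
  invisible(x)
}

#' Prepare a survival cohort from raw inputs
#'
#' Convenience wrapper running the full preparation contract: per-sample QC
#' ([apply_qc()]), restriction of the expression matrix to retained samples,
#' log2 transformation with whole-probe exclusion of non-positive values
#' ([log2_transform()]), and assembly into a [cohort_table()].
#'
#' @param expression Raw probes-by-samples matrix.
#' @param samples Annotation table (see [cohort_table()]), including the QC
#'   metric columns.
#' @param probe_map Probe-to-gene map.
#' @param thresholds A [qc_thresholds()].
#' @return A [cohort_table()].
#' @export
prepare_cohort <- function(expression, samples, probe_map,
                           thresholds = qc_thresholds()) {
  qc <- apply_qc(samples, thresholds)
  if (nrow(qc$retained) == 0L) stop("QC excluded every sample")
  expr <- expression[, qc$retained$sample_id, drop = FALSE]
  attr(expr, "scale") <- attr(expression, "scale")
  lt <- log2_transform(expr)
  cohort_table(lt$matrix, qc$retained, probe_map,
               excluded_samples = qc$excluded,
               excluded_probes = lt$excluded_probes)
}

#' Read / write cohort input tables
#'
#' `read_expression_matrix()` reads a TSV whose first column is `probe_id`
#' and remaining columns are samples; `read_sample_annotations()` and
#' `read_probe_map()` read the corresponding annotation tables.
#'
#' @param path File path.
#' @param scale Scale flag recorded on the matrix (`"raw"` or `"log2"`).
#' @return A matrix or `data.frame`, respectively.
#' @export
read_expression_matrix <- function(path, scale = "raw") {
  tab <- read_tsv_file(path)
  if (names(tab)[1L] != "probe_id")
    stop("expression table must start with a probe_id column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$probe_id
  storage.mode(m) <- "double"
  attr(m, "scale") <- scale
  m
}

#' @param matrix Probes-by-samples matrix to serialize.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' @rdname read_expression_matrix
#' @export
read_sample_annotations <- function(path) {
  tab <- read_tsv_file(path)
  need <- c("sample_id", "tp53_status", "os_time", "os_event")
  if (!all(need %in% names(tab)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_expression_matrix
#' @export
read_probe_map <- function(path) {
  tab <- read_tsv_file(path)
  if (!all(c("probe_id", "gene") %in% names(tab)))
    stop("probe map needs columns probe_id, gene")
  tab
}
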