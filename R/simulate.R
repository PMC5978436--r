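# Seeded simulators for every pipeline input, with planted ground truth.
# Each generator draws from its own labelled sub-stream of the user seed
# (see derive_seed), so outputs are byte-identical across re-runs and
# independent of which other generators ran.

#' Screen simulation configuration
#'
#' Emulates the structure of a pooled lentiviral shRNA screen sequenced to
#' deep coverage: a multi-hairpin-per-gene library (5 shRNAs/gene by
#' default, echoing ~27,500 hairpins over ~5,000 genes), negative-binomial
#' barcode counts in one treated and one control pool, and planted
#' sensitive/resistant genes whose treated abundance is multiplied or
#' divided by `effect_fold`.
#'
#' @param n_genes Number of genes in the library.
#' @param shrnas_per_gene Hairpins per gene.
#' @param n_sensitive_planted,n_resistant_planted Numbers of planted hit
#'   genes (all hairpins of a planted gene carry the effect). Ignored when
#'   explicit gene lists are given.
#' @param sensitive_genes,resistant_genes Optional explicit planted gene
#'   symbols (must be disjoint subsets of the library genes).
#' @param effect_fold Planted treated/control mean ratio (> 1; resistant
#'   genes use its reciprocal).
#' @param baseline_mean Mean reads per shRNA per condition.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param barcode_length Barcode length in bases.
#' @param seed Base seed; the generator uses the `"screen"` sub-stream.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 200, shrnas_per_gene = 5,
                              n_sensitive_planted = 10,
                              n_resistant_planted = 10,
                              sensitive_genes = NULL,
                              resistant_genes = NULL,
                              effect_fold = 2.5, baseline_mean = 500,
                              nb_dispersion = 0.01, barcode_length = 18,
                              seed = 1) {
  stopifnot(n_genes >= 1, shrnas_per_gene >= 1, effect_fold > 1,
            baseline_mean > 0, nb_dispersion >= 0, barcode_length >= 1)
  if (is.null(sensitive_genes) || is.null(resistant_genes)) {
    if (n_sensitive_planted + n_resistant_planted > n_genes)
      stop("planted gene counts exceed n_genes")
  }
  structure(list(n_genes = n_genes, shrnas_per_gene = shrnas_per_gene,
                 n_sensitive_planted = n_sensitive_planted,
                 n_resistant_planted = n_resistant_planted,
                 sensitive_genes = sensitive_genes,
                 resistant_genes = resistant_genes,
                 effect_fold = effect_fold, baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion,
                 barcode_length = as.integer(barcode_length), seed = seed),
            class = "screen_sim_config")
}

rcounts <- function(n, mu, phi) {
  if (phi > 0) stats::rnbinom(n, mu = mu, size = 1 / phi)
  else stats::rpois(n, mu)
}

random_barcodes <- function(n, len) {
  if (log(n) > len * log(4))
    stop("barcode length too short for ", n, " unique barcodes")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    chunk <- vapply(seq_len(need * 1.1 + 10), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    out <- unique(c(out, chunk))
  }
  out[seq_len(n)]
}

#' Simulate a pooled shRNA screen
#'
#' Generates a barcoded library, negative-binomial treated/control counts
#' with planted fold-change effects, and a truth table of planted classes.
#' Identical configs (seed included) give bit-identical output.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_simulation`: `library`
#'   ([shrna_library()]), `treated` and `control` ([barcode_counts()]),
#'   `truth` (`data.frame` with `shrna_id`, `gene`, `planted_class`),
#'   `sensitive_genes`, `resistant_genes`, `config`.
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(derive_seed(config$seed, "screen"), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    per <- config$shrnas_per_gene
    gene_of <- rep(genes, each = per)
    ids <- paste0(gene_of, "_sh", rep(seq_len(per), times = config$n_genes))
    lib <- shrna_library(ids,
                         random_barcodes(length(ids),
                                         config$barcode_length),
                         gene_of)
    if (!is.null(config$sensitive_genes) ||
        !is.null(config$resistant_genes)) {
      sens <- config$sensitive_genes %||% character(0)
      res <- config$resistant_genes %||% character(0)
      if (length(intersect(sens, res)))
        stop("a gene cannot be planted both sensitive and resistant")
      if (!all(c(sens, res) %in% genes))
        stop("planted genes must be library genes")
    } else {
      sens <- sample(genes, config$n_sensitive_planted)
      res <- sample(setdiff(genes, sens), config$n_resistant_planted)
    }
    planted <- ifelse(gene_of %in% sens, "sensitive",
               ifelse(gene_of %in% res, "resistant", "neutral"))
    mult <- ifelse(planted == "sensitive", config$effect_fold,
            ifelse(planted == "resistant", 1 / config$effect_fold, 1))
    mu <- config$baseline_mean
    control <- rcounts(length(ids), mu, config$nb_dispersion)
    treated <- rcounts(length(ids), mu * mult, config$nb_dispersion)
    structure(list(
      library = lib,
      treated = barcode_counts(stats::setNames(treated, ids), "treated"),
      control = barcode_counts(stats::setNames(control, ids), "control"),
      truth = data.frame(shrna_id = ids, gene = gene_of,
                         planted_class = planted,
                         stringsAsFactors = FALSE),
      sensitive_genes = sort(sens), resistant_genes = sort(res),
      config = config), class = "screen_simulation")
  })
}

#' Expand barcode counts into synthetic FASTQ reads
#'
#' Materializes a counts object as reads (each barcode repeated `count`
#' times, padded with random bases to `read_length`, shuffled, optionally
#' mixed with unassignable junk reads) — the inverse of
#' [extract_barcodes()], for round-trip testing at small scale.
#'
#' @param counts A [barcode_counts()].
#' @param library The matching [shrna_library()].
#' @param path Output FASTQ path.
#' @param read_length Total read length (>= barcode length).
#' @param n_junk Number of random non-barcode reads to add.
#' @param seed Base seed (sub-stream `"fastq"`).
#' @return `path`, invisibly.
#' @export
counts_to_fastq <- function(counts, library, path, read_length = 40,
                            n_junk = 0, seed = 1) {
  stopifnot(inherits(counts, "barcode_counts"),
            inherits(library, "shrna_library"))
  L <- attr(library, "barcode_length")
  stopifnot(read_length >= L)
  with_seed(derive_seed(seed, "fastq"), {
    bc <- library$barcode[match(names(counts$counts), library$shrna_id)]
    reads <- rep(bc, counts$counts)
    pad <- read_length - L
    if (pad > 0) {
      tails <- vapply(seq_along(reads), function(i)
        paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
              collapse = ""), character(1))
      reads <- paste0(reads, tails)
    }
    if (n_junk > 0) {
      junk <- vapply(seq_len(n_junk), function(i)
        paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
              collapse = ""), character(1))
      junk <- junk[!substr(junk, 1, L) %in% bc]
      reads <- c(reads, junk)
    }
    reads <- sample(reads)
    write_barcode_fastq(reads, path)
  })
}

#' Cohort simulation configuration
#'
#' Emulates a TP53-genotyped tumour expression cohort with overall
#' survival: 200 wild-type and 221 mutant samples by default (the size of
#' the colorectal reference cohort this package's workflow targets),
#' Gaussian log2 probe intensities, exponential survival with independent
#' exponential censoring, and planted probes whose hazard depends on the
#' sample being above the probe's stratum median — exactly the effect the
#' pipeline's dichotomized log-rank test measures. Planted effects act in
#' the WT stratum only (`planted_wt`), with an optional set active in the
#' Mut stratum only (`planted_mut`); Mut survival is otherwise independent
#' of expression.
#'
#' @param n_wt,n_mut Stratum sizes.
#' @param n_probes Number of probes.
#' @param n_prognostic_planted,n_mut_active_planted Planted gene counts
#'   when explicit lists are not given.
#' @param planted_wt,planted_mut Optional named numeric vectors (names =
#'   gene symbols, values = per-group hazard ratios) or character vectors
#'   (all given `hazard_ratio_high`).
#' @param hazard_ratio_high Hazard multiplier for the high-expression group
#'   of a planted probe (default 0.35: high expressors of a protective gene
#'   die at roughly a third the baseline rate).
#' @param baseline_hazard Baseline event rate per month (default 0.01,
#'   median survival ~69 months).
#' @param censoring_rate Rate of the independent exponential censoring
#'   process (default 3/7 of the baseline hazard, i.e. ~30% censoring under
#'   the null).
#' @param qc_failure_count Samples given one failing QC metric; failures
#'   are planted in the WT stratum (so a 200/221 cohort with 3 failures
#'   retains 197/221).
#' @param n_zero_probes Probes given a single zero raw intensity (excluded
#'   by the log2 step); never planted probes.
#' @param n_two_probe_genes Genes measured by two probes (the remaining
#'   probes map 1:1); duplicates are drawn from unplanted genes.
#' @param gene_names Optional gene symbols to use (length
#'   `n_probes - n_two_probe_genes`).
#' @param seed Base seed (sub-stream `"cohort"`).
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_wt = 200, n_mut = 221, n_probes = 400,
                              n_prognostic_planted = 6,
                              n_mut_active_planted = 0,
                              planted_wt = NULL, planted_mut = NULL,
                              hazard_ratio_high = 0.35,
                              baseline_hazard = 0.01,
                              censoring_rate = 0.01 * 3 / 7,
                              qc_failure_count = 0,
                              n_zero_probes = 0,
                              n_two_probe_genes = 0,
                              gene_names = NULL, seed = 1) {
  stopifnot(n_wt >= 2, n_mut >= 2, n_probes >= 1,
            hazard_ratio_high > 0, baseline_hazard > 0,
            censoring_rate >= 0, qc_failure_count >= 0,
            n_zero_probes >= 0, n_two_probe_genes >= 0)
  if (n_two_probe_genes >= n_probes)
    stop("n_two_probe_genes must be smaller than n_probes")
  if (is.null(planted_wt) && is.null(planted_mut) &&
      n_prognostic_planted + n_mut_active_planted >
        n_probes - n_two_probe_genes)
    stop("planted gene counts exceed available genes")
  structure(list(n_wt = n_wt, n_mut = n_mut, n_probes = n_probes,
                 n_prognostic_planted = n_prognostic_planted,
                 n_mut_active_planted = n_mut_active_planted,
                 planted_wt = planted_wt, planted_mut = planted_mut,
                 hazard_ratio_high = hazard_ratio_high,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 qc_failure_count = qc_failure_count,
                 n_zero_probes = n_zero_probes,
                 n_two_probe_genes = n_two_probe_genes,
                 gene_names = gene_names, seed = seed),
            class = "cohort_sim_config")
}

as_planted <- function(x, default_hr) {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  if (is.character(x)) return(stats::setNames(rep(default_hr, length(x)), x))
  stopifnot(is.numeric(x), !is.null(names(x)), all(x > 0))
  x
}

#' Simulate a genotyped survival cohort
#'
#' See [cohort_sim_config()] for the generating model. The returned raw
#' expression matrix is `2^z` for Gaussian log2 intensities `z`, so the
#' pipeline's log2 step recovers the latent values exactly; planted QC
#' failures and zero-intensity probes exercise the preparation filters.
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `cohort_simulation`: `expression` (raw matrix,
#'   attribute `scale = "raw"`), `annotations` (sample table with QC metric
#'   columns), `probe_map`, `truth` (`data.frame` per probe: `probe_id`,
#'   `gene`, `stratum_active` in `{WT, Mut, none}`, `hazard_ratio`,
#'   `expected_direction`), `planted_wt_genes`, `planted_mut_genes`,
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(derive_seed(config$seed, "cohort"), {
    n_probes <- config$n_probes
    n_genes <- n_probes - config$n_two_probe_genes
    genes <- config$gene_names %||% sprintf("G%04d", seq_len(n_genes))
    if (length(genes) != n_genes)
      stop("gene_names must have length n_probes - n_two_probe_genes")

    planted_wt <- as_planted(config$planted_wt, config$hazard_ratio_high)
    planted_mut <- as_planted(config$planted_mut, config$hazard_ratio_high)
    if (is.null(config$planted_wt) && config$n_prognostic_planted > 0) {
      g <- sample(genes, config$n_prognostic_planted)
      planted_wt <- stats::setNames(
        rep(config$hazard_ratio_high, length(g)), g)
    }
    if (is.null(config$planted_mut) && config$n_mut_active_planted > 0) {
      g <- sample(setdiff(genes, names(planted_wt)),
                  config$n_mut_active_planted)
      planted_mut <- stats::setNames(
        rep(config$hazard_ratio_high, length(g)), g)
    }
    planted_genes <- c(names(planted_wt), names(planted_mut))
    if (anyDuplicated(planted_genes))
      stop("a gene cannot be planted in both strata")
    if (!all(planted_genes %in% genes))
      stop("planted genes must be cohort genes")

    # probe map: 1:1, plus second probes for a few unplanted genes
    probe_gene <- genes
    if (config$n_two_probe_genes > 0) {
      pool <- setdiff(genes, planted_genes)
      if (length(pool) < config$n_two_probe_genes)
        stop("not enough unplanted genes for duplicate probes")
      probe_gene <- c(probe_gene, sample(pool, config$n_two_probe_genes))
    }
    probes <- sprintf("P%05d_at", seq_len(n_probes))
    probe_map <- data.frame(probe_id = probes, gene = probe_gene,
                            stringsAsFactors = FALSE)

    sample_id <- c(sprintf("WT_%03d", seq_len(config$n_wt)),
                   sprintf("MUT_%03d", seq_len(config$n_mut)))
    status <- rep(c("WT", "Mut"), c(config$n_wt, config$n_mut))
    n_samp <- length(sample_id)

    mu_probe <- stats::runif(n_probes, 6, 10)
    z <- matrix(stats::rnorm(n_probes * n_samp, mean = mu_probe, sd = 1),
                nrow = n_probes, ncol = n_samp,
                dimnames = list(probes, sample_id))

    # per-sample hazard: baseline times HR^(above stratum median) over the
    # planted probes active in the sample's stratum
    log_h <- rep(log(config$baseline_hazard), n_samp)
    add_effects <- function(log_h, planted, members) {
      for (g in names(planted)) {
        for (pr in probes[probe_gene == g]) {
          v <- z[pr, members]
          hi <- v > stats::median(v)
          log_h[members][hi] <- log_h[members][hi] + log(planted[[g]])
        }
      }
      log_h
    }
    log_h <- add_effects(log_h, planted_wt, which(status == "WT"))
    log_h <- add_effects(log_h, planted_mut, which(status == "Mut"))

    t_event <- stats::rexp(n_samp, rate = exp(log_h))
    t_cens <- if (config$censoring_rate > 0)
      stats::rexp(n_samp, rate = config$censoring_rate) else rep(Inf, n_samp)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    ann <- data.frame(
      sample_id = sample_id, tp53_status = status,
      os_time = os_time, os_event = os_event,
      background = stats::runif(n_samp, 40, 110),
      rawq = stats::runif(n_samp, 2, 8),
      percent_present = stats::runif(n_samp, 35, 54),
      scaling_factor = stats::runif(n_samp, 0.5, 2.5),
      gapdh_ratio = stats::runif(n_samp, 1, 3),
      actin_ratio = stats::runif(n_samp, 1, 3),
      stringsAsFactors = FALSE)
    if (config$qc_failure_count > 0) {
      wt_idx <- which(status == "WT")
      if (config$qc_failure_count > length(wt_idx))
        stop("more QC failures requested than WT samples")
      fail_idx <- sample(wt_idx, config$qc_failure_count)
      metrics <- sample(QC_METRICS, config$qc_failure_count, replace = TRUE)
      bounds <- qc_thresholds()$bounds
      for (j in seq_along(fail_idx))
        ann[fail_idx[j], metrics[j]] <- bounds[[metrics[j]]] * 1.3
    }

    raw <- 2^z
    if (config$n_zero_probes > 0) {
      unplanted_probes <- probes[!probe_gene %in% planted_genes]
      if (config$n_zero_probes > length(unplanted_probes))
        stop("more zero probes requested than unplanted probes")
      zp <- sample(unplanted_probes, config$n_zero_probes)
      raw[cbind(zp, sample(sample_id, config$n_zero_probes,
                           replace = TRUE))] <- 0
    }
    attr(raw, "scale") <- "raw"

    hr <- ifelse(probe_gene %in% names(planted_wt),
                 planted_wt[probe_gene],
          ifelse(probe_gene %in% names(planted_mut),
                 planted_mut[probe_gene], 1))
    stratum_active <- ifelse(probe_gene %in% names(planted_wt), "WT",
                      ifelse(probe_gene %in% names(planted_mut), "Mut",
                             "none"))
    truth <- data.frame(
      probe_id = probes, gene = probe_gene,
      stratum_active = stratum_active, hazard_ratio = unname(hr),
      expected_direction = ifelse(stratum_active == "none", "none",
                           ifelse(hr < 1, "high_better", "low_better")),
      stringsAsFactors = FALSE)

    structure(list(expression = raw, annotations = ann,
                   probe_map = probe_map, truth = truth,
                   planted_wt_genes = sort(names(planted_wt)),
                   planted_mut_genes = sort(names(planted_mut)),
                   config = config),
              class = "cohort_simulation")
  })
}

#' Simulate gene sets with one planted enriched term
#'
#' Random-membership terms in GMT-ready form, except one designated term
#' built to overlap a given gene list.
#'
#' @param genes Gene universe.
#' @param n_terms Number of terms.
#' @param term_size_range Inclusive size range for random terms.
#' @param planted_term_overlap Members of the planted term drawn from
#'   `planted_genes` (0 disables planting; the planted term is then random
#'   like the rest).
#' @param planted_genes Gene list the planted term should be enriched in.
#' @param seed Base seed (sub-stream `"genesets"`).
#' @return A [gene_set_collection()]; attribute `planted_term` names the
#'   planted term id (`"T001"`).
#' @export
simulate_gene_sets <- function(genes, n_terms = 50,
                               term_size_range = c(10, 40),
                               planted_term_overlap = 0,
                               planted_genes = character(0), seed = 1) {
  stopifnot(length(genes) >= max(term_size_range), n_terms >= 1,
            term_size_range[1] >= 1,
            term_size_range[2] >= term_size_range[1])
  if (planted_term_overlap > term_size_range[2])
    stop("planted overlap larger than the maximum term size")
  if (planted_term_overlap > length(planted_genes))
    stop("planted overlap larger than the planted gene list")
  with_seed(derive_seed(seed, "genesets"), {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    ids <- sprintf("T%03d", seq_len(n_terms))
    sets <- lapply(sizes, function(s) sample(genes, s))
    names(sets) <- ids
    if (planted_term_overlap > 0) {
      s <- max(sizes[1L], planted_term_overlap)
      core <- sample(planted_genes, planted_term_overlap)
      filler <- sample(setdiff(genes, core), s - planted_term_overlap)
      sets[[1L]] <- c(core, filler)
    }
    out <- gene_set_collection(
      sets, stats::setNames(sprintf("synthetic process %d",
                                    seq_len(n_terms)), ids))
    attr(out, "planted_term") <- if (planted_term_overlap > 0) ids[1L]
                                 else NA_character_
    out
  })
}
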