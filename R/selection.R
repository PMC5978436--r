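# The defining filter: screen-category genes prognostic in the TP53
# wild-type stratum but not in the mutant stratum.

#' Selection configuration
#'
#' @param alpha Raw log-rank significance level (default 0.05, mirroring a
#'   raw p < 0.05 rule with no multiplicity correction).
#' @param require_direction_concordance If `TRUE`, a sensitive gene must
#'   show `high_better` prognosis in WT and a resistant gene `low_better`;
#'   off by default (direction is reported either way).
#' @param probe_rule How multiple probes of one gene combine: `"any"` (one
#'   significant probe suffices, the default) or `"all"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05,
                             require_direction_concordance = FALSE,
                             probe_rule = c("any", "all")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha,
                 require_direction_concordance =
                   isTRUE(require_direction_concordance),
                 probe_rule = match.arg(probe_rule)),
            class = "selection_config")
}

#' Select genotype-conditional prognostic genes
#'
#' Applies the intersection filter to the screen's sensitive/resistant gene
#' lists: a gene is *selected* iff it is significant (raw log-rank
#' `p < alpha` under the probe rule) in the TP53 wild-type scan AND not
#' significant under the same rule in the mutant scan (and, optionally,
#' shows the expected prognosis direction for its screen class). Genes with
#' no probe tested in the WT scan are reported `untested` and never
#' selected. Significance in each stratum is evaluated over that stratum's
#' tested (`flag == "ok"`) probes.
#'
#' @param screen A `screen_result` from [quantify_screen()], or its
#'   gene-level `data.frame` (columns `gene`, `class`).
#' @param wt_scan,mut_scan Scan tables from [run_survival_scan()] for the
#'   WT and Mut strata; they must cover the same probe universe.
#' @param probe_map `data.frame` with columns `probe_id`, `gene`.
#' @param config A [selection_config()].
#' @return `data.frame` with one row per screen-category gene: `gene`,
#'   `screen_class`, `n_probes`, `n_probes_tested`, `min_wt_p`, `min_mut_p`,
#'   `wt_direction` (direction of the smallest-p WT probe), boolean columns
#'   `wt_significant`, `mut_significant`, `concordant`, `selected`,
#'   `supporting_probes` (WT-significant probe ids), `status`
#'   (`tested`/`untested`).
#' @export
select_prognostic_genes <- function(screen, wt_scan, mut_scan, probe_map,
                                    config = selection_config()) {
  gene_tab <- if (inherits(screen, "screen_result")) screen$gene else screen
  stopifnot(is.data.frame(gene_tab),
            all(c("gene", "class") %in% names(gene_tab)),
            inherits(config, "selection_config"))
  if (!setequal(wt_scan$probe_id, mut_scan$probe_id))
    stop("WT and Mut scans cover different probe universes")
  cand <- gene_tab[gene_tab$class %in% c("sensitive", "resistant"),
                   c("gene", "class")]
  empty <- data.frame(gene = character(0), screen_class = character(0),
                      n_probes = integer(0), n_probes_tested = integer(0),
                      min_wt_p = numeric(0), min_mut_p = numeric(0),
                      wt_direction = character(0),
                      wt_significant = logical(0),
                      mut_significant = logical(0),
                      concordant = logical(0), selected = logical(0),
                      supporting_probes = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) {
    warning("screen produced no sensitive or resistant genes")
    return(empty)
  }
  wt_ok <- wt_scan[wt_scan$flag == "ok", ]
  mut_ok <- mut_scan[mut_scan$flag == "ok", ]
  alpha <- config$alpha
  rule <- if (config$probe_rule == "any") any else all
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    g <- cand$gene[i]
    cls <- cand$class[i]
    probes <- probe_map$probe_id[probe_map$gene == g]
    wt_i <- match(probes, wt_ok$probe_id)
    wt_i <- wt_i[!is.na(wt_i)]
    mut_i <- match(probes, mut_ok$probe_id)
    mut_i <- mut_i[!is.na(mut_i)]
    if (length(wt_i) == 0L) {
      return(data.frame(gene = g, screen_class = cls,
                        n_probes = length(probes), n_probes_tested = 0L,
                        min_wt_p = NA_real_, min_mut_p = NA_real_,
                        wt_direction = NA_character_,
                        wt_significant = FALSE, mut_significant = FALSE,
                        concordant = NA, selected = FALSE,
                        supporting_probes = "", status = "untested",
                        stringsAsFactors = FALSE))
    }
    wt_p <- wt_ok$p[wt_i]
    mut_p <- if (length(mut_i)) mut_ok$p[mut_i] else numeric(0)
    wt_sig <- rule(wt_p < alpha)
    mut_sig <- if (length(mut_p)) rule(mut_p < alpha) else FALSE
    best <- wt_i[which.min(wt_p)]
    wt_dir <- wt_ok$direction[best]
    concordant <- (cls == "sensitive" && wt_dir == "high_better") ||
                  (cls == "resistant" && wt_dir == "low_better")
    selected <- wt_sig && !mut_sig &&
      (!config$require_direction_concordance || concordant)
    data.frame(gene = g, screen_class = cls,
               n_probes = length(probes),
               n_probes_tested = length(wt_i),
               min_wt_p = min(wt_p),
               min_mut_p = if (length(mut_p)) min(mut_p) else NA_real_,
               wt_direction = wt_dir,
               wt_significant = wt_sig, mut_significant = mut_sig,
               concordant = concordant, selected = selected,
               supporting_probes =
                 paste(wt_ok$probe_id[wt_i][wt_p < alpha], collapse = ","),
               status = "tested", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$screen_class, out$min_wt_p), , drop = FALSE]
}

#' Venn-style selection summary
#'
#' Counts, per screen class, the genes tested, the genes prognostic in the
#' WT stratum, and the genes surviving the Mut-non-significant filter —
#' the two-step funnel reported by this kind of study.
#'
#' @param selection Output of [select_prognostic_genes()].
#' @return `data.frame` with one row per screen class.
#' @export
selection_summary <- function(selection) {
  cls <- c("sensitive", "resistant")
  do.call(rbind, lapply(cls, function(k) {
    s <- selection[selection$screen_class == k, ]
    data.frame(screen_class = k,
               n_genes = nrow(s),
               n_tested = sum(s$status == "tested"),
               n_wt_significant = sum(s$wt_significant, na.rm = TRUE),
               n_selected = sum(s$selected, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}
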