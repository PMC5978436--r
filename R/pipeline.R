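# Orchestration of the full workflow: screen -> prepare -> scan WT ->
# scan Mut -> select -> enrich, from a single YAML config.

#' Default configs for a simulated end-to-end study
#'
#' Builds a matched pair of simulator configurations with planted genes
#' wired across stages: ten screen-category genes (five sensitive, five
#' resistant), of which three per class are prognostic in the WT stratum
#' only (sensitive genes protective, resistant genes deleterious), one per
#' class is prognostic in the Mut stratum only, and one per class carries
#' no survival effect. The cohort mirrors the 200 WT / 221 Mut reference
#' design with three QC failures planted in WT (197/221 retained), and the
#' gene sets contain one term enriched in the planted WT-prognostic genes.
#'
#' @param seed Base seed for every generator sub-stream.
#' @return A list: `screen` ([screen_sim_config()]), `cohort`
#'   ([cohort_sim_config()]), `gene_sets` (argument list for
#'   [simulate_gene_sets()]), and the planted gene lists
#'   `expected_selected`, `mut_active`, `null_screen_genes`.
#' @export
default_study_configs <- function(seed = 421) {
  sens <- sprintf("G%04d", 1:5)    # planted screen-sensitive genes
  res <- sprintf("G%04d", 6:10)    # planted screen-resistant genes
  hr <- 0.35
  planted_wt <- c(G0001 = hr, G0002 = hr, G0003 = hr,
                  G0006 = 1 / hr, G0007 = 1 / hr, G0008 = 1 / hr)
  planted_mut <- c(G0004 = hr, G0009 = 1 / hr)
  list(
    screen = screen_sim_config(n_genes = 200, shrnas_per_gene = 5,
                               sensitive_genes = sens,
                               resistant_genes = res, seed = seed),
    cohort = cohort_sim_config(n_wt = 200, n_mut = 221, n_probes = 210,
                               planted_wt = planted_wt,
                               planted_mut = planted_mut,
                               qc_failure_count = 3, n_zero_probes = 5,
                               n_two_probe_genes = 10,
                               gene_names = sprintf("G%04d", 1:200),
                               seed = seed),
    gene_sets = list(n_terms = 40, term_size_range = c(10, 30),
                     planted_term_overlap = 5,
                     planted_genes = names(planted_wt), seed = seed),
    expected_selected = sort(names(planted_wt)),
    mut_active = sort(names(planted_mut)),
    null_screen_genes = c("G0005", "G0010"))
}

#' Write a complete simulated study to disk
#'
#' Runs the three generators and writes every file the pipeline consumes
#' (library, treated/control counts, expression, annotations, probe map,
#' GMT), the truth tables, a ready-to-run pipeline config, and a YAML
#' manifest recording configs, seed and planted gene lists.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Base seed.
#' @param configs Study configs as from [default_study_configs()].
#' @return Invisibly, a list with the file `paths`, the `truth` tables,
#'   the planted gene lists and the `config_file` for [run_pipeline()].
#' @export
simulate_study_files <- function(outdir, seed = 421,
                                 configs = default_study_configs(seed)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  scr <- simulate_screen(configs$screen)
  coh <- simulate_cohort(configs$cohort)
  gs_args <- configs$gene_sets
  gs <- simulate_gene_sets(genes = unique(coh$probe_map$gene),
                           n_terms = gs_args$n_terms,
                           term_size_range = gs_args$term_size_range,
                           planted_term_overlap = gs_args$planted_term_overlap,
                           planted_genes = gs_args$planted_genes,
                           seed = gs_args$seed)

  write_shrna_library(scr$library, pth("library.tsv"))
  write_counts_table(scr$treated, pth("treated_counts.tsv"))
  write_counts_table(scr$control, pth("control_counts.tsv"))
  write_expression_matrix(coh$expression, pth("expression.tsv"))
  write_tsv_file(coh$annotations, pth("annotations.tsv"))
  write_tsv_file(coh$probe_map, pth("probe_map.tsv"))
  write_gmt(gs, pth("gene_sets.gmt"))
  write_tsv_file(scr$truth, pth("truth_screen.tsv"))
  write_tsv_file(coh$truth, pth("truth_cohort.tsv"))

  config <- list(
    inputs = list(library = pth("library.tsv"),
                  treated_counts = pth("treated_counts.tsv"),
                  control_counts = pth("control_counts.tsv"),
                  expression = pth("expression.tsv"),
                  annotations = pth("annotations.tsv"),
                  probe_map = pth("probe_map.tsv"),
                  gene_sets = pth("gene_sets.gmt")),
    screen = list(up_threshold = 1.75, down_threshold = 1 / 1.75,
                  pseudocount = 0.5, max_mismatch = 0),
    qc = as.list(qc_thresholds()$bounds),
    survival = list(median_scope = "stratum", tie = "gt", bh = FALSE),
    selection = list(alpha = 0.05, probe_rule = "any",
                     require_direction_concordance = FALSE),
    enrichment = list(background = "scan"),
    outdir = pth("results"),
    seed = seed)
  yaml::write_yaml(config, pth("config.yaml"))
  yaml::write_yaml(list(seed = seed,
                        planted_sensitive = scr$sensitive_genes,
                        planted_resistant = scr$resistant_genes,
                        planted_wt_prognostic = coh$planted_wt_genes,
                        planted_mut_active = coh$planted_mut_genes,
                        expected_selected = configs$expected_selected,
                        planted_term = attr(gs, "planted_term")),
                   pth("manifest.yaml"))

  invisible(list(
    paths = list(outdir = outdir, config = pth("config.yaml"),
                 manifest = pth("manifest.yaml")),
    truth = list(screen = scr$truth, cohort = coh$truth),
    planted_sensitive = scr$sensitive_genes,
    planted_resistant = scr$resistant_genes,
    planted_wt_genes = coh$planted_wt_genes,
    planted_mut_genes = coh$planted_mut_genes,
    expected_selected = configs$expected_selected,
    planted_term = attr(gs, "planted_term"),
    config_file = pth("config.yaml")))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$inputs))
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("input file not found: ", p)
  config
}

run_stage <- function(report, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  report$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  report$value <- res
  report
}

#' Run the full selection pipeline
#'
#' Executes, in order: screen quantification, cohort preparation, the WT
#' and Mut survival scans, the WT-significant / Mut-non-significant
#' intersection filter, and (when gene sets are supplied and at least one
#' gene is selected) over-representation analysis. Each stage writes its
#' table under `outdir`; a YAML + text run report records per-stage counts,
#' the funnel (Venn) numbers, timings, package version and a config hash.
#' A failure in any stage aborts with the stage name and cause.
#'
#' @param config Path to a YAML config (as written by
#'   [simulate_study_files()]) or the equivalent list. Sections: `inputs`
#'   (paths: `library`, `treated_counts`/`treated_fastq`,
#'   `control_counts`/`control_fastq`, `expression`, `annotations`,
#'   `probe_map`, optional `gene_sets`), `screen`, `qc`, `survival`,
#'   `selection`, `enrichment`, `outdir`.
#' @param outdir Optional override of the config's output directory.
#' @return A list of class `run_report`, invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- load_pipeline_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  rep <- list(timings = list())

  scr_cfg <- do.call(screen_config, config$screen %||% list())
  sel_cfg <- do.call(selection_config, config$selection %||% list())
  qc_thr <- do.call(qc_thresholds, config$qc %||% list())
  surv <- config$survival %||% list()

  # --- screen ---------------------------------------------------------
  rep <- run_stage(rep, "screen", function() {
    lib <- read_shrna_library(config$inputs$library)
    get_counts <- function(cond) {
      cpath <- config$inputs[[paste0(cond, "_counts")]]
      fpath <- config$inputs[[paste0(cond, "_fastq")]]
      if (!is.null(cpath)) read_counts_table(cpath, lib, cond)
      else if (!is.null(fpath))
        extract_barcodes(read_barcode_fastq(fpath), lib, scr_cfg, cond)
      else stop("no ", cond, " counts or FASTQ in config")
    }
    screen <- quantify_screen(lib, get_counts("treated"),
                              get_counts("control"), scr_cfg)
    write_screen_result(screen, out("screen_shrnas.tsv"))
    write_tsv_file(screen$gene, out("screen_genes.tsv"))
    screen
  })
  screen <- rep$value

  # --- prepare --------------------------------------------------------
  rep <- run_stage(rep, "prepare", function() {
    expr <- read_expression_matrix(config$inputs$expression)
    ann <- read_sample_annotations(config$inputs$annotations)
    pmap <- read_probe_map(config$inputs$probe_map)
    cohort <- prepare_cohort(expr, ann, pmap, qc_thr)
    write_tsv_file(cohort$samples, out("samples_retained.tsv"))
    write_tsv_file(cohort$excluded_samples, out("samples_excluded.tsv"))
    writeLines(cohort$excluded_probes, out("probes_excluded.txt"))
    cohort
  })
  cohort <- rep$value

  # --- scans ----------------------------------------------------------
  scan1 <- function(stratum) {
    run_survival_scan(cohort, stratum,
                      median_scope = surv$median_scope %||% "stratum",
                      tie = surv$tie %||% "gt",
                      bh = isTRUE(surv$bh))
  }
  rep <- run_stage(rep, "scan_wt", function() {
    s <- scan1("WT"); write_tsv_file(s, out("scan_WT.tsv")); s
  })
  wt_scan <- rep$value
  rep <- run_stage(rep, "scan_mut", function() {
    s <- scan1("Mut"); write_tsv_file(s, out("scan_Mut.tsv")); s
  })
  mut_scan <- rep$value

  # --- select ---------------------------------------------------------
  rep <- run_stage(rep, "select", function() {
    sel <- select_prognostic_genes(screen, wt_scan, mut_scan,
                                   cohort$probe_map, sel_cfg)
    write_tsv_file(sel, out("selection.tsv"))
    sel
  })
  selection <- rep$value
  selected_genes <- selection$gene[selection$selected]

  # --- enrich ---------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$inputs$gene_sets) && length(selected_genes) > 0) {
    rep <- run_stage(rep, "enrich", function() {
      gs <- read_gmt(config$inputs$gene_sets)
      bg_mode <- (config$enrichment %||% list())$background %||% "scan"
      background <- if (identical(bg_mode, "scan")) {
        tested <- wt_scan$probe_id[wt_scan$flag == "ok"]
        unique(cohort$probe_map$gene[cohort$probe_map$probe_id %in% tested])
      } else unique(cohort$probe_map$gene)
      enr <- hypergeom_enrichment(selected_genes, gs, background)
      write_tsv_file(enr, out("enrichment.tsv"))
      enr
    })
    enrichment <- rep$value
  }

  # --- report ---------------------------------------------------------
  funnel <- selection_summary(selection)
  cfg_file <- out("config_used.yaml")
  yaml::write_yaml(config, cfg_file)
  report <- structure(list(
    version = as.character(utils::packageVersion("p53screen")),
    config_hash = unname(tools::md5sum(cfg_file)),
    counts = list(
      shrnas = nrow(screen$shrna),
      screen_genes = nrow(screen$gene),
      samples_retained = nrow(cohort$samples),
      samples_excluded = nrow(cohort$excluded_samples),
      probes_excluded = length(cohort$excluded_probes),
      probes_tested_wt = sum(wt_scan$flag == "ok"),
      probes_tested_mut = sum(mut_scan$flag == "ok")),
    funnel = funnel,
    selected_genes = sort(selected_genes),
    top_term = if (!is.null(enrichment)) enrichment$term_id[1L]
               else NA_character_,
    timings = rep$timings,
    outdir = outdir), class = "run_report")
  yaml::write_yaml(list(
    version = report$version, config_hash = report$config_hash,
    counts = report$counts,
    funnel = split(funnel[-1], funnel$screen_class),
    selected_genes = report$selected_genes,
    top_term = report$top_term, timings = report$timings),
    out("report.yaml"))
  writeLines(utils::capture.output(print(report)), out("report.txt"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("p53screen run report (v%s, config %s)\n",
              x$version, substr(x$config_hash, 1, 8)))
  cat(sprintf("  screen : %d shRNAs over %d genes\n",
              x$counts$shrnas, x$counts$screen_genes))
  cat(sprintf("  cohort : %d samples retained (%d excluded), %d probes dropped\n",
              x$counts$samples_retained, x$counts$samples_excluded,
              x$counts$probes_excluded))
  cat(sprintf("  scans  : %d probes tested (WT), %d (Mut)\n",
              x$counts$probes_tested_wt, x$counts$probes_tested_mut))
  for (i in seq_len(nrow(x$funnel))) {
    f <- x$funnel[i, ]
    cat(sprintf("  %s: %d screen genes -> %d WT-prognostic -> %d selected\n",
                format(f$screen_class, width = 9), f$n_genes,
                f$n_wt_significant, f$n_selected))
  }
  cat("  selected genes:",
      if (length(x$selected_genes)) paste(x$selected_genes, collapse = ", ")
      else "(none)", "\n")
  if (!is.na(x$top_term))
    cat("  top enriched term:", x$top_term, "\n")
  invisible(x)
}
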