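scan_row <- function(probe_id, p, direction = "high_better",
                     stratum = "WT", flag = "ok") {
  data.frame(probe_id = probe_id, stratum = stratum, n_high = 10L,
             n_low = 10L, median = 8, observed = 1, expected = 2,
             chi2 = 1, p = p, direction = direction, flag = flag,
             stringsAsFactors = FALSE)
}

screen_genes <- function(...) {
  g <- list(...)
  data.frame(gene = names(g), class = unlist(g),
             n_shrnas = 2L, supporting_shrnas = "x",
             stringsAsFactors = FALSE)
}

test_that("the WT-significant / Mut-non-significant filter selects correctly", {
  pmap <- data.frame(probe_id = c("p1", "p2"), gene = c("gA", "gB"),
                     stringsAsFactors = FALSE)
  wt <- rbind(scan_row("p1", 0.03), scan_row("p2", 0.03))
  mut <- rbind(scan_row("p1", 0.40, stratum = "Mut"),
               scan_row("p2", 0.01, stratum = "Mut"))
  sel <- select_prognostic_genes(
    screen_genes(gA = "sensitive", gB = "sensitive"), wt, mut, pmap)
  expect_true(sel$selected[sel$gene == "gA"])   # Mut p = 0.40
  expect_false(sel$selected[sel$gene == "gB"])  # Mut-significant exclusion
  expect_true(sel$mut_significant[sel$gene == "gB"])
})

test_that("the probe rule distinguishes any from all", {
  pmap <- data.frame(probe_id = c("p1", "p2"), gene = c("gA", "gA"),
                     stringsAsFactors = FALSE)
  wt <- rbind(scan_row("p1", 0.03), scan_row("p2", 0.20))
  mut <- rbind(scan_row("p1", 0.50, stratum = "Mut"),
               scan_row("p2", 0.50, stratum = "Mut"))
  scr <- screen_genes(gA = "sensitive")
  sel_any <- select_prognostic_genes(scr, wt, mut, pmap,
                                     selection_config(probe_rule = "any"))
  sel_all <- select_prognostic_genes(scr, wt, mut, pmap,
                                     selection_config(probe_rule = "all"))
  expect_true(sel_any$selected)
  expect_false(sel_all$selected)
  expect_identical(sel_any$supporting_probes, "p1")
})

test_that("selection is monotone in alpha and all implies any", {
  set.seed(51)
  genes <- sprintf("g%02d", 1:30)
  pmap <- data.frame(
    probe_id = sprintf("p%02d", 1:45),
    gene = c(genes, sample(genes, 15)), stringsAsFactors = FALSE)
  wt <- do.call(rbind, lapply(pmap$probe_id, function(p)
    scan_row(p, runif(1), sample(c("high_better", "low_better"), 1))))
  mut <- do.call(rbind, lapply(pmap$probe_id, function(p)
    scan_row(p, runif(1), sample(c("high_better", "low_better"), 1),
             stratum = "Mut")))
  scr <- data.frame(gene = genes,
                    class = rep(c("sensitive", "resistant"), 15),
                    stringsAsFactors = FALSE)

  alphas <- c(0.01, 0.05, 0.2, 0.5)
  sel_by_alpha <- lapply(alphas, function(a)
    select_prognostic_genes(scr, wt, mut, pmap, selection_config(alpha = a)))
  # decreasing alpha never adds a WT-significant gene
  for (i in seq_len(length(alphas) - 1)) {
    wt_lo <- sel_by_alpha[[i]]$gene[sel_by_alpha[[i]]$wt_significant]
    wt_hi <- sel_by_alpha[[i + 1]]$gene[sel_by_alpha[[i + 1]]$wt_significant]
    expect_true(all(wt_lo %in% wt_hi))
  }

  sel_any <- select_prognostic_genes(scr, wt, mut, pmap,
                                     selection_config(probe_rule = "any"))
  sel_all <- select_prognostic_genes(scr, wt, mut, pmap,
                                     selection_config(probe_rule = "all"))
  expect_true(all(sel_all$gene[sel_all$selected] %in%
                    sel_any$gene[sel_any$wt_significant]))
  # every selected gene carries a screen category
  expect_true(all(sel_any$screen_class[sel_any$selected] %in%
                    c("sensitive", "resistant")))
})

test_that("direction concordance and untested genes are handled", {
  pmap <- data.frame(probe_id = c("p1", "p2"), gene = c("gA", "gB"),
                     stringsAsFactors = FALSE)
  wt <- rbind(scan_row("p1", 0.01, direction = "low_better"),
              scan_row("p2", 0.01, direction = "high_better"))
  mut <- rbind(scan_row("p1", 0.8, stratum = "Mut"),
               scan_row("p2", 0.8, stratum = "Mut"))
  scr <- screen_genes(gA = "sensitive", gB = "sensitive", gC = "resistant")
  sel <- select_prognostic_genes(scr, wt, mut, pmap,
    selection_config(require_direction_concordance = TRUE))
  expect_false(sel$selected[sel$gene == "gA"])  # wrong direction
  expect_true(sel$selected[sel$gene == "gB"])
  expect_identical(sel$status[sel$gene == "gC"], "untested")
  expect_false(sel$selected[sel$gene == "gC"])

  expect_warning(
    empty <- select_prognostic_genes(screen_genes(gA = "neutral"),
                                     wt, mut, pmap),
    "no sensitive or resistant")
  expect_identical(nrow(empty), 0L)

  mut_short <- mut[1, ]
  expect_error(select_prognostic_genes(scr, wt, mut_short, pmap),
               "different probe universes")
})

test_that("hypergeometric enrichment matches closed-form examples", {
  # N=10, K=4, n=5, k=4 -> C(4,4) C(6,1) / C(10,5) = 6/252
  universe <- sprintf("g%02d", 1:10)
  gs <- gene_set_collection(list(TERM = universe[1:4], ALL = universe))
  sel <- c(universe[1:4], universe[5])
  res <- hypergeom_enrichment(sel, gs, universe)
  expect_equal(res$p[res$term_id == "TERM"], 6 / 252)
  expect_equal(res[res$term_id == "TERM", c("k", "K", "n", "N")],
               data.frame(k = 4L, K = 4L, n = 5L, N = 10L),
               ignore_attr = TRUE)

  # zero overlap: upper tail at 0 is 1
  gs0 <- gene_set_collection(list(TERM = universe[1:3], ALL = universe))
  res0 <- hypergeom_enrichment(universe[4:6], gs0, universe)
  expect_equal(res0$p[res0$term_id == "TERM"], 1)

  # term identical to the selection with universe = selection: p = 1
  gs1 <- gene_set_collection(list(TERM = universe[1:5]))
  res1 <- hypergeom_enrichment(universe[1:5], gs1, universe[1:5])
  expect_equal(res1$p, 1)

  expect_error(hypergeom_enrichment(character(0), gs, universe), "empty")
  expect_error(hypergeom_enrichment("g01", gs, character(0)), "empty")
})

test_that("unannotated genes are dropped from the universe and reported", {
  universe <- c(sprintf("g%02d", 1:10), "orphan1", "orphan2")
  gs <- gene_set_collection(list(TERM = sprintf("g%02d", 1:4),
                                 ALL = sprintf("g%02d", 1:10)))
  res <- hypergeom_enrichment(c("g01", "g02", "orphan1"), gs, universe)
  expect_identical(attr(res, "dropped_genes"), "orphan1")
  expect_equal(res$N[1], 10L)  # orphans leave the universe too
  expect_equal(res$n[1], 2L)
})

test_that("BH q-values are monotone in p-rank and bounded below by p", {
  set.seed(52)
  universe <- sprintf("g%03d", 1:60)
  sets <- c(lapply(1:15, function(i) sample(universe, sample(5:20, 1))),
            list(universe))
  names(sets) <- c(sprintf("T%02d", 1:15), "ALL")
  gs <- gene_set_collection(sets)
  res <- hypergeom_enrichment(sample(universe, 12), gs, universe)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q) >= -1e-12))  # sorted by p
  expect_true(all(res$k <= pmin(res$K, res$n)))
})

test_that("the funnel summary is consistent with the selection table", {
  set.seed(53)
  genes <- sprintf("g%02d", 1:20)
  pmap <- data.frame(probe_id = sprintf("p%02d", 1:20), gene = genes,
                     stringsAsFactors = FALSE)
  wt <- do.call(rbind, lapply(pmap$probe_id, function(p)
    scan_row(p, runif(1))))
  mut <- do.call(rbind, lapply(pmap$probe_id, function(p)
    scan_row(p, runif(1), stratum = "Mut")))
  scr <- data.frame(gene = genes,
                    class = rep(c("sensitive", "resistant"), 10),
                    stringsAsFactors = FALSE)
  sel <- select_prognostic_genes(scr, wt, mut, pmap)
  fun <- selection_summary(sel)
  for (k in c("sensitive", "resistant")) {
    s <- sel[sel$screen_class == k, ]
    f <- fun[fun$screen_class == k, ]
    expect_identical(f$n_genes, nrow(s))
    expect_identical(f$n_wt_significant, sum(s$wt_significant))
    expect_identical(f$n_selected, sum(s$selected))
    expect_lte(f$n_selected, f$n_wt_significant)
    expect_lte(f$n_wt_significant, f$n_tested)
  }
})
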