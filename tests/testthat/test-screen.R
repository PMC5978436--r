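test_that("barcode assignment follows the unique-within-distance rule", {
  lib <- shrna_library(c("B1", "B2"), c("ACGT", "TTTT"), c("g1", "g2"))

  bc <- extract_barcodes(c("ACGTAA", "TTTTGG", "ACGTCC"), lib)
  expect_identical(unname(bc$counts), c(2L, 1L))
  expect_identical(bc$unassigned_reads, 0L)

  # one mismatch, unique hit
  bc1 <- extract_barcodes("ACGA", lib, screen_config(max_mismatch = 1))
  expect_identical(unname(bc1$counts), c(1L, 0L))

  # equidistant from two barcodes: ambiguous, stays unassigned
  lib2 <- shrna_library(c("B1", "B2"), c("AAAA", "AAAT"), c("g1", "g2"))
  bc2 <- extract_barcodes("AAAC", lib2, screen_config(max_mismatch = 1))
  expect_identical(sum(bc2$counts), 0L)
  expect_identical(bc2$unassigned_reads, 1L)

  # short reads are unassigned, not an error; accounting holds
  bc3 <- extract_barcodes(c("ACG", "ACGT"), lib)
  expect_identical(sum(bc3$counts) + bc3$unassigned_reads, bc3$total_reads)
  expect_identical(bc3$unassigned_reads, 1L)

  expect_error(shrna_library(c("a", "b"), c("ACGT", "ACGT"), c("g", "g")),
               "duplicate barcodes")
})

test_that("barcode assignment matches a brute-force Hamming scan", {
  set.seed(101)
  for (rep_i in 1:15) {
    n_bc <- sample(2:10, 1)
    L <- 6
    bcs <- character(0)
    while (length(bcs) < n_bc)
      bcs <- unique(c(bcs, paste(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = "")))
    lib <- shrna_library(sprintf("sh%02d", seq_len(n_bc)), bcs,
                         sprintf("g%02d", seq_len(n_bc)))
    # reads: mutated barcodes plus random junk plus a short read
    reads <- c(
      vapply(sample(bcs, 60, replace = TRUE), function(b) {
        nmut <- sample(0:2, 1)
        ch <- strsplit(b, "")[[1]]
        pos <- sample(L, nmut)
        ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
        paste(c(ch, sample(c("A", "C", "G", "T"), 4, TRUE)), collapse = "")
      }, character(1)),
      vapply(1:30, function(i)
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
        character(1)),
      "ACG")
    for (m in 0:2) {
      got <- extract_barcodes(reads, lib, screen_config(max_mismatch = m))
      want <- oracle_assign_counts(reads, lib, m)
      expect_identical(unname(got$counts), unname(want$counts))
      expect_identical(got$unassigned_reads, want$unassigned)
    }
  }
})

test_that("normalization scales to a fixed total and preserves ratios", {
  cfg <- screen_config()
  expect_equal(normalize_counts(c(a = 10, b = 30, c = 60), cfg),
               c(a = 1e5, b = 3e5, c = 6e5))
  expect_equal(normalize_counts(c(a = 1), cfg), c(a = 1e6))
  v <- normalize_counts(c(a = 7, b = 13), cfg)
  expect_equal(sum(v), 1e6)
  expect_equal(unname(v["a"] / v["b"]), 7 / 13)
  expect_error(normalize_counts(c(a = 0, b = 0), cfg), "empty sample")

  # conservation on random counts
  set.seed(7)
  for (i in 1:10) {
    x <- stats::setNames(rpois(50, 20) + 1, sprintf("s%02d", 1:50))
    expect_equal(sum(normalize_counts(x, cfg)), cfg$normalization_scale)
  }
})

test_that("fold changes use the pseudocount and hit the 1.75 boundary", {
  cfg0 <- screen_config(pseudocount = 0)
  expect_equal(unname(compute_fold_changes(c(a = 350), c(a = 200), cfg0)),
               1.75)
  expect_equal(unname(compute_fold_changes(c(a = 5), c(a = 5), cfg0)), 1)
  expect_equal(unname(compute_fold_changes(c(a = 0), c(a = 0),
                                           screen_config(pseudocount = 0.5))),
               1)
  expect_error(compute_fold_changes(c(a = 1), c(b = 1), cfg0),
               "different shRNA universes")
})

test_that("classification partitions shRNAs and is monotone and reciprocal", {
  cfg <- screen_config(down_threshold = 0.57)
  expect_identical(unname(classify_shrnas(c(x = 1.75), cfg)), "sensitive")
  expect_identical(unname(classify_shrnas(c(x = 0.57), cfg)), "resistant")
  expect_identical(unname(classify_shrnas(c(x = 1.0), cfg)), "neutral")

  set.seed(11)
  fc <- stats::setNames(exp(rnorm(500, 0, 0.5)), sprintf("s%03d", 1:500))
  cls <- classify_shrnas(fc, screen_config())
  expect_true(all(cls %in% c("sensitive", "resistant", "neutral")))
  # raising the up threshold can only shrink the sensitive set
  for (up in c(1.5, 1.75, 2, 3)) {
    s_lo <- names(fc)[classify_shrnas(fc, screen_config(up_threshold = up)) ==
                        "sensitive"]
    s_hi <- names(fc)[classify_shrnas(
      fc, screen_config(up_threshold = up + 0.5)) == "sensitive"]
    expect_true(all(s_hi %in% s_lo))
  }

  # reciprocity: pseudocount 0 and down = 1/up swaps sensitive/resistant
  # exactly under treated/control exchange
  cfg0 <- screen_config(pseudocount = 0, down_threshold = 1 / 1.75)
  t_ab <- stats::setNames(runif(200, 10, 1000), sprintf("s%03d", 1:200))
  c_ab <- stats::setNames(runif(200, 10, 1000), sprintf("s%03d", 1:200))
  fwd <- classify_shrnas(compute_fold_changes(t_ab, c_ab, cfg0), cfg0)
  rev <- classify_shrnas(compute_fold_changes(c_ab, t_ab, cfg0), cfg0)
  expect_identical(unname(fwd == "sensitive"), unname(rev == "resistant"))
  expect_identical(unname(fwd == "resistant"), unname(rev == "sensitive"))
})

test_that("gene aggregation resolves support and discordance", {
  lib <- shrna_library(c("a1", "a2"), c("AAAA", "CCCC"), c("gA", "gA"))
  g <- aggregate_to_genes(c(a1 = "sensitive", a2 = "neutral"), lib)
  expect_identical(g$class, "sensitive")
  expect_identical(g$supporting_shrnas, "a1")
  g2 <- aggregate_to_genes(c(a1 = "sensitive", a2 = "resistant"), lib)
  expect_identical(g2$class, "discordant")

  # enumerate the rule over all class pairs against an independent oracle
  classes <- c("sensitive", "resistant", "neutral")
  for (c1 in classes) for (c2 in classes) {
    got <- aggregate_to_genes(c(a1 = c1, a2 = c2), lib)$class
    expect_identical(got, oracle_pair_call(c1, c2))
  }
})

test_that("FASTQ round-trips through the extractor at small scale", {
  lib <- shrna_library(sprintf("sh%d", 1:4),
                       c("ACGTAC", "TTTTTT", "GGGCCC", "ATATAT"),
                       sprintf("g%d", 1:4))
  counts <- barcode_counts(c(sh1 = 5L, sh2 = 0L, sh3 = 3L, sh4 = 7L),
                           "treated")
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq), add = TRUE)
  counts_to_fastq(counts, lib, fq, read_length = 12, n_junk = 0, seed = 3)
  reads <- read_barcode_fastq(fq)
  expect_length(reads, 15L)
  back <- extract_barcodes(reads, lib, condition = "treated")
  expect_identical(back$counts, counts$counts)
  expect_identical(back$unassigned_reads, 0L)
})

test_that("replicates are averaged on the normalized scale", {
  lib <- shrna_library(c("s1", "s2"), c("AAAA", "TTTT"), c("g1", "g2"))
  t1 <- barcode_counts(c(s1 = 10L, s2 = 90L), "treated")
  t2 <- barcode_counts(c(s1 = 30L, s2 = 70L), "treated")
  ctl <- barcode_counts(c(s1 = 50L, s2 = 50L), "control")
  res <- quantify_screen(lib, list(t1, t2), ctl,
                         screen_config(pseudocount = 0))
  # mean of (0.1, 0.3) and (0.9, 0.7) of the scale
  expect_equal(res$shrna$treated_norm, c(2e5, 8e5))
  expect_equal(res$shrna$fc, c(2e5 / 5e5, 8e5 / 5e5))
})
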