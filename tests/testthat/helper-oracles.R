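# Independent oracles used across the suite. These deliberately use
# different algorithms from the package code paths they check.

# Brute-force read assignment: all-pairs Hamming scan over every barcode.
oracle_assign_counts <- function(reads, library, max_mismatch) {
  L <- attr(library, "barcode_length")
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  idx <- vapply(reads, function(r) {
    if (is.na(r) || nchar(r) < L) return(NA_integer_)
    p <- toupper(substr(r, 1, L))
    d <- vapply(library$barcode, hamming, numeric(1), a = p)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
  counts <- tabulate(idx, nbins = nrow(library))
  names(counts) <- library$shrna_id
  list(counts = counts, unassigned = sum(is.na(idx)))
}

# Exhaustive hypergeometric upper tail: enumerate every draw of n from N
# with the first K elements marked, and count draws with >= k marked.
enum_hyper_p <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Random small censored cohort with ties, for survival oracle checks.
random_small_cohort <- function(n = 12) {
  repeat {
    time <- sample(1:8, n, replace = TRUE)
    event <- stats::rbinom(n, 1, 0.7)
    group <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(group)) == 2L && sum(event) >= 1) break
  }
  list(time = time, event = event, group = group)
}

# The gene-aggregation rule restated independently as a truth table over a
# pair of shRNA classes.
oracle_pair_call <- function(c1, c2) {
  s <- "sensitive" %in% c(c1, c2)
  r <- "resistant" %in% c(c1, c2)
  if (s && r) "discordant" else if (s) "sensitive" else if (r) "resistant"
  else "neutral"
}
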