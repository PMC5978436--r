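# Kaplan-Meier estimation and the two-group log-rank test, implemented from
# the product-limit / hypergeometric definitions.

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of one group from right-censored data.
#' At each distinct event time `t_i` with `d_i` deaths among `n_i` subjects
#' at risk, `S(t_i) = prod_{j <= i} (1 - d_j / n_j)`. Subjects censored at
#' an event time are still at risk at that time (events are processed
#' before censorings, the standard tie convention); censored times reduce
#' the risk set afterwards.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator per subject: 1 = death observed,
#'   0 = censored.
#' @return A `data.frame` of class `km_curve` with one row per distinct
#'   event time: `time`, `n_risk`, `n_event`, `surv`; attribute `n` is the
#'   group size. Zero rows when no events occurred (S identically 1).
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))  # S(1) = 2/3, S(3) = 0
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one observation")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (any(!is.finite(time))) stop("times must be finite")
  if (any(time < 0)) stop("negative survival time")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  et <- sort(unique(time[event == 1L]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1L), numeric(1))
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    surv = cumprod(1 - n_event / n_risk))
  structure(out, class = c("km_curve", "data.frame"), n = length(time))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n",
              attr(x, "n"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time the deaths observed in the reference group
#' are compared with their conditional (hypergeometric) expectation given
#' the pooled risk set: `O = sum d1_t`, `E = sum d_t n1_t / n_t`, and
#' `V = sum d_t (n1_t / n_t)(1 - n1_t / n_t)(n_t - d_t)/(n_t - 1)` (a time
#' with a single subject at risk contributes zero variance). The statistic
#' `(O - E)^2 / V` is referred to chi-square with 1 df. The reference group
#' is the level named `"high"` when present (so the direction reads as the
#' prognosis of high expressors), else the first sorted level.
#'
#' A test with zero total variance (no events, or every event at a time
#' where one group holds the whole risk set) is flagged degenerate and
#' reported with `chi2 = 0`, `p = 1`, `direction = "none"`.
#'
#' @param time,event As in [km_estimate()].
#' @param group Vector with exactly two levels splitting the subjects.
#' @return A list of class `logrank_result`: `observed`, `expected`,
#'   `variance` (all for the reference group), `chi2`, `p`, `direction`
#'   (`high_better` iff `O < E`, `low_better` iff `O > E`, else `none`),
#'   `degenerate`, `reference`, `n_high`, `n_low`.
#' @export
#' @examples
#' logrank_test(c(1, 2, 1, 3), c(1, 1, 1, 0),
#'              c("high", "high", "low", "low"))
logrank_test <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group))
    stop("time, event and group lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) stop("invalid survival times")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  group <- as.character(group)
  lv <- sort(unique(group))
  if (length(lv) != 2L) stop("group must have exactly two non-empty levels")
  ref <- if ("high" %in% lv) "high" else lv[1L]
  other <- setdiff(lv, ref)
  in_ref <- group == ref
  et <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_ref)
    dead <- time == t & event == 1L
    d <- sum(dead)
    d1 <- sum(dead & in_ref)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1L)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  degenerate <- length(et) == 0L || V <= 0
  if (degenerate) {
    chi2 <- 0
    p <- 1
    direction <- "none"
  } else {
    chi2 <- (O - E)^2 / V
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    direction <- if (O < E) "high_better"
                 else if (O > E) "low_better"
                 else "none"
  }
  structure(list(observed = O, expected = E, variance = V, chi2 = chi2,
                 p = p, direction = direction, degenerate = degenerate,
                 reference = ref,
                 n_high = sum(in_ref), n_low = sum(!in_ref),
                 groups = c(ref, other)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank ('%s' vs '%s'): O = %.3f, E = %.3f, V = %.4f\n",
              x$groups[1L], x$groups[2L], x$observed, x$expected,
              x$variance))
  cat(sprintf("  chi2 = %.4f (1 df), p = %.4g, direction = %s%s\n",
              x$chi2, x$p, x$direction,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Probe-by-probe survival scan within one genotype stratum
#'
#' For every probe of a prepared cohort, splits the stratum's samples at
#' the probe's median expression ([median_split()]) and runs a two-group
#' log-rank test on overall survival. Probes whose values are all identical
#' are flagged `non_informative` and carry no test; probes whose test has
#' zero variance (or a one-sided split under a pooled median) are flagged
#' `degenerate` with p = 1.
#'
#' @param cohort A prepared [cohort_table()].
#' @param stratum `"WT"` or `"Mut"`.
#' @param median_scope Where the dichotomizing median is computed:
#'   `"stratum"` (default; each test self-contained in its stratum) or
#'   `"pooled"` (median over WT + Mut samples).
#' @param tie Tie rule passed to [median_split()].
#' @param bh If `TRUE`, add a Benjamini-Hochberg adjusted p column over the
#'   tested probes (off by default; selection mirrors a raw p < alpha rule).
#' @return `data.frame` with one row per probe: `probe_id`, `stratum`,
#'   `n_high`, `n_low`, `median`, `observed`, `expected`, `chi2`, `p`,
#'   `direction`, `flag` (`ok` / `non_informative` / `degenerate`), and
#'   `p_bh` when requested.
#' @export
run_survival_scan <- function(cohort, stratum = c("WT", "Mut"),
                              median_scope = c("stratum", "pooled"),
                              tie = c("gt", "ge"), bh = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  stratum <- match.arg(stratum)
  median_scope <- match.arg(median_scope)
  tie <- match.arg(tie)
  samp <- cohort$samples
  in_str <- samp$tp53_status == stratum
  if (!any(in_str)) stop("stratum '", stratum, "' absent from cohort")
  if (sum(in_str) < 2L) stop("stratum '", stratum, "' has fewer than 2 samples")
  expr <- cohort$expression[, samp$sample_id[in_str], drop = FALSE]
  time <- samp$os_time[in_str]
  event <- samp$os_event[in_str]
  pooled_ids <- samp$sample_id[samp$tp53_status %in% c("WT", "Mut")]
  probes <- rownames(expr)
  n <- length(probes)
  out <- data.frame(
    probe_id = probes, stratum = stratum,
    n_high = NA_integer_, n_low = NA_integer_, median = NA_real_,
    observed = NA_real_, expected = NA_real_, chi2 = NA_real_,
    p = NA_real_, direction = NA_character_, flag = "ok",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- expr[i, ]
    if (all(v == v[1L])) {
      out$flag[i] <- "non_informative"
      out$median[i] <- v[1L]
      next
    }
    med <- if (median_scope == "stratum") stats::median(v)
           else stats::median(cohort$expression[probes[i], pooled_ids])
    hi <- if (tie == "gt") v > med else v >= med
    out$median[i] <- med
    out$n_high[i] <- sum(hi)
    out$n_low[i] <- sum(!hi)
    if (all(hi) || all(!hi)) {  # possible under a pooled median
      out$flag[i] <- "degenerate"
      out$p[i] <- 1
      out$direction[i] <- "none"
      next
    }
    lr <- logrank_test(time, event, ifelse(hi, "high", "low"))
    out$observed[i] <- lr$observed
    out$expected[i] <- lr$expected
    out$chi2[i] <- lr$chi2
    out$p[i] <- lr$p
    out$direction[i] <- lr$direction
    if (lr$degenerate) out$flag[i] <- "degenerate"
  }
  if (bh) {
    out$p_bh <- NA_real_
    ok <- out$flag == "ok"
    out$p_bh[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  }
  out
}
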