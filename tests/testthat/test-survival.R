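test_that("Kaplan-Meier estimate reproduces hand product-limit values", {
  # all censored: S identically 1, no event rows
  km0 <- km_estimate(c(5, 7), c(0, 0))
  expect_identical(nrow(km0), 0L)

  # hand computation: at t=1 risk 3 death 1 -> 2/3; at t=3 risk 1 death 1 -> 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$n_risk, c(3, 1))
  expect_equal(km$surv, c(2 / 3, 0))

  km1 <- km_estimate(4, 1)
  expect_equal(km1$surv, 0)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")

  # S(t0) = 1 implicitly, non-increasing, product-limit invariant
  set.seed(31)
  for (i in 1:10) {
    co <- random_small_cohort(15)
    km <- km_estimate(co$time, co$event)
    expect_true(all(diff(c(1, km$surv)) <= 1e-12))
    expect_equal(km$surv, cumprod(1 - km$n_event / km$n_risk))
    expect_true(all(diff(km$n_risk) < 0))
  }
})

test_that("KM curves match the reference survival implementation", {
  skip_if_not_installed("survival")
  set.seed(32)
  for (i in 1:25) {
    co <- random_small_cohort(sample(5:25, 1))
    km <- km_estimate(co$time, co$event)
    sf <- survival::survfit(survival::Surv(co$time, co$event) ~ 1)
    at_events <- sf$n.event > 0
    expect_equal(km$time, sf$time[at_events])
    expect_equal(km$n_risk, sf$n.risk[at_events])
    expect_equal(km$surv, sf$surv[at_events], tolerance = 1e-12)
  }
})

test_that("log-rank test reproduces the hand-computed O/E/V example", {
  # groups A [(1,1),(2,1)], B [(1,1),(3,0)]; event times 1 and 2:
  #   t=1: n=4, nA=2, d=2 -> E += 1,   V += 2*(1/2)*(1/2)*(2/3) = 1/3
  #   t=2: n=2, nA=1, d=1 -> E += 1/2, V += 1*(1/2)*(1/2)*1     = 1/4
  lr <- logrank_test(time = c(1, 2, 1, 3), event = c(1, 1, 1, 0),
                     group = c("A", "A", "B", "B"))
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 1.5)
  expect_equal(lr$variance, 7 / 12)
  expect_equal(lr$chi2, 0.25 / (7 / 12))
  expect_equal(lr$chi2, 0.4286, tolerance = 1e-4)
  expect_identical(lr$direction, "low_better")  # A observed > expected

  # identical groups: chi2 = 0, p = 1
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                      rep(c("high", "low"), each = 3))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)
  expect_identical(lr0$direction, "none")

  # zero-variance degenerate case: no events at comparable risk sets
  lrd <- logrank_test(c(1, 2), c(0, 0), c("high", "low"))
  expect_true(lrd$degenerate)
  expect_equal(lrd$p, 1)
  expect_identical(lrd$direction, "none")
})

test_that("log-rank agrees with the reference implementation and permutations", {
  skip_if_not_installed("survival")
  set.seed(33)
  for (i in 1:25) {
    co <- random_small_cohort(sample(8:30, 1))
    lr <- logrank_test(co$time, co$event, co$group)
    if (lr$degenerate) next
    sd <- survival::survdiff(
      survival::Surv(co$time, co$event) ~ co$group)
    expect_equal(lr$chi2, unname(sd$chisq), tolerance = 1e-10)
  }

  # permutation oracle on one fixed cohort
  set.seed(34)
  co <- random_small_cohort(20)
  lr <- logrank_test(co$time, co$event, co$group)
  perm <- replicate(1000, {
    logrank_test(co$time, co$event, sample(co$group))$chi2
  })
  p_emp <- mean(perm >= lr$chi2 - 1e-12)
  expect_lt(abs(p_emp - lr$p), 0.06)
})

test_that("log-rank is symmetric under label exchange", {
  set.seed(35)
  for (i in 1:10) {
    co <- random_small_cohort(20)
    a <- logrank_test(co$time, co$event, co$group)
    b <- logrank_test(co$time, co$event,
                      ifelse(co$group == "high", "low", "high"))
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    if (!a$degenerate && a$direction != "none") {
      expect_identical(sort(c(a$direction, b$direction)),
                       c("high_better", "low_better"))
    }
  }
})

test_that("late censored observations change risk sets but no death counts", {
  co <- list(time = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 1))
  km_a <- km_estimate(co$time, co$event)
  km_b <- km_estimate(c(co$time, 99), c(co$event, 0))
  expect_equal(km_b$n_event, km_a$n_event)
  expect_equal(km_b$time, km_a$time)
  expect_equal(km_b$n_risk, km_a$n_risk + 1)
  expect_equal(km_b$surv, cumprod(1 - km_a$n_event / (km_a$n_risk + 1)))
})

test_that("survival scan ranks a planted WT-only probe first in WT only", {
  sim <- simulate_cohort(cohort_sim_config(
    n_wt = 200, n_mut = 200, n_probes = 51,
    planted_wt = c(G0001 = 0.3), qc_failure_count = 0,
    n_zero_probes = 0, seed = 42))
  cohort <- prepare_cohort(sim$expression, sim$annotations, sim$probe_map)
  planted_probe <- sim$truth$probe_id[sim$truth$stratum_active == "WT"]

  wt <- run_survival_scan(cohort, "WT")
  expect_identical(wt$probe_id[which.min(wt$p)], planted_probe)
  expect_lt(wt$p[wt$probe_id == planted_probe], 0.001)
  expect_identical(wt$direction[wt$probe_id == planted_probe],
                   "high_better")

  # in the Mut stratum the same probe is just another null
  mut <- run_survival_scan(cohort, "Mut")
  null_fraction <- mean(mut$p < 0.05)
  expect_lt(null_fraction, 0.15)

  # one record per probe, group sizes add to the stratum size
  expect_identical(nrow(wt), nrow(cohort$expression))
  ok <- wt$flag == "ok"
  expect_true(all(wt$n_high[ok] + wt$n_low[ok] == sum(
    cohort$samples$tp53_status == "WT")))
})

test_that("planted Mut false-positive rate stays near the nominal level", {
  # replicate small cohorts; the planted WT effect must not leak into Mut
  set.seed(36)
  pvals <- vapply(1:60, function(i) {
    sim <- simulate_cohort(cohort_sim_config(
      n_wt = 30, n_mut = 60, n_probes = 2,
      planted_wt = c(G0001 = 0.3), qc_failure_count = 0,
      n_zero_probes = 0, seed = 1000 + i))
    cohort <- prepare_cohort(sim$expression, sim$annotations,
                             sim$probe_map)
    scan <- run_survival_scan(cohort, "Mut")
    scan$p[scan$probe_id == "P00001_at"]
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.18)  # binomial bound around 0.05, n = 60
})

test_that("degenerate probes propagate as flags, not test rows", {
  sim <- simulate_cohort(cohort_sim_config(
    n_wt = 10, n_mut = 10, n_probes = 5, n_prognostic_planted = 0,
    qc_failure_count = 0, n_zero_probes = 0, seed = 2))
  expr <- log2_transform(sim$expression)$matrix
  expr["P00001_at", ] <- 3.25  # flat probe
  cohort <- cohort_table(expr, sim$annotations, sim$probe_map)
  scan <- run_survival_scan(cohort, "WT")
  row <- scan[scan$probe_id == "P00001_at", ]
  expect_identical(row$flag, "non_informative")
  expect_true(is.na(row$p))
  expect_error(run_survival_scan(cohort, "unknown"))
})
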