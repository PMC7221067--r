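test_that("KM estimator matches hand-computed product limits", {
  # 10 flies all dying at day 30
  tab <- make_surv(rep(30, 10), numeric(0))
  km <- km_estimate(tab, "A")
  expect_identical(nrow(km), 1L)
  expect_equal(km$surv, 0)
  expect_equal(km$time, 30)

  # deaths at days 1..10: S after k-th death = (10 - k)/10
  tab2 <- make_surv(1:10, numeric(0))
  km2 <- km_estimate(tab2, "A")
  expect_equal(km2$surv, (10 - 1:10) / 10)
  expect_equal(km2$n_risk, as.numeric(10:1))

  # survival is non-increasing, starts at <= 1, stays in [0, 1]
  withr::with_seed(81, {
    tab3 <- make_surv(rexp(25, 0.05), numeric(0),
                      status_a = rbinom(25, 1, 0.8))
    km3 <- km_estimate(tab3, "A")
    expect_true(all(diff(km3$surv) <= 1e-12))
    expect_true(all(km3$surv >= 0 & km3$surv <= 1))
    # product-limit identity at every step
    expect_equal(km3$surv, cumprod(1 - km3$n_event / km3$n_risk),
                 tolerance = 1e-12)
  })
})

test_that("KM equals the empirical survivor function without censoring", {
  withr::with_seed(82, {
    times <- round(rexp(40, 0.02), 1)
    tab <- make_surv(times, numeric(0))
    km <- km_estimate(tab, "A")
    emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
    expect_equal(km$surv, emp, tolerance = 1e-12)
  })
})

test_that("median lifespan is the first time S reaches one half", {
  expect_equal(as.numeric(median_lifespan(
    km_estimate(make_surv(rep(30, 10), numeric(0)), "A"))), 30)
  expect_equal(as.numeric(median_lifespan(
    km_estimate(make_surv(1:10, numeric(0)), "A"))), 5)
  # heavy censoring leaves the median undefined and flagged
  heavy <- make_surv(c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14), numeric(0),
                     status_a = c(1, 1, 1, rep(0, 7)))
  med <- median_lifespan(km_estimate(heavy, "A"))
  expect_true(is.na(med))
  expect_true(attr(med, "censored_median"))
})

test_that("maximum lifespan definitions are tagged and hand-checkable", {
  tab <- make_surv(1:10, numeric(0))
  top <- maximum_lifespan(tab, "A", "top_decile_mean")
  expect_equal(top$maximum, 10)          # top 10% is the single fly at 10
  expect_identical(top$definition, "top_decile_mean")
  expect_equal(maximum_lifespan(tab, "A", "percentile_90")$maximum, 9.1)
  expect_equal(maximum_lifespan(tab, "A", "last_death")$maximum, 10)

  # every definition agrees when all flies die on the same day
  same <- make_surv(rep(17, 12), numeric(0))
  for (d in c("top_decile_mean", "last_death", "percentile_90")) {
    expect_equal(maximum_lifespan(same, "A", d)$maximum, 17)
  }

  # < 10 deaths: top-decile falls back to last death, flagged
  few <- make_surv(1:5, numeric(0))
  fb <- maximum_lifespan(few, "A", "top_decile_mean")
  expect_identical(fb$definition, "last_death")
  expect_true(fb$fallback)
  expect_true(all(!top$fallback))
})

test_that("log-rank matches the frozen hand computation and the oracle", {
  # A = {1,2,3}, B = {4,5,6}: U = 1.85, V = 0.6775 by risk-set enumeration
  tab <- make_surv(c(1, 2, 3), c(4, 5, 6))
  lr <- logrank_test(tab, "A", "B")
  expect_equal(lr$statistic, 1.85^2 / 0.6775, tolerance = 1e-12)
  expect_equal(lr$statistic, oracle_rank_stat(tab, "A", "B"),
               tolerance = 1e-12)
  expect_identical(lr$df, 1L)
})

test_that("identical groups give statistic 0 and p = 1", {
  withr::with_seed(83, {
    times <- rexp(15, 0.03)
    tab <- make_surv(times, times)
    lr <- logrank_test(tab, "A", "B")
    gw <- gehan_wilcoxon_test(tab, "A", "B")
    expect_equal(lr$statistic, 0, tolerance = 1e-12)
    expect_equal(lr$p_raw, 1, tolerance = 1e-12)
    expect_equal(gw$statistic, 0, tolerance = 1e-12)
  })
})

test_that("rank statistics equal brute-force risk-set enumeration", {
  withr::with_seed(84, {
    for (i in 1:25) {
      na <- sample(5:15, 1)
      nb <- sample(5:15, 1)
      tab <- make_surv(round(rexp(na, 0.04), 1) + 0.1, round(rexp(nb, 0.06), 1) + 0.1,
                       status_a = rbinom(na, 1, 0.85),
                       status_b = rbinom(nb, 1, 0.85))
      if (sum(tab$status[tab$genotype == "A"]) == 0 ||
          sum(tab$status[tab$genotype == "B"]) == 0) next
      expect_equal(logrank_test(tab, "A", "B")$statistic,
                   oracle_rank_stat(tab, "A", "B"), tolerance = 1e-12)
      expect_equal(gehan_wilcoxon_test(tab, "A", "B")$statistic,
                   oracle_rank_stat(tab, "A", "B", gehan = TRUE),
                   tolerance = 1e-12)
    }
  })
})

test_that("log-rank agrees with survival::survdiff", {
  withr::with_seed(85, {
    tab <- gen_cohort(cohort_synth_spec(
      groups = list(A = c(a = 0.02, b = 0.05), B = c(a = 0.01, b = 0.05)),
      n_per_group = 60, censor_prob = 0.1, seed = 86))
    sd <- survival::survdiff(survival::Surv(time, status) ~ genotype,
                             data = tab)
    expect_equal(logrank_test(tab, "A", "B")$statistic, sd$chisq,
                 tolerance = 1e-9)
  })
})

test_that("tests are invariant to fly relabeling and time-unit changes", {
  withr::with_seed(87, {
    tab <- make_surv(rexp(20, 0.05), rexp(20, 0.08),
                     status_a = rbinom(20, 1, 0.9),
                     status_b = rbinom(20, 1, 0.9))
    base <- logrank_test(tab, "A", "B")$statistic
    shuffled <- tab
    shuffled$fly_id <- sample(shuffled$fly_id)
    perm <- sample(nrow(shuffled))
    shuffled <- survival_table(as.data.frame(shuffled)[perm, ])
    expect_equal(logrank_test(shuffled, "A", "B")$statistic, base,
                 tolerance = 1e-12)
    hours <- tab
    hours$time <- hours$time * 24
    hours <- survival_table(as.data.frame(hours), time_unit = "hours")
    expect_equal(logrank_test(hours, "A", "B")$statistic, base,
                 tolerance = 1e-12)
    expect_equal(gehan_wilcoxon_test(hours, "A", "B")$statistic,
                 gehan_wilcoxon_test(tab, "A", "B")$statistic,
                 tolerance = 1e-12)
  })
})

test_that("Gehan weighting emphasizes early separation", {
  # curves separate early (7 quick deaths in A) and cross late
  tab <- make_surv(c(1:7, 40, 41, 42), 20:29)
  gw <- gehan_wilcoxon_test(tab, "A", "B")
  lr <- logrank_test(tab, "A", "B")
  expect_gt(gw$statistic, lr$statistic)
  expect_equal(gw$statistic, oracle_rank_stat(tab, "A", "B", gehan = TRUE),
               tolerance = 1e-12)

  # with a single death time and no censoring the weights are constant and
  # Gehan reduces to the log-rank result
  one <- make_surv(rep(12, 6), rep(12, 8))
  expect_equal(gehan_wilcoxon_test(one, "A", "B")$statistic,
               logrank_test(one, "A", "B")$statistic, tolerance = 1e-12)
})

test_that("multiple-comparison correction follows Bonferroni and Holm", {
  withr::with_seed(88, {
    tab <- gen_cohort(cohort_synth_spec(
      groups = list(A = c(a = 0.02, b = 0.05), B = c(a = 0.012, b = 0.05),
                    C = c(a = 0.008, b = 0.05)),
      n_per_group = 40, seed = 89))
    pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    bf <- multi_compare(tab, pairs, method = "bonferroni")
    expect_identical(nrow(bf), 6L)       # 3 pairs x 2 tests
    expect_equal(bf$p_adjusted, pmin(1, 3 * bf$p_raw), tolerance = 1e-12)
    expect_true(all(bf$p_adjusted >= bf$p_raw))

    hm <- multi_compare(tab, pairs, method = "holm")
    lr <- hm[hm$test == "log-rank", ]
    o <- order(lr$p_raw)
    manual <- cummax(pmin(1, (3:1) * lr$p_raw[o]))
    expect_equal(lr$p_adjusted[o], manual, tolerance = 1e-12)

    # m = 1 leaves the p-value untouched
    single <- multi_compare(tab, list(c("A", "B")))
    expect_equal(single$p_adjusted, single$p_raw, tolerance = 1e-12)

    expect_error(multi_compare(tab, list(c("A", "B"), c("B", "A"))),
                 "duplicate")
  })
})

test_that("additivity verdict logic behaves on constructed cohorts", {
  # all four groups identical -> singles never differ -> inconclusive
  withr::with_seed(90, {
    times <- rexp(40, 0.03)
    tab <- survival_table(data.frame(
      fly_id = paste0("f", 1:160),
      genotype = rep(c("ctl", "sA", "sB", "dbl"), each = 40),
      condition = "standard", time = rep(times, 4), status = 1))
    rep_same <- additivity_report(tab, "ctl", "sA", "sB", "dbl")
    expect_identical(rep_same$verdict, "inconclusive")
  })
})

test_that("additivity verdicts track the generating hazards", {
  n_rep <- 150
  verdicts_na <- character(n_rep)
  for (i in seq_len(n_rep)) {
    # double shares the singles' (longer-lived) parameters -> non-additive
    tab <- gen_cohort(cohort_synth_spec(
      groups = list(ctl = c(a = 0.03, b = 0.08),
                    sA = c(a = 0.012, b = 0.08),
                    sB = c(a = 0.012, b = 0.08),
                    dbl = c(a = 0.012, b = 0.08)),
      n_per_group = 100, seed = 9000 + i))
    verdicts_na[i] <- additivity_report(tab, "ctl", "sA", "sB",
                                        "dbl")$verdict
  }
  expect_gte(mean(verdicts_na == "non-additive"), 0.9)

  verdicts_add <- character(60)
  for (i in seq_len(60)) {
    # double has a much lower hazard than either single -> additive
    tab <- gen_cohort(cohort_synth_spec(
      groups = list(ctl = c(a = 0.03, b = 0.08),
                    sA = c(a = 0.015, b = 0.08),
                    sB = c(a = 0.015, b = 0.08),
                    dbl = c(a = 0.004, b = 0.08)),
      n_per_group = 100, seed = 9500 + i))
    verdicts_add[i] <- additivity_report(tab, "ctl", "sA", "sB",
                                         "dbl")$verdict
  }
  expect_gt(mean(verdicts_add == "additive-consistent"), 0.5)
})

test_that("log-rank has power against a doubled Gompertz hazard", {
  rej <- vapply(1:200, function(i) {
    tab <- gen_cohort(cohort_synth_spec(
      groups = list(A = c(a = 0.02, b = 0.08), B = c(a = 0.01, b = 0.08)),
      n_per_group = 100, seed = 9700 + i))
    logrank_test(tab, "A", "B")$p_raw < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("survival tables validate their contract", {
  expect_error(survival_table(data.frame(fly_id = "a", genotype = "g",
                                         condition = "standard",
                                         time = -1, status = 1)),
               "positive")
  expect_error(survival_table(data.frame(fly_id = "a", genotype = "g",
                                         time = 1, status = 1)),
               "condition")
  expect_error(survival_table(data.frame(fly_id = "a", genotype = "g",
                                         condition = "standard",
                                         time = 1, status = 2)),
               "status")
  tab <- make_surv(1:5, 6:10)
  expect_error(km_estimate(tab, "missing"), "not found")
})
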