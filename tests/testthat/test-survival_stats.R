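test_that("product-limit hand example: deaths at 1,2,3,4", {
  v <- vitals_df(c(1, 2, 3, 4), dead = rep(TRUE, 4))
  km <- km_estimate(v)
  expect_equal(km$time, c(1, 2, 3, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, c(4, 3, 2, 1))
  expect_equal(median_survival(km), 2)
})

test_that("all-censored groups give S = 1 and no median", {
  v <- vitals_df(rep(30, 5), dead = rep(FALSE, 5))
  km <- km_estimate(v)
  expect_length(km$time, 0)
  expect_equal(km_survival_at(km, c(0, 10, 30)), c(1, 1, 1))
  expect_true(is.na(km$median))
  expect_error(km_estimate(v[0, ]), "Empty")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(42)
  for (i in 1:50) {
    t <- round(rexp(sample(3:40, 1), 1 / 20), 2)
    km <- km_estimate(vitals_df(t, dead = rep(TRUE, length(t))))
    grid <- sort(unique(c(t, t / 2, t + 0.1)))
    expect_equal(km_survival_at(km, grid), empirical_survival(t, grid))
  }
})

test_that("KM handles ties and censoring like the survival package", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    t <- sample(1:15, n, replace = TRUE)  # heavy ties
    d <- runif(n) < 0.7
    km <- km_estimate(vitals_df(t, dead = d))
    sf <- survival::survfit(survival::Surv(t, d) ~ 1)
    ev <- summary(sf, times = km$time)
    expect_equal(km$surv, ev$surv, tolerance = 1e-12)
    expect_equal(km$n_risk, ev$n.risk)
  }
})

test_that("median at an exact 0.5 plateau: inclusive vs midpoint", {
  # n = 4, deaths at 10, 21, censored later: S hits exactly 0.5 at 21
  v <- vitals_df(c(10, 21, 25, 28), dead = c(TRUE, TRUE, TRUE, TRUE))
  km <- km_estimate(v)
  expect_equal(km_survival_at(km, 21), 0.5)
  expect_equal(median_survival(km), 21)
  expect_equal(median_survival(km, interpolate = TRUE), 23)
})

test_that("KM median is consistent for a large exponential cohort", {
  set.seed(99)
  t <- rexp(300, rate = log(2) / 17)
  v <- vitals_df(pmin(t, 30), dead = t <= 30)
  km <- km_estimate(v)
  expect_lt(abs(km$median - 17), 2)
})

test_that("log-rank: identical groups score 0 and swap-invariance holds", {
  v <- vitals_df(c(5, 10, 15, 30), dead = c(TRUE, TRUE, TRUE, FALSE))
  lr <- logrank_test(v, v)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p_value, 1)

  set.seed(12)
  a <- vitals_df(rexp(20, 1 / 15), dead = rep(TRUE, 20), genotype = "a")
  b <- vitals_df(rexp(25, 1 / 25), dead = rep(TRUE, 25), genotype = "b")
  lr_ab <- logrank_test(a, b)
  lr_ba <- logrank_test(b, a)
  expect_equal(lr_ab$chisq, lr_ba$chisq)
  expect_error(logrank_test(a[0, ], b), "non-empty")
})

test_that("log-rank matches survdiff and a hand risk-table oracle", {
  # brute-force oracle on a tiny example: A dies {1,2}, B dies {3,4}
  a <- vitals_df(c(1, 2), dead = c(TRUE, TRUE), genotype = "a")
  b <- vitals_df(c(3, 4), dead = c(TRUE, TRUE), genotype = "b")
  # risk tables: t=1: n=4,nA=2,d=1 E=.5 V=1*(.5)(.5)(3/3)=.25
  #              t=2: n=3,nA=1,d=1 E=1/3 V=(1/3)(2/3)(2/2)=2/9
  #              t=3: n=2,nA=0    E=0   V=0
  #              t=4: n=1,nA=0    E=0   V=0 (skipped, n=1)
  o <- 2; e <- 0.5 + 1 / 3; v <- 0.25 + 2 / 9
  expect_equal(logrank_test(a, b)$chisq, (o - e)^2 / v)

  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:25) {
    na <- sample(5:30, 1); nb <- sample(5:30, 1)
    ta <- sample(1:12, na, replace = TRUE)
    tb <- sample(1:12, nb, replace = TRUE)
    da <- runif(na) < 0.8; db <- runif(nb) < 0.8
    if (!any(da) && !any(db)) next
    lr <- logrank_test(vitals_df(ta, da, "a"), vitals_df(tb, db, "b"))
    sd_ <- survival::survdiff(
      survival::Surv(c(ta, tb), c(da, db)) ~ rep(c("a", "b"), c(na, nb)))
    expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank is invariant under monotone time rescaling", {
  set.seed(55)
  a <- vitals_df(rexp(15, 1 / 10), dead = runif(15) < 0.8, genotype = "a")
  b <- vitals_df(rexp(15, 1 / 20), dead = runif(15) < 0.8, genotype = "b")
  lr1 <- logrank_test(a, b)
  a2 <- a; b2 <- b
  a2$lifespan_days <- log1p(a$lifespan_days)^2
  b2$lifespan_days <- log1p(b$lifespan_days)^2
  lr2 <- logrank_test(a2, b2)
  expect_equal(lr1$chisq, lr2$chisq)
})

test_that("single-event-time log-rank equals the 2x2 chi-square score", {
  # all events at one time: chi-square score statistic of the 2x2 table
  a <- vitals_df(c(5, 5, 30, 30), dead = c(TRUE, TRUE, FALSE, FALSE), "a")
  b <- vitals_df(c(5, 30, 30, 30), dead = c(TRUE, FALSE, FALSE, FALSE), "b")
  n <- 8; n_a <- 4; d <- 3
  e <- n_a * d / n
  v <- d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  expect_equal(logrank_test(a, b)$chisq, (2 - e)^2 / v)
})

test_that("eclosion percentages, degenerate t fallback, single replicate", {
  perfect <- data.frame(genotype = "wt", replicate = 1:3,
                        n_input_larvae = 20, n_eclosed = 20)
  res <- eclosion_stats(perfect)
  expect_equal(res$summary$mean_pct_eclosed, 100)
  expect_equal(res$summary$sem_pct_eclosed, 0)

  # 50% vs 80% with zero within-group variance: permutation fallback
  tab <- rbind(
    data.frame(genotype = "mut", replicate = 1:3, n_input_larvae = 20,
               n_eclosed = 10),
    data.frame(genotype = "wt", replicate = 1:3, n_input_larvae = 20,
               n_eclosed = 16)
  )
  res2 <- eclosion_stats(tab)
  expect_equal(sort(res2$summary$mean_pct_eclosed), c(50, 80))
  expect_equal(res2$tests$method, "permutation (zero variance)")
  expect_equal(res2$tests$p_value, 2 / 20)  # exhaustive 3v3 enumeration

  one_rep <- rbind(tab, data.frame(genotype = "solo", replicate = 1,
                                   n_input_larvae = 20, n_eclosed = 12))
  expect_warning(res3 <- eclosion_stats(one_rep), "solo")
  expect_true(is.na(res3$summary$sem_pct_eclosed[
    res3$summary$genotype == "solo"]))
  expect_false("solo" %in% c(res3$tests$group_a, res3$tests$group_b))

  bad <- data.frame(genotype = "x", replicate = 1, n_input_larvae = 20,
                    n_eclosed = 25)
  expect_error(eclosion_stats(bad), "out of range")
})

test_that("similar true eclosion rates are usually non-significant", {
  set.seed(61)
  n_sig <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    tab <- simulate_eclosion_table(c(a = 0.88, b = 0.80), seed = 1000 + r)
    p <- eclosion_stats(tab)$tests$p_value
    if (!is.na(p) && p <= 0.05) n_sig <- n_sig + 1L
  }
  expect_gt((n_rep - n_sig) / n_rep, 0.5)
})

test_that("count comparisons: identity null and group summaries", {
  tab <- simulate_count_table(c(a = 2e5, b = 2e5), cv = 0, n_per_group = 5)
  res <- count_compare(tab, "a", "b")
  expect_equal(res$p_value, 1)

  set.seed(3)
  tab2 <- simulate_count_table(c(lo = 1e5, hi = 4e5), cv = 0.3,
                               n_per_group = 20, seed = 5)
  res2 <- count_compare(tab2, "lo", "hi")
  expect_lt(res2$p_value, 0.001)
  expect_lt(res2$mean_a, res2$mean_b)

  tiny <- tab2[c(1, 21), ]
  expect_true(is.na(count_compare(tiny, "lo", "hi")$p_value))
})

test_that("programmed haemocyte separations are detected consistently", {
  # means follow the reported scale: ~4.0e5 vs ~1.9e5, n = 34 vs 30
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    tab <- simulate_count_table(c(R1261C = 3.97e5, wt = 1.94e5), cv = 0.3,
                                n_per_group = c(34, 30), seed = 400 + r)
    if (count_compare(tab, "R1261C", "wt")$p_value < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("haemocytometer back-calculation applies the 1:1 dilution", {
  # chamber count x 1e4 per square x 2 (10 uL haemolymph + 10 uL dye)
  expect_equal(haemocyte_concentration(6.45), 6.45 * 1e4 * 2)
  expect_equal(haemocyte_concentration(6.45), 1.29e5)
  expect_equal(haemocyte_concentration(40, n_squares = 4), 2e5)
  expect_equal(haemocyte_concentration(10, dilution_factor = 1), 1e5)
})
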