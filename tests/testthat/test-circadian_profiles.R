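make_bins <- function(recs, horizon = 30) {
  suppressMessages(score_cohort(recs, horizon_days = horizon))$bins
}

const_recs <- function(values, n_days = 2) {
  lapply(seq_along(values), function(i) {
    r <- rec_from_counts(rep(values[i], 288L * n_days))
    r$fly_id <- sprintf("T#%02d", i)
    r
  })
}

test_that("identical constant flies give a flat profile with sem 0", {
  bins <- make_bins(const_recs(c(2L, 2L, 2L)))
  p <- population_profile(bins, "activity")
  expect_equal(nrow(p), 288)
  expect_true(all(p$mean == 2))
  expect_true(all(p$sem == 0))
  expect_true(all(p$n == 3))
})

test_that("profile mean and sem match the closed form for two flies", {
  # bins table built directly so the 0-count fly counts as alive
  recs <- const_recs(c(0L, 2L), n_days = 1)
  bins <- do.call(rbind, lapply(recs, function(r) {
    b <- as.data.frame(r)
    b$asleep <- r$counts == 0L
    b$alive <- TRUE
    b
  }))
  p <- population_profile(bins, "activity")
  expect_true(all(p$mean == 1))
  expect_true(all(p$sem == 1))  # sd(c(0,2))/sqrt(2) = sqrt(2)/sqrt(2)
})

test_that("profiles of concatenated identical days equal one day's", {
  set.seed(5)
  day <- rpois(288, 4) + 1L
  r1 <- rec_from_counts(rep(day, 1))
  r3 <- rec_from_counts(rep(day, 3))
  p1 <- population_profile(make_bins(list(r1)), "activity")
  p3 <- population_profile(make_bins(list(r3)), "activity")
  expect_equal(p1$mean, p3$mean)
})

test_that("sleep-percent profile is 1 - fraction of flies active per bin", {
  set.seed(8)
  recs <- lapply(1:4, function(i) {
    r <- rec_from_counts(rpois(288L, 1.5))
    r$fly_id <- sprintf("T#%02d", i)
    r
  })
  bins <- make_bins(recs)
  p <- population_profile(bins, "sleep")
  counts <- sapply(recs, `[[`, "counts")
  expect_equal(p$mean, unname(1 - rowMeans(counts > 0)))
})

test_that("simulated profiles peak at the programmed ZT0/ZT12 positions", {
  cfg <- sim_genotype_config(
    "g", 8, lifespan = list(dist = "exponential", median = 200))
  sim <- simulate_cohort(cfg, 17, n_days = 10)
  p <- population_profile(make_bins(sim$recordings, horizon = 10), "activity")
  # morning peak: within 3 bins of ZT0 (circular); evening: of ZT12 (bin 144)
  top <- order(p$mean, decreasing = TRUE)[1:24] - 1L
  circ <- function(b, centre) pmin((b - centre) %% 288, (centre - b) %% 288)
  expect_lte(min(circ(top, 0L)), 3)
  expect_lte(min(circ(top, 144L)), 3)
  best_morning <- top[which.min(circ(top, 0L))]
  best_evening <- top[which.min(circ(top, 144L))]
  expect_lte(circ(best_morning, 0L), 3)
  expect_lte(circ(best_evening, 144L), 3)
})

test_that("anticipation index: flat 0.5, packed 1.0, midpoint ramp 0.75", {
  flat <- rec_from_counts(rep(3L, 288L * 2))
  expect_equal(anticipation_index(flat, "lights_off"), 0.5)
  expect_equal(anticipation_index(flat, "lights_on"), 0.5)

  # all pre-ZT12 activity packed in the last 3 h
  counts <- rep(0L, 288L)
  counts[(144 - 36 + 1):144] <- 5L  # ZT9..ZT12
  counts[200] <- 2L  # some unrelated night activity
  packed <- rec_from_counts(counts)
  expect_equal(anticipation_index(packed, "lights_off"), 1.0)

  # linear ramp over the 6-h window, evaluated at bin midpoints -> 3/4
  ramp <- rep(0L, 288L)
  ramp[(144 - 72 + 1):144] <- 2L * (0:71) + 1L
  expect_equal(anticipation_index(rec_from_counts(ramp), "lights_off"), 0.75)
})

test_that("anticipation is scale-invariant and averages across cycles", {
  set.seed(13)
  counts <- rpois(288L * 4, 3) + 1L
  r1 <- rec_from_counts(counts)
  r10 <- rec_from_counts(counts * 10L)
  a1 <- anticipation_index(r1, "lights_off")
  expect_equal(a1, anticipation_index(r10, "lights_off"))
  # manual per-cycle oracle
  per_cycle <- vapply(1:4, function(d) {
    idx <- (d - 1) * 288 + ((144 - 72 + 1):144)
    sum(counts[idx[37:72]]) / sum(counts[idx])
  }, numeric(1))
  expect_equal(a1, mean(per_cycle))
})

test_that("anticipation skips dead/masked/empty cycles and can be NA", {
  # zero long window in every cycle -> NA
  quiet <- rep(0L, 288L)
  quiet[200] <- 3L
  expect_true(is.na(anticipation_index(rec_from_counts(quiet), "lights_off")))

  # ZT12 falls at bins 145 and 433 of a 2-day record; masking inside the
  # first pre-transition window leaves only cycle 2 contributing
  counts <- rep(1L, 576L)
  counts[397:432] <- 9L  # extra activity in cycle 2's last 3 h before ZT12
  masked <- rep(FALSE, 576L)
  masked[100] <- TRUE    # inside cycle 1's 6-h window (bins 73..144)
  r <- rec_from_counts(counts, masked = masked)
  a <- anticipation_index(r, "lights_off")
  counts2 <- counts[361:432]
  expect_equal(a, sum(counts2[37:72]) / sum(counts2))
})

test_that("actograms double-plot with the row-overlap identity", {
  set.seed(3)
  counts <- rpois(288L * 3, 2)
  m <- actogram_matrix(rec_from_counts(counts))
  expect_equal(dim(m), c(2, 576))
  expect_equal(m[1, 1:288], counts[1:288], ignore_attr = TRUE)
  # left half of row d equals right half of row d-1
  expect_equal(m[2, 1:288], m[1, 289:576], ignore_attr = TRUE)

  expect_warning(m1 <- actogram_matrix(rec_from_counts(rpois(300, 1))),
                 "single")
  expect_equal(dim(m1), c(1, 288))
})

test_that("actogram column means show the programmed night trough", {
  cfg <- sim_genotype_config(
    "g", 1, lifespan = list(dist = "exponential", median = 500))
  sim <- simulate_fly(cfg, 5, n_days = 10)
  m <- actogram_matrix(sim$recording)
  day_mean <- mean(m[, 1:144])
  night_mean <- mean(m[, 145:288])
  expect_lt(night_mean, day_mean)
})

test_that("age strata comparison matches the closed-form Student t", {
  daily <- data.frame(
    fly_id = rep(sprintf("f%d", 1:6), each = 2),
    genotype = rep(c("A", "B"), each = 6),
    day_index = rep(c(2L, 20L), 6),
    value = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6),
    age_class = rep(c("young", "old"), 6),
    stringsAsFactors = FALSE
  )
  res <- age_strata_compare(daily, "value", "A", "B")
  young <- res[res$stratum == "young", ]
  expect_equal(young$mean_a, 2)
  expect_equal(young$mean_b, 5)
  expect_equal(young$t, -3.674, tolerance = 1e-3)
  expect_equal(young$df, 4)
  expect_equal(young$p_value, 0.0214, tolerance = 1e-2)

  # identical groups: t = 0, p = 1
  daily2 <- daily
  daily2$value <- 1
  res2 <- age_strata_compare(daily2, "value", "A", "B")
  expect_equal(res2$t, c(0, 0))
  expect_equal(res2$p_value, c(1, 1))

  # a stratum with < 2 flies reports NA
  daily3 <- daily[daily$genotype == "B" | daily$fly_id == "f1", ]
  res3 <- age_strata_compare(daily3, "value", "A", "B")
  expect_true(all(is.na(res3$p_value)))
})

test_that("a programmed activity deficit is detected in the young stratum", {
  base <- activity_template_bimodal()
  cfg_a <- sim_genotype_config(
    "ctrl", 10, template = base,
    lifespan = list(dist = "exponential", median = 300))
  cfg_b <- sim_genotype_config(
    "weak", 10, template = base * 0.7,
    lifespan = list(dist = "exponential", median = 300))
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    sims <- c(simulate_cohort(cfg_a, 100 + r, n_days = 6)$recordings,
              simulate_cohort(cfg_b, 200 + r, n_days = 6,
                              monitor = "M2")$recordings)
    sc <- suppressMessages(score_cohort(sims, horizon_days = 6))
    res <- age_strata_compare(sc$daily, "total_counts", "ctrl", "weak")
    p <- res$p_value[res$stratum == "young"]
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})
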