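#' Population activity or sleep profile in Zeitgeber time
#'
#' Averages activity (or sleep) per ZT bin, first within fly across its
#' living days and then across flies, so long-lived flies do not dominate;
#' SEM is computed across flies (sample SD, n - 1). Only living, unmasked
#' fly-bins contribute. For sleep the default metric is the fraction of
#' time asleep, which with fly-first averaging equals the mean "percent of
#' flies sleeping" per bin; a pooled fly-day mode is available.
#'
#' @param bins Long per-bin table from [score_cohort()].
#' @param metric `"activity"` (mean counts per bin) or `"sleep"`
#'   (fraction asleep in `[0, 1]`).
#' @param average `"fly_first"` (default) or `"pool"` (pool all fly-days).
#' @return A data frame: `genotype`, `zt_bin` (0-based), `zt_minutes`,
#'   `mean`, `sem`, `n` (flies, or fly-days when pooling).
#' @export
population_profile <- function(bins, metric = c("activity", "sleep"),
                               average = c("fly_first", "pool")) {
  metric <- match.arg(metric)
  average <- match.arg(average)
  if (!nrow(bins)) stop("Empty bin table.", call. = FALSE)
  use <- bins$alive & !bins$masked
  if (metric == "sleep") use <- use & !is.na(bins$asleep)
  b <- bins[use, , drop = FALSE]
  b$value <- if (metric == "activity") b$counts else as.numeric(b$asleep)

  out <- lapply(split(b, b$genotype), function(g) {
    if (!nrow(g)) stop("Empty genotype group in profile.", call. = FALSE)
    if (average == "fly_first") {
      # mean per fly per zt bin, then across flies
      per_fly <- stats::aggregate(value ~ fly_id + zt_minutes, g, mean)
      agg <- stats::aggregate(value ~ zt_minutes, per_fly, function(v) {
        c(mean = mean(v), sem = sem(v), n = length(v))
      })
    } else {
      agg <- stats::aggregate(value ~ zt_minutes, g, function(v) {
        c(mean = mean(v), sem = sem(v), n = length(v))
      })
    }
    data.frame(
      genotype = g$genotype[1],
      zt_minutes = agg$zt_minutes,
      mean = agg$value[, "mean"],
      sem = agg$value[, "sem"],
      n = agg$value[, "n"],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  bin_min <- min(diff(sort(unique(out$zt_minutes))), 1440)
  out$zt_bin <- as.integer(out$zt_minutes / bin_min)
  out[order(out$genotype, out$zt_bin),
      c("genotype", "zt_bin", "zt_minutes", "mean", "sem", "n")]
}

sem <- function(v) {
  n <- length(v)
  if (n < 2L) return(NA_real_)
  stats::sd(v) / sqrt(n)
}

#' Anticipation of a light transition
#'
#' The rise in activity preceding lights-on (ZT0, morning anticipation) or
#' lights-off (ZT12, evening anticipation), quantified per cycle as the
#' activity in the last `short` minutes before the transition divided by
#' the activity in the last `long` minutes (default 3 h / 6 h), then
#' averaged across cycles. Perfectly flat activity gives 0.5; all activity
#' packed into the final window gives 1. Cycles with an incomplete,
#' masked, or dead pre-transition window are skipped; cycles with zero
#' activity in the long window are skipped, and the index is `NA` if no
#' cycle qualifies. The index is invariant to rescaling all counts.
#'
#' @param rec An [activity_recording()].
#' @param transition `"lights_on"` (ZT0) or `"lights_off"` (ZT12).
#' @param windows Lengths in minutes of the (long, short) pre-transition
#'   windows, default `c(360, 180)`.
#' @param vitals Optional [call_death()] row; post-death cycles are skipped.
#' @return A single numeric index in `[0, 1]`, or `NA`.
#' @export
anticipation_index <- function(rec, transition = c("lights_on", "lights_off"),
                               windows = c(360, 180), vitals = NULL) {
  transition <- match.arg(transition)
  sch <- rec$schedule
  bin <- sch$bin_minutes
  if (any(windows %% bin != 0) || windows[2] >= windows[1]) {
    stop("Windows must be whole bins with short < long.", call. = FALSE)
  }
  long_bins <- windows[1] %/% bin
  short_bins <- windows[2] %/% bin
  zt <- assign_zt(rec)
  target <- if (transition == "lights_on") 0 else sch$photoperiod_minutes
  trans <- which(zt == target)
  n <- n_bins(rec)
  last_live <- if (!is.null(vitals) && isTRUE(vitals$dead)) vitals$death_bin - 1L else n

  ratios <- c()
  for (t in trans) {
    lo <- t - long_bins
    if (lo < 1L || t - 1L > last_live) next
    idx <- lo:(t - 1L)
    if (any(rec$masked[idx])) next
    total <- sum(rec$counts[idx])
    if (total == 0L) next
    late <- sum(rec$counts[(t - short_bins):(t - 1L)])
    ratios <- c(ratios, late / total)
  }
  if (!length(ratios)) return(NA_real_)
  mean(ratios)
}

#' Double-plotted actogram matrix
#'
#' The conventional actogram raster: one row per day, each row showing day
#' *d* followed by day *d + 1* (so consecutive rows overlap by one day and
#' the left half of row *d* equals the right half of row *d - 1*). With
#' fewer than 2 complete days a single-plot matrix is returned with a
#' warning.
#'
#' @param rec An [activity_recording()].
#' @return An integer matrix; `n_days - 1` rows of `2 * bins_per_day`
#'   columns (or 1 row of `bins_per_day` for the single-plot fallback).
#' @export
actogram_matrix <- function(rec) {
  stopifnot(inherits(rec, "activity_recording"))
  sch <- rec$schedule
  bpd <- sch$period_minutes %/% sch$bin_minutes
  nd <- n_bins(rec) %/% bpd
  if (nd < 1L) stop("Recording shorter than one day.", call. = FALSE)
  day_rows <- matrix(rec$counts[seq_len(nd * bpd)], nrow = nd, byrow = TRUE)
  if (nd < 2L) {
    warning("Fewer than 2 complete days: returning a single-plotted actogram.",
            call. = FALSE)
    rownames(day_rows) <- "day1"
    return(day_rows)
  }
  out <- cbind(day_rows[-nd, , drop = FALSE], day_rows[-1L, , drop = FALSE])
  rownames(out) <- paste0("day", seq_len(nd - 1L))
  out
}

#' Compare young and old strata between genotypes
#'
#' Each fly contributes one mean per age stratum (the fly is the unit of
#' replication); strata are compared between two genotypes with an
#' unpaired two-tailed Student t-test (Welch available via `var_equal`).
#' Strata with fewer than 2 flies in either group report `NA` statistics.
#'
#' @param daily Daily-summary table from [score_cohort()].
#' @param metric Name of the daily column to compare
#'   (e.g. `"total_counts"`, `"sleep_minutes"`).
#' @param group_a,group_b Genotype labels.
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @return A data frame with one row per stratum (`young`, `old`):
#'   group means, sems, ns, `t`, `df`, `p_value`.
#' @export
age_strata_compare <- function(daily, metric, group_a, group_b,
                               var_equal = TRUE) {
  if (!metric %in% names(daily)) {
    stop("No such daily metric: ", metric, call. = FALSE)
  }
  rows <- lapply(c("young", "old"), function(stratum) {
    d <- daily[daily$age_class == stratum, , drop = FALSE]
    fly_means <- function(g) {
      dd <- d[d$genotype == g, , drop = FALSE]
      if (!nrow(dd)) return(numeric(0))
      as.numeric(tapply(dd[[metric]], dd$fly_id, mean, na.rm = TRUE))
    }
    xa <- fly_means(group_a)
    xb <- fly_means(group_b)
    tt <- student_t(xa, xb, var_equal = var_equal)
    data.frame(
      stratum = stratum, metric = metric,
      group_a = group_a, group_b = group_b,
      mean_a = if (length(xa)) mean(xa) else NA_real_, sem_a = sem(xa),
      n_a = length(xa),
      mean_b = if (length(xb)) mean(xb) else NA_real_, sem_b = sem(xb),
      n_b = length(xb),
      t = tt$t, df = tt$df, p_value = tt$p_value, method = tt$method,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
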