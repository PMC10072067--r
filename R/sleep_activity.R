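#' Score sleep from binned counts
#'
#' Implements the standard fly sleep definition: five consecutive minutes
#' of zero beam breaks. At the native 5-min acquisition a single zero bin
#' is therefore one sleep bin; a longer threshold (expressed in minutes,
#' a whole multiple of the bin width) requires a run of zero bins at least
#' that long before any of its bins score as sleep. Masked bins and bins
#' at or after death are `NA` (sleep undefined there) and interrupt runs.
#'
#' @param rec An [activity_recording()].
#' @param vitals Optional row from [call_death()] for this fly; bins from
#'   `death_bin` onwards are set to `NA`.
#' @param threshold_minutes Minimum uninterrupted inactivity to count as
#'   sleep, default 5.
#' @return Logical vector, one value per bin (`NA` = undefined).
#' @export
score_sleep <- function(rec, vitals = NULL, threshold_minutes = 5) {
  stopifnot(inherits(rec, "activity_recording"))
  bin <- rec$schedule$bin_minutes
  if (threshold_minutes <= 0 || threshold_minutes %% bin != 0) {
    stop(sprintf(
      "Sleep threshold (%s min) must be a positive multiple of the %d-min bin.",
      format(threshold_minutes), bin), call. = FALSE)
  }
  k <- threshold_minutes %/% bin
  valid <- !rec$masked
  if (!is.null(vitals) && isTRUE(vitals$dead)) {
    valid[seq_len(n_bins(rec)) >= vitals$death_bin] <- FALSE
  }
  zero <- rec$counts == 0L & valid
  r <- rle(zero)
  r$values <- r$values & r$lengths >= k
  asleep <- inverse.rle(r)
  asleep[!valid] <- NA
  asleep
}

#' Find maximal runs of a boolean series (sleep/rest bouts)
#'
#' A rest bout is a maximal run of consecutive inactive (asleep) bins.
#' `NA` values break runs and never belong to a bout.
#'
#' @param series Logical vector (e.g. from [score_sleep()]).
#' @return A data frame with one row per bout: `start_bin` (1-based index
#'   of the first bin) and `length_bins`.
#' @export
find_bouts <- function(series) {
  x <- !is.na(series) & series
  if (!length(x) || !any(x)) {
    return(data.frame(start_bin = integer(0), length_bins = integer(0)))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_bin = starts[keep], length_bins = r$lengths[keep])
}

#' Call death from terminal inactivity
#'
#' A fly is scored dead when the maximal run of zero-count bins at the end
#' of the recording is strictly longer than `threshold_hours` (default 24 h,
#' i.e. "more than 24 hours" of terminal silence). Death is placed at the
#' START of that run — the bin after the fly's last movement — so the silent
#' tail does not count as lived time. Flies that survive the analysis
#' horizon are right-censored there; flies whose recording ends early with a
#' sub-threshold silent tail are censored at the recording end. Masked bins
#' cannot break a silent run (their counts are untrusted) but a death call
#' still requires the run to exceed the threshold.
#'
#' @param rec An [activity_recording()].
#' @param threshold_hours Terminal silence needed to call death (default 24).
#'   Must be a whole number of bins.
#' @param horizon_days Analysis horizon in days (default 30); deaths after
#'   the horizon are treated as censoring at the horizon.
#' @return A one-row data frame (`fly_id`, `genotype`, `dead`, `death_bin`,
#'   `lifespan_days`, `censor_day`).
#' @export
call_death <- function(rec, threshold_hours = 24, horizon_days = 30) {
  stopifnot(inherits(rec, "activity_recording"))
  bin <- rec$schedule$bin_minutes
  thr_min <- threshold_hours * 60
  if (thr_min <= 0 || abs(thr_min %% bin) > 1e-9) {
    stop(sprintf(
      "Death threshold (%s h) must be a whole number of %d-min bins.",
      format(threshold_hours), bin), call. = FALSE)
  }
  thr_bins <- as.integer(round(thr_min / bin))
  n <- n_bins(rec)
  silent <- rec$counts == 0L | rec$masked

  dead <- FALSE
  death_bin <- NA_integer_
  if (silent[n]) {
    r <- rle(silent)
    tail_len <- r$lengths[length(r$lengths)]
    if (tail_len > thr_bins) {
      dead <- TRUE
      death_bin <- n - tail_len + 1L
    }
  }
  rec_days <- n * bin / 1440
  if (dead) {
    lifespan <- (death_bin - 1L) * bin / 1440
    if (lifespan > horizon_days) {
      dead <- FALSE
      death_bin <- NA_integer_
      lifespan <- horizon_days
    }
  } else {
    lifespan <- min(rec_days, horizon_days)
  }
  data.frame(
    fly_id = rec$fly_id,
    genotype = rec$genotype,
    dead = dead,
    death_bin = death_bin,
    lifespan_days = lifespan,
    censor_day = horizon_days,
    stringsAsFactors = FALSE
  )
}

#' Wake activity: beam breaks per waking minute
#'
#' Total counts over the awake, living, unmasked bins of a window, divided
#' by the waking minutes in that window. Returns `NA` (not 0) when the
#' window contains no awake bins.
#'
#' @param rec An [activity_recording()].
#' @param sleep Logical vector from [score_sleep()].
#' @param window `"24h"` (whole cycle), `"day"` (lights-on bins) or
#'   `"night"`.
#' @return Counts per waking minute, or `NA`.
#' @export
wake_activity <- function(rec, sleep, window = c("24h", "day", "night")) {
  window <- match.arg(window)
  in_window <- switch(window,
    "24h" = rep(TRUE, n_bins(rec)),
    "day" = zt_is_light(assign_zt(rec), rec$schedule),
    "night" = !zt_is_light(assign_zt(rec), rec$schedule)
  )
  awake <- in_window & !is.na(sleep) & !sleep
  if (!any(awake)) return(NA_real_)
  sum(rec$counts[awake]) / (rec$schedule$bin_minutes * sum(awake))
}

#' Per-day behavioural summaries for one fly
#'
#' One row per complete living day, days running ZT0 to ZT0 (a leading
#' partial day before the first ZT0 bin is skipped; the day of death and
#' anything past the horizon are excluded). Sleep bouts are counted
#' separately for the light and dark half of each day, so a bout spanning
#' the ZT12 boundary contributes one bout to each side. Age classes follow
#' the 1-13 day ("young") / 14-30 day ("old") convention.
#'
#' @param rec An [activity_recording()].
#' @param sleep Logical vector from [score_sleep()] (scored with the same
#'   vitals).
#' @param vitals One-row data frame from [call_death()].
#' @param young_max_day Last day of the "young" stratum (default 13).
#' @return A data frame with one row per living day.
#' @export
daily_summaries <- function(rec, sleep, vitals, young_max_day = 13) {
  stopifnot(inherits(rec, "activity_recording"))
  sch <- rec$schedule
  bins_per_day <- sch$period_minutes %/% sch$bin_minutes
  zt <- assign_zt(rec)
  first_zt0 <- which(zt == 0)[1]
  if (is.na(first_zt0)) return(empty_daily_df())
  n <- n_bins(rec)
  horizon_bins <- vitals$censor_day * 1440 / sch$bin_minutes
  last_bin <- min(n, first_zt0 - 1L + floor(horizon_bins))

  rows <- list()
  day <- 0L
  start <- first_zt0
  while (start + bins_per_day - 1L <= last_bin) {
    day <- day + 1L
    idx <- start:(start + bins_per_day - 1L)
    start <- start + bins_per_day
    if (isTRUE(vitals$dead) && idx[length(idx)] >= vitals$death_bin) break
    live <- !rec$masked[idx]
    if (!any(live)) next
    s <- sleep[idx]
    light <- zt_is_light(zt[idx], sch)
    asleep <- !is.na(s) & s
    awake <- !is.na(s) & !s
    wk_day <- if (any(awake & light)) {
      sum(rec$counts[idx][awake & light]) / (sch$bin_minutes * sum(awake & light))
    } else NA_real_
    wk_night <- if (any(awake & !light)) {
      sum(rec$counts[idx][awake & !light]) / (sch$bin_minutes * sum(awake & !light))
    } else NA_real_
    rows[[day]] <- data.frame(
      fly_id = rec$fly_id,
      genotype = rec$genotype,
      day_index = day,
      total_counts = sum(rec$counts[idx][live]),
      n_living_bins = sum(live),
      sleep_minutes = sch$bin_minutes * sum(asleep),
      wake_minutes = sch$bin_minutes * sum(awake),
      sleep_minutes_day = sch$bin_minutes * sum(asleep & light),
      sleep_minutes_night = sch$bin_minutes * sum(asleep & !light),
      wake_activity_day = wk_day,
      wake_activity_night = wk_night,
      n_sleep_bouts_day = nrow(find_bouts(s[light])),
      n_sleep_bouts_night = nrow(find_bouts(s[!light])),
      age_class = if (day <= young_max_day) "young" else "old",
      stringsAsFactors = FALSE
    )
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_daily_df())
  do.call(rbind, rows)
}

empty_daily_df <- function() {
  data.frame(
    fly_id = character(0), genotype = character(0), day_index = integer(0),
    total_counts = integer(0), n_living_bins = integer(0),
    sleep_minutes = numeric(0), wake_minutes = numeric(0),
    sleep_minutes_day = numeric(0), sleep_minutes_night = numeric(0),
    wake_activity_day = numeric(0), wake_activity_night = numeric(0),
    n_sleep_bouts_day = integer(0), n_sleep_bouts_night = integer(0),
    age_class = character(0), stringsAsFactors = FALSE
  )
}

#' Score a whole cohort
#'
#' Runs death calling, sleep scoring and daily summaries over a list of
#' recordings and returns tidy tables ready for profiling and survival
#' statistics. Flies dying on day 1 (dead on arrival) are kept in the
#' vitals (survival must not drop events) but excluded from the behavioural
#' tables, with a message.
#'
#' @param recordings List of [activity_recording()] objects.
#' @param threshold_hours,horizon_days Passed to [call_death()].
#' @param sleep_threshold_minutes Passed to [score_sleep()].
#' @param young_max_day Passed to [daily_summaries()].
#' @return A list with `vitals` (one row per fly), `daily` (one row per
#'   living fly-day) and `bins` (long per-bin table with `asleep` and
#'   `alive` flags).
#' @export
score_cohort <- function(recordings, threshold_hours = 24, horizon_days = 30,
                         sleep_threshold_minutes = 5, young_max_day = 13) {
  recordings <- Filter(function(r) !is.na(r$genotype), recordings)
  if (!length(recordings)) stop("No recordings with genotype labels.", call. = FALSE)
  vitals <- list(); daily <- list(); bins <- list()
  n_doa <- 0L
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    v <- call_death(rec, threshold_hours, horizon_days)
    vitals[[i]] <- v
    doa <- isTRUE(v$dead) && v$lifespan_days < 1
    if (doa) {
      n_doa <- n_doa + 1L
      next
    }
    s <- score_sleep(rec, v, sleep_threshold_minutes)
    daily[[i]] <- daily_summaries(rec, s, v, young_max_day)
    b <- as.data.frame(rec)
    b$asleep <- s
    horizon_bin <- v$censor_day * 1440 / rec$schedule$bin_minutes
    b$alive <- b$bin_index <= horizon_bin &
      (!isTRUE(v$dead) | b$bin_index < v$death_bin)
    bins[[i]] <- b
  }
  if (n_doa > 0L) {
    message(sprintf(
      "%d fly/flies dead on arrival (day 1): kept in vitals, excluded from behavioural tables.",
      n_doa))
  }
  list(
    vitals = do.call(rbind, vitals),
    daily = do.call(rbind, Filter(Negate(is.null), daily)),
    bins = do.call(rbind, Filter(Negate(is.null), bins))
  )
}
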