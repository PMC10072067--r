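# Shared fixtures and independent oracles used across test files.

sched5 <- light_schedule("08:00")

# Minimal recording straight from a counts vector (starts at lights-on).
rec_from_counts <- function(counts, schedule = sched5, masked = NULL,
                            genotype = "test") {
  activity_recording("T#01", counts, schedule, masked = masked,
                     genotype = genotype, monitor = "T", channel = 1L)
}

# Brute-force run-length oracle: scan bin by bin, independent of rle().
naive_bouts <- function(series) {
  starts <- integer(0)
  lengths <- integer(0)
  run <- 0L
  for (i in seq_along(series)) {
    on <- !is.na(series[i]) && series[i]
    if (on) {
      if (run == 0L) starts <- c(starts, i)
      run <- run + 1L
    } else if (run > 0L) {
      lengths <- c(lengths, run)
      run <- 0L
    }
  }
  if (run > 0L) lengths <- c(lengths, run)
  data.frame(start_bin = starts, length_bins = lengths)
}

# Empirical survival function (no censoring): fraction still alive past t.
empirical_survival <- function(times, t) {
  vapply(t, function(tt) mean(times > tt), numeric(1))
}

# Write a hand-rolled 42-column monitor file for parser tests.
write_fake_dam <- function(path, counts_matrix,
                           start = as.POSIXct("2024-01-01 08:00:00",
                                              tz = "UTC"),
                           bin_minutes = 5, status = NULL) {
  n <- nrow(counts_matrix)
  stopifnot(ncol(counts_matrix) == 32L)
  if (is.null(status)) status <- rep(1L, n)
  ts <- start + (seq_len(n) - 1L) * bin_minutes * 60
  lines <- vapply(seq_len(n), function(i) {
    paste(c(i, format(ts[i], "%d %b %y"), format(ts[i], "%H:%M:%S"),
            status[i], rep(0L, 6), counts_matrix[i, ]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

vitals_row <- function(lifespan_days, dead, genotype = "g",
                       fly_id = "f", censor_day = 30) {
  data.frame(fly_id = fly_id, genotype = genotype, dead = dead,
             death_bin = NA_integer_, lifespan_days = lifespan_days,
             censor_day = censor_day, stringsAsFactors = FALSE)
}

vitals_df <- function(lifespans, dead, genotype = "g") {
  data.frame(fly_id = sprintf("%s_%02d", genotype, seq_along(lifespans)),
             genotype = genotype, dead = dead, death_bin = NA_integer_,
             lifespan_days = lifespans, censor_day = 30,
             stringsAsFactors = FALSE)
}
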