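#' Construct a per-fly activity recording
#'
#' The raw material of the pipeline: one fly's beam-break counts in
#' contiguous, uniform time bins, together with the light schedule that
#' anchors Zeitgeber time and a per-bin mask for monitor rows whose status
#' code was not OK.
#'
#' @param fly_id Identifier, conventionally `"<monitor>#<channel>"`.
#' @param counts Non-negative integer vector of beam breaks per bin.
#' @param schedule A [light_schedule()].
#' @param start_time `POSIXct` timestamp of the first bin (optional for
#'   simulated data; if missing, the recording is assumed to start at
#'   lights-on).
#' @param genotype Genotype label (may be `NA` until a manifest is applied).
#' @param masked Logical vector, `TRUE` where the monitor status was not OK.
#'   Masked bins are retained but excluded from all scoring denominators.
#' @param monitor,channel Provenance of the recording.
#' @return An object of class `activity_recording`.
#' @export
activity_recording <- function(fly_id, counts, schedule,
                               start_time = NULL, genotype = NA_character_,
                               masked = NULL, monitor = NA_character_,
                               channel = NA_integer_) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (length(counts) == 0L) stop("counts must be non-empty.", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing.", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers (beam breaks).", call. = FALSE)
  }
  if (is.null(masked)) masked <- rep(FALSE, length(counts))
  if (length(masked) != length(counts)) {
    stop("masked must have one value per bin.", call. = FALSE)
  }
  if (is.null(start_time)) {
    start_clock_minutes <- schedule$lights_on_minutes
  } else {
    stopifnot(inherits(start_time, "POSIXct"))
    lt <- as.POSIXlt(start_time)
    start_clock_minutes <- lt$hour * 60 + lt$min + lt$sec / 60
  }
  structure(
    list(
      fly_id = as.character(fly_id),
      genotype = as.character(genotype),
      counts = as.integer(round(counts)),
      masked = as.logical(masked),
      schedule = schedule,
      start_time = start_time,
      start_clock_minutes = start_clock_minutes,
      monitor = as.character(monitor),
      channel = as.integer(channel)
    ),
    class = "activity_recording"
  )
}

#' @export
print.activity_recording <- function(x, ...) {
  cat(sprintf(
    "<activity_recording> %s (%s): %d bins x %d min (%.1f days), %d masked\n",
    x$fly_id, x$genotype, length(x$counts), x$schedule$bin_minutes,
    length(x$counts) * x$schedule$bin_minutes / 1440, sum(x$masked)
  ))
  invisible(x)
}

n_bins <- function(rec) length(rec$counts)

#' Parse a TriKinetics DAM monitor file
#'
#' Reads the tab-separated Monitor file dialect written by DAMSystem:
#' reading index, date (`"d mmm yy"`), time (`"HH:MM:SS"`), a status code,
#' further metadata columns, then one count column per channel (32 channels
#' and 10 metadata columns in the common 42-column file). Column count is
#' validated per file and fails loudly rather than guessing at other
#' dialects. Rows whose status code differs from `ok_status` are retained
#' but masked; timestamps must be strictly increasing and uniformly spaced
#' at the schedule's bin width.
#'
#' @param path Path to the monitor file.
#' @param schedule A [light_schedule()]; its `bin_minutes` must match the
#'   file's acquisition interval.
#' @param n_channels Number of channel columns (default 32).
#' @param n_meta Number of metadata columns preceding the channels
#'   (default 10: index, date, time, status and six more).
#' @param ok_status Status code meaning a valid reading (default 1).
#' @param monitor Monitor label used in fly ids; defaults to the file name
#'   without extension.
#' @return A list of [activity_recording()] objects, one per channel.
#' @export
parse_monitor_file <- function(path, schedule, n_channels = 32L,
                               n_meta = 10L, ok_status = 1L,
                               monitor = NULL) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (!file.exists(path)) stop("No such monitor file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("Monitor file is empty: ", path, call. = FALSE)
  }
  if (is.null(monitor)) monitor <- sub("\\.[^.]*$", "", basename(path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  expected <- n_meta + n_channels
  nf <- lengths(fields)
  bad <- which(nf != expected)
  if (length(bad)) {
    stop(sprintf(
      "Malformed row in %s at line %d: %d columns, expected %d.",
      path, bad[1], nf[bad[1]], expected
    ), call. = FALSE)
  }
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)

  ts <- as.POSIXct(paste(m[, 2], m[, 3]),
                   format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    stop(sprintf("Unparseable timestamp in %s at line %d.",
                 path, which(is.na(ts))[1]), call. = FALSE)
  }
  if (length(ts) > 1L) {
    dt <- diff(as.numeric(ts)) / 60
    if (any(dt <= 0)) {
      stop(sprintf("Non-monotone timestamps in %s at line %d.",
                   path, which(dt <= 0)[1] + 1L), call. = FALSE)
    }
    if (any(abs(dt - schedule$bin_minutes) > 1e-6)) {
      stop(sprintf(
        "Row spacing in %s is not uniform at the %d-min bin width (line %d).",
        path, schedule$bin_minutes, which(abs(dt - schedule$bin_minutes) > 1e-6)[1] + 1L
      ), call. = FALSE)
    }
  }

  status <- suppressWarnings(as.integer(m[, 4]))
  masked <- is.na(status) | status != as.integer(ok_status)
  counts <- suppressWarnings(
    matrix(as.integer(m[, (n_meta + 1L):expected]), nrow = nrow(m))
  )
  if (anyNA(counts)) {
    stop(sprintf("Non-integer count in %s at line %d.",
                 path, which(rowSums(is.na(counts)) > 0)[1]), call. = FALSE)
  }
  if (any(counts < 0)) {
    stop(sprintf("Negative count in %s at line %d.",
                 path, which(rowSums(counts < 0) > 0)[1]), call. = FALSE)
  }

  lapply(seq_len(n_channels), function(ch) {
    activity_recording(
      fly_id = sprintf("%s#%02d", monitor, ch),
      counts = counts[, ch],
      schedule = schedule,
      start_time = ts[1],
      masked = masked,
      monitor = monitor,
      channel = ch
    )
  })
}

#' Read a cohort manifest
#'
#' A manifest maps monitor channels to genotypes: a CSV with header
#' `monitor_file,channel,genotype`. Channels must lie in 1..32, genotype
#' labels must be non-empty, and `(monitor_file, channel)` pairs must be
#' unique.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with columns `monitor_file`, `channel`, `genotype`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("No such manifest: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("monitor_file", "channel", "genotype")
  if (!all(required %in% names(man))) {
    stop("Manifest must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  man$channel <- as.integer(man$channel)
  if (any(is.na(man$channel)) || any(man$channel < 1L | man$channel > 32L)) {
    stop("Manifest channels must be integers in 1..32.", call. = FALSE)
  }
  if (any(!nzchar(trimws(man$genotype)))) {
    stop("Manifest genotype labels must be non-empty.", call. = FALSE)
  }
  key <- paste(man$monitor_file, man$channel)
  if (anyDuplicated(key)) {
    stop("Duplicate (monitor_file, channel) in manifest: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  man
}

#' Attach genotype labels from a manifest
#'
#' Channels not listed in the manifest keep genotype `NA` (e.g. empty
#' tubes); downstream cohort functions drop unlabelled recordings.
#'
#' @param recordings List of recordings from [parse_monitor_file()].
#' @param manifest Data frame from [read_manifest()].
#' @param monitor_file The monitor file name the recordings came from.
#' @return The recordings with `genotype` filled in.
#' @export
apply_manifest <- function(recordings, manifest, monitor_file) {
  rows <- manifest[manifest$monitor_file == monitor_file, , drop = FALSE]
  lapply(recordings, function(rec) {
    hit <- rows$channel == rec$channel
    if (any(hit)) rec$genotype <- rows$genotype[hit][1]
    rec
  })
}

#' Aggregate a recording to wider time bins
#'
#' Sums counts within each target bin (total counts conserved); supports
#' e.g. 1-min raw acquisitions aggregated to the standard 5-min bins. A
#' trailing partial bin is discarded with a warning. A target bin is masked
#' if any contributing source bin was masked.
#'
#' @param rec An [activity_recording()].
#' @param target_bin_minutes New bin width; must be a positive multiple of
#'   the current width.
#' @return A rebinned [activity_recording()].
#' @export
rebin <- function(rec, target_bin_minutes) {
  stopifnot(inherits(rec, "activity_recording"))
  src <- rec$schedule$bin_minutes
  target_bin_minutes <- as.integer(target_bin_minutes)
  if (target_bin_minutes <= 0L || target_bin_minutes %% src != 0L) {
    stop(sprintf("target_bin_minutes (%d) must be a positive multiple of %d.",
                 target_bin_minutes, src), call. = FALSE)
  }
  k <- target_bin_minutes %/% src
  if (k == 1L) return(rec)
  n_full <- length(rec$counts) %/% k
  dropped <- length(rec$counts) - n_full * k
  if (dropped > 0L) {
    warning(sprintf("rebin: discarding trailing partial bin (%d source bins).",
                    dropped), call. = FALSE)
  }
  idx <- seq_len(n_full * k)
  grp <- rep(seq_len(n_full), each = k)
  sched <- rec$schedule
  sched$bin_minutes <- target_bin_minutes
  out <- rec
  out$counts <- as.integer(tapply(rec$counts[idx], grp, sum))
  out$masked <- as.logical(tapply(rec$masked[idx], grp, any))
  out$schedule <- sched
  out
}

#' Zeitgeber time of each bin
#'
#' ZT of bin *i* is the clock time of its start minus the lights-on time,
#' modulo the cycle period; lights-on bins are exactly those with
#' ZT < photoperiod.
#'
#' @param rec An [activity_recording()].
#' @return Numeric vector of ZT values in minutes, one per bin, in
#'   `[0, period)`.
#' @export
assign_zt <- function(rec) {
  stopifnot(inherits(rec, "activity_recording"))
  sch <- rec$schedule
  if (is.null(sch$lights_on_minutes)) {
    stop("Schedule has no lights_on clock time; ZT cannot be assigned.",
         call. = FALSE)
  }
  starts <- rec$start_clock_minutes + (seq_len(n_bins(rec)) - 1L) * sch$bin_minutes
  (starts - sch$lights_on_minutes) %% sch$period_minutes
}

#' Tidy long-format view of a recording
#'
#' @param x An [activity_recording()].
#' @param ... Unused.
#' @return A data frame with one row per bin: `fly_id`, `genotype`,
#'   `bin_index` (1-based), `zt_minutes`, `light`, `counts`, `masked`.
#' @export
as.data.frame.activity_recording <- function(x, ...) {
  zt <- assign_zt(x)
  data.frame(
    fly_id = x$fly_id,
    genotype = x$genotype,
    bin_index = seq_len(n_bins(x)),
    zt_minutes = zt,
    light = zt_is_light(zt, x$schedule),
    counts = x$counts,
    masked = x$masked,
    stringsAsFactors = FALSE
  )
}
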