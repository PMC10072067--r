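#' Define a light:dark schedule
#'
#' A light schedule anchors Zeitgeber time (ZT): ZT0 is lights-on, and under
#' the default 12:12 LD cycle lights go off at ZT12 (720 min). All downstream
#' scoring and profiling is expressed in ZT.
#'
#' @param lights_on Clock time of lights-on as an `"HH:MM"` string. There is
#'   no default: ZT anchoring is meaningless if guessed, so the caller must
#'   supply it (the simulator starts its recordings at lights-on and fills
#'   this in itself).
#' @param period_minutes Length of one full cycle in minutes (default 1440).
#' @param photoperiod_minutes Minutes of light per cycle (default 720,
#'   i.e. 12:12 LD).
#' @param bin_minutes Width of one acquisition bin in minutes (default 5,
#'   the DAMSystem acquisition interval).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule("08:00")
#' @export
light_schedule <- function(lights_on,
                           period_minutes = 1440L,
                           photoperiod_minutes = 720L,
                           bin_minutes = 5L) {
  if (missing(lights_on) || is.null(lights_on)) {
    stop("`lights_on` must be given (\"HH:MM\"); ZT0 cannot be guessed.",
         call. = FALSE)
  }
  lights_on_minutes <- parse_clock_minutes(lights_on)
  period_minutes <- as.integer(period_minutes)
  photoperiod_minutes <- as.integer(photoperiod_minutes)
  bin_minutes <- as.integer(bin_minutes)
  if (photoperiod_minutes >= period_minutes) {
    stop("photoperiod_minutes must be shorter than period_minutes.",
         call. = FALSE)
  }
  if (period_minutes %% bin_minutes != 0L) {
    stop("period_minutes must be divisible by bin_minutes.", call. = FALSE)
  }
  if (bin_minutes <= 0L || photoperiod_minutes <= 0L) {
    stop("bin_minutes and photoperiod_minutes must be positive.",
         call. = FALSE)
  }
  structure(
    list(
      lights_on = lights_on,
      lights_on_minutes = lights_on_minutes,
      period_minutes = period_minutes,
      photoperiod_minutes = photoperiod_minutes,
      bin_minutes = bin_minutes
    ),
    class = "light_schedule"
  )
}

# "HH:MM" or "HH:MM:SS" -> minutes past midnight
parse_clock_minutes <- function(x) {
  if (is.numeric(x)) {
    m <- as.numeric(x)
  } else {
    parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
    if (!length(parts) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop("Clock time must be \"HH:MM\" or \"HH:MM:SS\", got: ", x,
           call. = FALSE)
    }
    parts <- as.numeric(parts)
    m <- parts[1] * 60 + parts[2] + if (length(parts) == 3L) parts[3] / 60 else 0
  }
  if (m < 0 || m >= 1440) stop("Clock time out of range: ", x, call. = FALSE)
  m
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_schedule> lights-on %s, %d:%d LD (h), %d-min bins\n",
    x$lights_on,
    x$photoperiod_minutes %/% 60L,
    (x$period_minutes - x$photoperiod_minutes) %/% 60L,
    x$bin_minutes
  ))
  invisible(x)
}

#' Is a given ZT (minutes) inside the photophase?
#'
#' @param zt_minutes Numeric vector of ZT values in minutes, in
#'   `[0, period)`.
#' @param schedule A [light_schedule()].
#' @return Logical vector: `TRUE` for lights-on bins (ZT < photoperiod).
#' @export
zt_is_light <- function(zt_minutes, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  zt_minutes < schedule$photoperiod_minutes
}
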