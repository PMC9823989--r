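#' Construct an RR-interval series
#'
#' An `rr_series` is a tibble with one row per heartbeat: `beat_time` (seconds
#' from record start, strictly increasing), `interval` (the RR interval ending
#' at that beat, in milliseconds) and `valid` (logical flag set by
#' [clean_rr()]; beats flagged invalid are excluded from feature computation).
#'
#' @param beat_time Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param interval Numeric vector of RR intervals in milliseconds, positive.
#' @param valid Logical vector (recycled) of per-beat validity flags.
#' @param record_id Identifier carried through all downstream tables.
#'
#' @return A tibble of class `rr_series` with columns `beat_time`, `interval`,
#'   `valid` and attribute `record_id`.
#' @examples
#' rr_series(c(0.8, 1.6, 2.4), c(800, 800, 800))
#' @export
rr_series <- function(beat_time, interval, valid = TRUE, record_id = "record") {
  beat_time <- as.numeric(beat_time)
  interval <- as.numeric(interval)
  if (length(beat_time) != length(interval)) {
    abort("`beat_time` and `interval` must have the same length.")
  }
  if (length(beat_time) == 0) abort("an rr_series needs at least one beat.")
  bad <- which(diff(beat_time) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("beat times must be strictly increasing (first violation at beat %d).", bad[1] + 1L))
  }
  if (any(interval <= 0)) abort("all intervals must be positive.")
  out <- tibble(
    beat_time = beat_time,
    interval = interval,
    valid = rep_len(as.logical(valid), length(beat_time))
  )
  attr(out, "record_id") <- record_id
  class(out) <- c("rr_series", class(out))
  out
}

#' @export
print.rr_series <- function(x, ...) {
  dur <- diff(range(x$beat_time))
  cat(sprintf(
    "<rr_series '%s'> %d beats over %.1f min (%.1f%% valid)\n",
    record_id(x), nrow(x), dur / 60, 100 * mean(x$valid)
  ))
  NextMethod()
}

#' Record identifier of a series or hypnogram
#' @param x An `rr_series` or `hypnogram`.
#' @return A character scalar.
#' @export
record_id <- function(x) attr(x, "record_id") %||% "record"

# keep rr_series class through dplyr verbs used internally
restore_rr <- function(out, template) {
  attr(out, "record_id") <- record_id(template)
  if (!inherits(out, "rr_series")) class(out) <- c("rr_series", class(out))
  out
}

#' Duration of an RR series in seconds
#' @param rr An `rr_series`.
#' @return Time of the last beat, seconds.
#' @export
rr_duration <- function(rr) max(rr$beat_time)

#' Restrict an RR series to a time window
#'
#' @param rr An `rr_series`.
#' @param from,to Window bounds in seconds, half-open `[from, to)`.
#' @param valid_only Drop beats flagged invalid?
#' @return An `rr_series` (possibly empty tibble if no beats fall inside).
#' @export
rr_slice_time <- function(rr, from, to, valid_only = FALSE) {
  keep <- rr$beat_time >= from & rr$beat_time < to
  if (valid_only) keep <- keep & rr$valid
  restore_rr(rr[keep, , drop = FALSE], rr)
}
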