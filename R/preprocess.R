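#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins style detector: band-pass 5-15 Hz, differentiate, square,
#' 150-ms moving-window integration, then adaptive dual-threshold peak picking
#' with a 200-ms refractory period and search-back at half threshold. Peak
#' positions are refined to the local maximum of the band-passed signal.
#'
#' @param ecg Numeric waveform, or an `ecg_record` from [read_ecg()].
#' @param rate Sampling rate in Hz (ignored when `ecg` is an `ecg_record`).
#' @return Integer vector of strictly increasing sample indices of detected
#'   R peaks (empty, with a warning, for flat input).
#' @export
detect_r_peaks <- function(ecg, rate = NULL) {
  if (inherits(ecg, "ecg_record")) {
    rate <- ecg$rate
    ecg <- ecg$signal
  }
  if (is.null(rate)) abort("`rate` is required.")
  if (rate < 100) abort("sampling rate must be at least 100 Hz.")
  if (length(ecg) < 10 * rate) abort("need at least 10 s of signal.")
  if (sd(ecg) < .Machine$double.eps^0.5) {
    warn("flat-line ECG: no peaks detected.")
    return(integer(0))
  }

  bp <- signal::butter(3, c(5, 15) / (rate / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg - mean(ecg))
  dx <- c(0, diff(xf))
  sq <- dx^2
  win <- max(1L, round(0.150 * rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  refr <- round(0.200 * rate)
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (length(cand) == 0) {
    warn("no peaks found in ECG.")
    return(integer(0))
  }
  spki <- max(integ[cand]) * 0.25
  npki <- mean(integ) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last < refr) next
    if (integ[i] > thr) {
      spki <- 0.125 * integ[i] + 0.875 * spki
      peaks <- c(peaks, i)
      last <- i
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) == 0) {
    warn("no peaks exceeded threshold.")
    return(integer(0))
  }
  # refine each detection to the band-passed local maximum within +-100 ms
  half <- round(0.100 * rate)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(xf), i + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  refined <- refined[c(TRUE, diff(refined) >= refr)]
  unique(refined)
}

#' Convert detected R-peak indices to an RR series
#'
#' @param peaks Sample indices from [detect_r_peaks()].
#' @param rate Sampling rate in Hz.
#' @param record_id Identifier.
#' @return An [rr_series()]; the first beat is dropped (no preceding interval).
#' @export
peaks_to_rr <- function(peaks, rate, record_id = "record") {
  if (length(peaks) < 2) abort("need at least two peaks to form intervals.")
  tm <- peaks / rate
  rr_series(tm[-1], diff(tm) * 1000, record_id = record_id)
}

#' Flag abnormal beats in an RR series
#'
#' Marks beats whose interval is longer than 2 s or shorter than 0.35 s, and
#' ectopic-looking beats whose interval differs from the running median of the
#' five surrounding plausible intervals by more than `irregular_tol`.
#' Flagging only: no beat is removed or interpolated, so the operation is
#' idempotent.
#'
#' @param rr An `rr_series`.
#' @param wide_ms,narrow_ms Interval bounds in ms (defaults 2000 and 350).
#' @param irregular_tol Relative deviation from the local median that marks a
#'   beat irregular (default 0.2).
#' @return The series with `valid` recomputed.
#' @export
clean_rr <- function(rr, wide_ms = 2000, narrow_ms = 350, irregular_tol = 0.2) {
  iv <- rr$interval
  in_range <- iv <= wide_ms & iv >= narrow_ms
  med <- local_valid_median(iv, in_range, k = 5L)
  irregular <- in_range & !is.na(med) & abs(iv - med) / med > irregular_tol
  rr$valid <- in_range & !irregular
  restore_rr(rr, rr)
}

# median of the five nearest in-range intervals (excluding self) around each
# beat, computed on the subsequence of in-range beats (offsets -3..-1, +1, +2)
local_valid_median <- function(iv, ok, k = 5L) {
  n <- length(iv)
  med <- rep(NA_real_, n)
  idx_ok <- which(ok)
  m <- length(idx_ok)
  if (m < 3) {
    return(med)
  }
  v <- iv[idx_ok]
  offsets <- c(-3L, -2L, -1L, 1L, 2L)
  shifted <- vapply(offsets, function(o) {
    j <- seq_len(m) + o
    out <- rep(NA_real_, m)
    keep <- j >= 1L & j <= m
    out[keep] <- v[j[keep]]
    out
  }, numeric(m))
  med[idx_ok] <- apply(shifted, 1L, median, na.rm = TRUE)
  med
}

#' Trim excess leading wakefulness
#'
#' If the record opens with a contiguous run of more than ten wake epochs
#' (5 min), everything before the final ten wake epochs is cut off, from both
#' the hypnogram and the RR series; beat times are shifted so that epoch 0
#' still starts at time 0.
#'
#' @param rr An `rr_series` aligned to `hyp` (beat times in `[0, 30*n_epochs)`).
#' @param hyp A `hypnogram`.
#' @return A list with elements `rr` and `hyp`.
#' @export
trim_leading_wake <- function(rr, hyp) {
  runs <- hyp_runs(hyp)
  if (runs$stage[1] != "W" || runs$n_epochs[1] <= 10) {
    return(list(rr = rr, hyp = hyp))
  }
  drop <- runs$n_epochs[1] - 10L
  cut_s <- drop * EPOCH_LEN
  hyp2 <- restore_hyp(hyp[-seq_len(drop), , drop = FALSE], hyp)
  rr2 <- rr[rr$beat_time >= cut_s, , drop = FALSE]
  rr2$beat_time <- rr2$beat_time - cut_s
  list(rr = restore_rr(rr2, rr), hyp = hyp2)
}

#' Build per-epoch analysis windows
#'
#' Each scored 30-s epoch is analysed on the 4 min 30 s of signal centered on
#' it (the epoch itself plus four epochs on either side). In training mode a
#' window is unusable when it is truncated at a record edge or spans more than
#' two distinct annotated stages; in inference mode every epoch gets a window.
#'
#' @param rr A cleaned `rr_series`.
#' @param hyp Optional aligned `hypnogram` (required for training mode).
#' @param training Apply the training-mode usability rules?
#' @return A tibble with one row per epoch: `epoch`, `start`, `end` (window
#'   bounds, s), `stage` (center label or `NA`), `n_stages` in the window and
#'   `usable`.
#' @export
build_windows <- function(rr, hyp = NULL, training = FALSE) {
  n_epochs <- if (!is.null(hyp)) nrow(hyp) else floor(rr_duration(rr) / EPOCH_LEN)
  if (n_epochs < 1) {
    warn("record shorter than one epoch: no windows built.")
    return(tibble(
      epoch = integer(), start = numeric(), end = numeric(),
      stage = character(), n_stages = integer(), usable = logical()
    ))
  }
  if (training && is.null(hyp)) abort("training mode needs a hypnogram.")
  epoch <- seq_len(n_epochs) - 1L
  start <- (epoch - 4L) * EPOCH_LEN
  end <- (epoch + 5L) * EPOCH_LEN
  truncated <- epoch - 4L < 0L | epoch + 5L > n_epochs
  if (!is.null(hyp)) {
    stage <- hyp$stage
    n_stages <- vapply(epoch, function(i) {
      span <- max(0L, i - 4L):min(n_epochs - 1L, i + 4L)
      length(unique(hyp$stage[span + 1L]))
    }, integer(1))
  } else {
    stage <- rep(NA_character_, n_epochs)
    n_stages <- rep(NA_integer_, n_epochs)
  }
  usable <- if (training) !truncated & n_stages <= 2L else rep(TRUE, n_epochs)
  tibble(
    epoch = epoch, start = start, end = end,
    stage = stage, n_stages = n_stages, usable = usable
  )
}

#' Screen a recording for the staging/quality pipelines
#'
#' Applies the exclusion rules used before model building: record shorter than
#' 5 h; apnea-hypopnea index (AHI) of 5 or more; objective sleep efficiency
#' below 75%; more than 45 min of wake at the start; more than 30 min of wake
#' at the end; more than 25% of the signal lost to noise. Rules whose inputs
#' are absent (no hypnogram, no AHI, no noise estimate) are skipped and listed
#' in `skipped`.
#'
#' @param rr An `rr_series`.
#' @param hyp Optional aligned `hypnogram`.
#' @param meta Optional list with `AHI` (events/h) and `noise_fraction`
#'   (fraction of record unusable).
#' @return A list of class `screening_report`: `record_id`, `kept`, `reasons`
#'   (character vector of violated rules), `skipped`.
#' @export
screen_recording <- function(rr, hyp = NULL, meta = list()) {
  reasons <- character(0)
  skipped <- character(0)
  dur_h <- rr_duration(rr) / 3600
  if (dur_h < 5) reasons <- c(reasons, "too_short")
  if (nrow(rr) < 2 || any(diff(rr$beat_time) <= 0)) reasons <- c(reasons, "data_error")
  if (!is.null(meta$AHI)) {
    if (meta$AHI >= 5) reasons <- c(reasons, "AHI>=5")
  } else {
    skipped <- c(skipped, "AHI")
  }
  if (!is.null(meta$noise_fraction)) {
    if (meta$noise_fraction > 0.25) reasons <- c(reasons, "noise>25%")
  } else {
    skipped <- c(skipped, "noise")
  }
  if (!is.null(hyp)) {
    eff <- sleep_efficiency_screen(hyp)
    if (!is.na(eff) && eff < 0.75) reasons <- c(reasons, "efficiency<75%")
    runs <- hyp_runs(hyp)
    lead_w <- if (runs$stage[1] == "W") runs$n_epochs[1] else 0L
    trail_w <- if (runs$stage[nrow(runs)] == "W") runs$n_epochs[nrow(runs)] else 0L
    if (lead_w * EPOCH_LEN / 60 > 45) reasons <- c(reasons, "leading_wake>45min")
    if (trail_w * EPOCH_LEN / 60 > 30) reasons <- c(reasons, "trailing_wake>30min")
  } else {
    skipped <- c(skipped, "efficiency", "leading_wake", "trailing_wake")
  }
  structure(
    list(
      record_id = record_id(rr), kept = length(reasons) == 0,
      reasons = reasons, skipped = skipped
    ),
    class = "screening_report"
  )
}

# screening-time objective sleep efficiency: fraction of non-W epochs between
# the first and last non-W epoch
sleep_efficiency_screen <- function(hyp) {
  asleep <- which(hyp$stage != "W")
  if (length(asleep) == 0) {
    return(NA_real_)
  }
  span <- asleep[1]:asleep[length(asleep)]
  mean(hyp$stage[span] != "W")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report '%s'> kept=%s%s%s\n", x$record_id, x$kept,
    if (length(x$reasons)) paste0(" reasons: ", paste(x$reasons, collapse = ", ")) else "",
    if (length(x$skipped)) paste0(" (skipped: ", paste(x$skipped, collapse = ", "), ")") else ""
  ))
  invisible(x)
}
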