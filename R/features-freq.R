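# Evenly resampled RR tachogram of an rr_series (valid beats only).
resample_tachogram <- function(rr, fs = 4, min_span = 60, min_beats = 10) {
  v <- rr[rr$valid, , drop = FALSE]
  make_tachogram(v$beat_time, v$interval, fs = fs, min_span = min_span, min_beats = min_beats)
}

#' Welch power spectral density
#'
#' Mean of Hann-windowed, mean-removed periodograms over 50%-overlapping
#' segments. Used for all tachogram spectra in the package.
#'
#' @param x Numeric series, evenly sampled.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length in samples (shrunk to `length(x)` when the
#'   series is shorter).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A tibble with `freq` (Hz) and `psd` (power per Hz, units of
#'   `x` squared).
#' @export
welch_psd <- function(x, fs, seg_len = 512, overlap = 0.5) {
  as_tibble(welch_core(x, fs, seg_len, overlap))
}

#' Frequency-domain HRV features of a window
#'
#' The tachogram is spline-resampled at 4 Hz and its Welch spectrum (128-s
#' segments, 50% overlap) integrated over the standard bands: VLF
#' 0.0033-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz. `LFn = LF/(LF+HF)` and
#' `HFn = HF/(LF+HF)`, so `LFn + HFn = 1`.
#'
#' @inheritParams hrv_time_domain
#' @param fs Tachogram resampling rate, Hz.
#' @return A one-row tibble: `VLF`, `LF`, `HF` (ms^2), `LF_HF`, `LFn`, `HFn`.
#' @export
hrv_frequency_domain <- function(rr, fs = 4) {
  tg <- resample_tachogram(rr, fs = fs)
  sp <- if (is.null(tg)) NULL else welch_core(tg$y, tg$fs, seg_len = 128 * tg$fs)
  as_feature_row(ft_bands(sp))
}

#' Respiration-band features of a window
#'
#' `resf` is the dominant tachogram frequency in the respiratory band
#' 0.15-0.5 Hz (respiratory sinus arrhythmia makes the tachogram oscillate at
#' the breathing rate). `strf` is the standard deviation of `resf` re-estimated
#' over five 90-s sub-windows sliding across the unit. `coRR` is the Pearson
#' correlation between the raw interval sequence and its second-order smoothed
#' version (two passes of a centered 3-point moving average).
#'
#' @inheritParams hrv_frequency_domain
#' @return A one-row tibble with `coRR` in `[-1, 1]`, `resf` (Hz), `strf` (Hz).
#' @export
hrv_respiration <- function(rr, fs = 4) {
  tg <- resample_tachogram(rr, fs = fs)
  as_feature_row(ft_resp(tg, valid_intervals(rr)))
}

# centered 3-point moving average, endpoints kept
ma3 <- function(x) {
  n <- length(x)
  if (n < 3) {
    return(x)
  }
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

#' Detrended fluctuation analysis of a series
#'
#' Order-1 DFA: the mean-centered series is integrated, split into
#' non-overlapping windows of each scale, linearly detrended per window, and
#' the root-mean-square fluctuation `F(n)` regressed as `log10 F` on `log10 n`
#' over scales 4-64 beats. `alpha1` is the slope and `alpha2` the intercept
#' (offset) of that fit. `dual_exponent = TRUE` instead returns the
#' conventional two-regime slopes (scales 4-11 and 11-64).
#'
#' @param x Numeric series (at least 100 points).
#' @param scales Integer window sizes.
#' @param dual_exponent Report two slopes instead of slope + offset?
#' @return A one-row tibble with `alpha1`, `alpha2`.
#' @export
dfa <- function(x, scales = dfa_scales(), dual_exponent = FALSE) {
  x <- x[!is.na(x)]
  if (!dual_exponent) {
    return(as_feature_row(ft_dfa(x, scales)))
  }
  if (length(x) < 100 || sd(x) == 0) {
    return(as_feature_row(c(alpha1 = NA_real_, alpha2 = NA_real_)))
  }
  lo <- ft_dfa(x, scales[scales <= 11], min_beats = 100)
  hi <- ft_dfa(x, scales[scales >= 11], min_beats = 100)
  as_feature_row(c(alpha1 = lo[["alpha1"]], alpha2 = hi[["alpha1"]]))
}

#' Default DFA scales (4 to 64 beats, log-spaced)
#' @return An integer vector.
#' @export
dfa_scales <- function() {
  unique(round(exp(seq(log(4), log(64), length.out = 12))))
}

#' DFA features of a window
#'
#' @inheritParams hrv_time_domain
#' @param dual_exponent See [dfa()].
#' @return A one-row tibble with `alpha1` (slope) and `alpha2` (offset, or the
#'   large-scale slope when `dual_exponent`).
#' @export
hrv_dfa <- function(rr, min_beats = 100, dual_exponent = FALSE) {
  x <- valid_intervals(rr)
  if (length(x) < min_beats) {
    return(as_feature_row(c(alpha1 = NA_real_, alpha2 = NA_real_)))
  }
  dfa(x, dual_exponent = dual_exponent)
}
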