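# Successive differences between beats that are valid and adjacent in the
# original series; differences spanning a removed beat are dropped.
valid_successive_diffs <- function(rr) {
  v <- rr$valid
  d <- diff(rr$interval)
  d[v[-length(v)] & v[-1]]
}

valid_intervals <- function(rr) rr$interval[rr$valid]

as_feature_row <- function(x) as_tibble(as.list(x))

#' Time-domain HRV features of a window
#'
#' Mean heart rate plus the standard short-term variability statistics,
#' computed over the valid beats of the window. Successive-difference
#' statistics (RMSSD, SDSD, PNN50) use only differences between beats that
#' were adjacent in the raw series.
#'
#' @param rr An `rr_series` (typically one analysis window).
#' @param min_beats Minimum number of valid beats (default 10); fewer yields
#'   a row of missing values.
#' @return A one-row tibble: `HR` (bpm), `SDNN`, `RMSSD`, `SDSD` (ms),
#'   `PNN50` (% of successive differences exceeding 50 ms).
#' @export
hrv_time_domain <- function(rr, min_beats = 10) {
  as_feature_row(ft_time(valid_intervals(rr), valid_successive_diffs(rr), min_beats))
}

#' Poincare-plot descriptors
#'
#' Semi-minor (`SD1`) and semi-major (`SD2`) axes of the ellipse fitted to the
#' lag-1 Poincare plot of the RR intervals; `SD1^2 = var(diff)/2`,
#' `SD2^2 = 2 var(RR) - SD1^2`, so `SD1 = RMSSD/sqrt(2)` up to the sample
#' variance correction.
#'
#' @inheritParams hrv_time_domain
#' @return A one-row tibble with `SD1`, `SD2` in ms.
#' @export
hrv_poincare <- function(rr, min_beats = 10) {
  as_feature_row(ft_poincare(valid_intervals(rr), valid_successive_diffs(rr), min_beats))
}

#' Time-irreversibility statistics P1 and G1
#'
#' Based on the signs and energies of the successive RR differences:
#' `P1 = 100 * N(dRR-) / (N(dRR-) + N(dRR+))` is the percentage of negative
#' increments, and `G1 = 100 * sum(dRR+^2) / (sum(dRR+^2) + sum(dRR-^2))` the
#' share of increment energy carried by positive increments. Zero differences
#' count toward neither term. Under time reversal P1 maps to `100 - P1`.
#'
#' @inheritParams hrv_time_domain
#' @return A one-row tibble with `P1`, `G1`, both in `[0, 100]` (missing when
#'   every difference is zero).
#' @export
hrv_irreversibility <- function(rr, min_beats = 3) {
  as_feature_row(ft_irrev(valid_intervals(rr), valid_successive_diffs(rr), min_beats))
}

#' Lag-2 self-correlation
#'
#' For a sequence of length `n`, the Pearson correlation between its first and
#' last `n - 2` points.
#'
#' @inheritParams hrv_time_domain
#' @return A one-row tibble with `corr2` in `[-1, 1]` (missing for constant or
#'   too-short input).
#' @export
hrv_corr2 <- function(rr, min_beats = 4) {
  as_feature_row(ft_corr2(valid_intervals(rr), min_beats))
}

#' Sample entropy of a numeric series
#'
#' Richman-Moorman sample entropy with template length `m` and tolerance `r`
#' (Chebyshev distance, self-matches excluded). Returns 0 by convention for a
#' constant series and `NA` when no template pair matches.
#'
#' @param x Numeric vector.
#' @param m Template length (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(x)`.
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  ft_sampen(x, m, r)
}

#' Fuzzy entropy of a numeric series
#'
#' Like sample entropy but with baseline-removed templates and a Gaussian
#' membership `exp(-(d/r)^p)` in place of the hard tolerance.
#'
#' @inheritParams sample_entropy
#' @param p Membership exponent (default 2).
#' @return Fuzzy entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * sd(x), p = 2) {
  ft_fuzzen(x, m, r, p)
}

#' Entropy features of a window
#'
#' Sample entropy (`SE`) and fuzzy entropy (`FE`), both with `m = 2` and
#' tolerance `0.2` times the window SD.
#'
#' @inheritParams hrv_time_domain
#' @return A one-row tibble with `SE`, `FE` in nats.
#' @export
hrv_entropy <- function(rr, min_beats = 100) {
  x <- valid_intervals(rr)
  if (length(x) < min_beats) {
    return(as_feature_row(c(SE = NA_real_, FE = NA_real_)))
  }
  r <- 0.2 * sd(x)
  as_feature_row(c(SE = ft_sampen(x, 2, r), FE = ft_fuzzen(x, 2, r, 2)))
}
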