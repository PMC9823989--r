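# local extrema (indices) of a short window, endpoints allowed; plateaus
# contribute their first point
local_extrema <- function(w) {
  n <- length(w)
  if (n == 0) {
    return(list(max = integer(0), min = integer(0)))
  }
  if (n == 1) {
    return(list(max = 1L, min = 1L))
  }
  left <- c(-Inf, w[-n])
  right <- c(w[-1], -Inf)
  is_max <- w >= left & w >= right
  left <- c(Inf, w[-n])
  right <- c(w[-1], Inf)
  is_min <- w <= left & w <= right
  drop_runs <- function(idx) idx[c(TRUE, diff(idx) > 1)]
  list(max = drop_runs(which(is_max)), min = drop_runs(which(is_min)))
}

# slopes (per second) between first/second maxima (t1, t2) and minima
# (b1, b2) of one 3-min window; returns numeric(4): t1_b1, t1_b2, t2_b1, t2_b2
trend_slopes_core <- function(values, times) {
  out <- rep(NA_real_, 4)
  keep <- !is.na(values)
  values <- values[keep]
  times <- times[keep]
  if (length(values) < 2) {
    return(out)
  }
  ex <- local_extrema(values)
  slot <- function(t_i, b_i) {
    if (t_i > length(ex$max) || b_i > length(ex$min)) {
      return(NA_real_)
    }
    ti <- ex$max[t_i]
    bi <- ex$min[b_i]
    if (times[ti] == times[bi]) {
      return(NA_real_)
    }
    (values[ti] - values[bi]) / (times[ti] - times[bi])
  }
  out[1] <- slot(1, 1)
  out[2] <- slot(1, 2)
  out[3] <- slot(2, 1)
  out[4] <- slot(2, 2)
  out
}

# numeric(20) contextual row for 1-based epoch i given smoothed night series
ctx_row <- function(hr_raw, re_raw, hr_s, re_s, times, i, n) {
  win <- function(from, to) {
    idx <- from:to
    idx[idx >= 1L & idx <= n]
  }
  before <- if (i > 1) win(i - 6L, i - 1L) else integer(0)
  after <- if (i < n) win(i + 1L, i + 6L) else integer(0)
  hour <- win(i - 60L, i + 60L)
  ratio <- function(x, idx) {
    m <- mean(x[idx], na.rm = TRUE)
    if (is.na(x[i]) || is.na(m) || m == 0) NA_real_ else x[i] / m
  }
  c(
    trend_slopes_core(hr_s[before], times[before]),
    trend_slopes_core(re_s[before], times[before]),
    trend_slopes_core(hr_s[after], times[after]),
    trend_slopes_core(re_s[after], times[after]),
    ratio(hr_raw, hour),
    ratio(re_raw, hour),
    ratio(hr_raw, seq_len(n)),
    ratio(re_raw, seq_len(n))
  )
}

ctx_names <- function() {
  c(
    as.vector(t(outer(
      c("aHRs", "aress", "zHRs", "zress"),
      c("t1_b1", "t1_b2", "t2_b1", "t2_b2"), paste,
      sep = "_"
    ))),
    "HRm_m1", "resm_m1", "HRm_ma", "resm_ma"
  )
}

#' Contextual trend features of one epoch
#'
#' Relates the epoch's instantaneous heart rate and respiratory rate to their
#' neighbourhood: in the 3-min windows before (`a` prefix) and after
#' (`z` prefix) the epoch, the slopes between the first and second maxima
#' (`t1`, `t2`) and minima (`b1`, `b2`) of the 3-point-smoothed series are
#' emitted for both signals (16 slopes, per-second units), plus the ratios of
#' the epoch's HR and respiratory rate to their centered one-hour means
#' (`HRm_m1`, `resm_m1`) and overnight means (`HRm_ma`, `resm_ma`).
#'
#' @param instant_hr Per-epoch mean HR series for the night (bpm).
#' @param instant_resp Per-epoch respiratory-rate series (`resf`, Hz).
#' @param epoch_index 0-based epoch to describe.
#' @return A one-row tibble with 20 columns; slopes whose extremum is absent
#'   carry `NA`.
#' @export
context_features <- function(instant_hr, instant_resp, epoch_index) {
  n <- length(instant_hr)
  stopifnot(length(instant_resp) == n, epoch_index >= 0, epoch_index < n)
  row <- ctx_row(
    instant_hr, instant_resp, ma3(instant_hr), ma3(instant_resp),
    (seq_len(n) - 1L) * EPOCH_LEN, epoch_index + 1L, n
  )
  as_feature_row(setNames(row, ctx_names()))
}

#' Names of the per-window HRV features and contextual features
#'
#' `hrv_feature_names("retained")` gives the 13 features kept after the
#' useless-feature elimination; `"all"` gives the full 23-candidate set;
#' `"context"` the 20 contextual features.
#'
#' @param which One of `"all"`, `"retained"`, `"context"`.
#' @return A character vector of column names.
#' @export
hrv_feature_names <- function(which = c("all", "retained", "context")) {
  which <- match.arg(which)
  all23 <- c(
    "HR", "SDNN", "RMSSD", "SDSD", "PNN50", "VLF", "LF", "HF", "LF_HF",
    "LFn", "HFn", "coRR", "resf", "strf", "alpha1", "alpha2", "SE", "FE",
    "SD1", "SD2", "P1", "G1", "corr2"
  )
  retained <- c(
    "HR", "PNN50", "LF", "LF_HF", "coRR", "resf", "strf",
    "alpha1", "alpha2", "SE", "P1", "G1", "corr2"
  )
  switch(which, all = all23, retained = retained, context = ctx_names())
}

#' Extract the full per-epoch feature table of a night
#'
#' Runs every per-window feature over the analysis windows of a night and
#' appends the contextual features, yielding one row per epoch keyed by
#' `(record_id, epoch)`. Edge epochs and windows with too few valid beats get
#' missing values, never errors.
#'
#' @param rr A cleaned `rr_series`.
#' @param windows Window table from [build_windows()]; built on the fly when
#'   omitted.
#' @param features Character vector of window-feature columns to compute
#'   (default all 23); contextual features are always appended.
#' @param hyp Optional hypnogram; when supplied its labels are carried in a
#'   `stage` column.
#' @return A tibble with key columns `record_id`, `epoch`, `stage`, `usable`
#'   followed by the feature columns.
#' @export
extract_night <- function(rr, windows = NULL, features = hrv_feature_names("all"),
                          hyp = NULL) {
  if (is.null(windows)) windows <- build_windows(rr, hyp)
  features <- match_features(features)
  want <- function(group) any(group %in% features)
  n_win <- nrow(windows)

  bt <- rr$beat_time
  iv_all <- rr$interval
  v_all <- rr$valid
  need_hr <- TRUE # HR always computed for the contextual series
  need_resp <- TRUE # resf likewise

  cols <- unique(c(features, "HR", "resf"))
  mat <- matrix(NA_real_, nrow = n_win, ncol = length(cols), dimnames = list(NULL, cols))

  w_time <- want(c("HR", "SDNN", "RMSSD", "SDSD", "PNN50"))
  w_freq <- want(c("VLF", "LF", "HF", "LF_HF", "LFn", "HFn"))
  w_resp <- want(c("coRR", "resf", "strf"))
  w_dfa <- want(c("alpha1", "alpha2"))
  w_se <- "SE" %in% features
  w_fe <- "FE" %in% features
  w_poin <- want(c("SD1", "SD2"))
  w_irr <- want(c("P1", "G1"))
  w_c2 <- "corr2" %in% features

  fill <- function(j, x) {
    x <- x[names(x) %in% colnames(mat)]
    if (length(x) > 0) mat[j, names(x)] <<- x
  }
  if (n_win == 0) {
    return(bind_cols(
      tibble(
        record_id = character(), epoch = integer(),
        stage = character(), usable = logical()
      ),
      as_tibble(mat[, features, drop = FALSE]),
      as_tibble(matrix(numeric(0), 0, 20, dimnames = list(NULL, ctx_names())))
    ))
  }
  for (j in seq_len(n_win)) {
    lo <- findInterval(windows$start[j] - 1e-9, bt) + 1L
    hi <- findInterval(windows$end[j] - 1e-9, bt)
    if (hi < lo) next
    idx <- lo:hi
    v <- v_all[idx]
    ivw <- iv_all[idx]
    viv <- ivw[v]
    d <- diff(ivw)
    d <- d[v[-length(v)] & v[-1]]

    tvals <- ft_time(viv, d)
    if (w_time || need_hr) mat[j, "HR"] <- tvals[["HR"]]
    if (w_time) fill(j, tvals[setdiff(names(tvals), "HR")])
    if (w_poin) fill(j, ft_poincare(viv, d))
    if (w_irr) fill(j, ft_irrev(viv, d))
    if (w_c2) fill(j, ft_corr2(viv))
    if (w_dfa) fill(j, ft_dfa(viv))
    if (w_se || w_fe) {
      r <- 0.2 * sd(viv)
      if (length(viv) >= 100) {
        if (w_se) mat[j, "SE"] <- ft_sampen(viv, 2, r)
        if (w_fe) mat[j, "FE"] <- ft_fuzzen(viv, 2, r, 2)
      }
    }
    if (w_freq || w_resp || need_resp) {
      tg <- make_tachogram(bt[idx][v], viv)
      sp <- if (is.null(tg)) NULL else welch_core(tg$y, tg$fs, seg_len = min(length(tg$y), 128 * tg$fs))
      if (w_freq) fill(j, ft_bands(sp))
      rvals <- ft_resp(tg, viv, sp = sp)
      mat[j, "resf"] <- rvals[["resf"]]
      if (w_resp) fill(j, rvals[setdiff(names(rvals), "resf")])
    }
  }

  hr_raw <- mat[, "HR"]
  re_raw <- mat[, "resf"]
  hr_s <- ma3(hr_raw)
  re_s <- ma3(re_raw)
  times <- windows$epoch * EPOCH_LEN
  ctx <- t(vapply(
    seq_len(n_win),
    function(j) ctx_row(hr_raw, re_raw, hr_s, re_s, times, j, n_win),
    numeric(20)
  ))
  colnames(ctx) <- ctx_names()

  bind_cols(
    tibble(
      record_id = record_id(rr),
      epoch = windows$epoch,
      stage = windows$stage,
      usable = windows$usable
    ),
    as_tibble(mat[, features, drop = FALSE]),
    as_tibble(ctx)
  )
}

match_features <- function(features) {
  known <- hrv_feature_names("all")
  bad <- setdiff(features, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")))
  }
  features
}
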