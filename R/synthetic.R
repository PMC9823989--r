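#' Configuration for a synthetic night
#'
#' Defines the semi-Markov stage structure and the stage-conditional RR
#' generator of a simulated night. Defaults encode the qualitative
#' stage contrasts the staging method exploits: wake and REM run a faster,
#' more variable heart rate with a higher and less stable respiratory
#' frequency; light and especially deep sleep are slower, highly regular and
#' dominated by respiratory (high-frequency) modulation. Bout means give the
#' conventional ~90-min non-REM/REM cycling.
#'
#' @param night_hours Record length in hours (default 8).
#' @param onset_wake_min Mean length of the opening wake bout, minutes.
#' @param bout_min Named mean bout lengths in minutes for `W`, `R`, `L`, `D`.
#' @param transition Named list of transition weights out of each stage
#'   (rows need not sum to 1; they are normalized).
#' @param mean_rr,jitter_sd,lf_amp,hf_amp Named per-stage RR parameters (ms):
#'   baseline interval, Gaussian beat-to-beat jitter, amplitude of the 0.1-Hz
#'   (sympathetic/baroreflex) modulation, amplitude of the respiratory
#'   modulation.
#' @param resp_f Named per-stage respiratory frequency, Hz (0.15-0.5).
#' @param artifact_rate Fraction of beats replaced by out-of-range artifacts
#'   (default 0.01).
#' @param seed Default seed used by the generators.
#' @return A list of class `night_config`.
#' @export
night_config <- function(night_hours = 8,
                         onset_wake_min = 10,
                         bout_min = c(W = 2, R = 15, L = 25, D = 12),
                         transition = list(
                           W = c(R = 0.05, L = 0.9, D = 0.05),
                           R = c(W = 0.3, L = 0.7, D = 0),
                           L = c(W = 0.2, R = 0.35, D = 0.45),
                           D = c(W = 0.2, R = 0, L = 0.8)
                         ),
                         mean_rr = c(W = 800, R = 850, L = 950, D = 1020),
                         jitter_sd = c(W = 45, R = 35, L = 18, D = 7),
                         lf_amp = c(W = 25, R = 30, L = 12, D = 5),
                         hf_amp = c(W = 8, R = 10, L = 25, D = 32),
                         resp_f = c(W = 0.35, R = 0.30, L = 0.26, D = 0.22),
                         artifact_rate = 0.01,
                         seed = 1) {
  stopifnot(
    all(STAGES %in% names(bout_min)),
    all(mean_rr >= 400 & mean_rr <= 1500),
    all(resp_f >= 0.15 & resp_f <= 0.5),
    all(lf_amp >= 0), all(hf_amp >= 0), all(jitter_sd >= 0),
    artifact_rate >= 0, artifact_rate < 1
  )
  structure(
    list(
      night_hours = night_hours, onset_wake_min = onset_wake_min,
      bout_min = bout_min, transition = transition,
      mean_rr = mean_rr, jitter_sd = jitter_sd,
      lf_amp = lf_amp, hf_amp = hf_amp, resp_f = resp_f,
      artifact_rate = artifact_rate, seed = seed
    ),
    class = "night_config"
  )
}

#' Simulate a night's hypnogram
#'
#' Semi-Markov simulation: the night opens with a wake bout, then stages
#' alternate with geometric bout lengths (mean `bout_min`) and the
#' `transition` weights, which by default produce the cyclic light/deep/REM
#' structure of healthy sleep with brief awakenings.
#'
#' @param cfg A [night_config()].
#' @param seed Seed (defaults to `cfg$seed`); identical seeds give identical
#'   nights.
#' @param record_id Identifier.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(cfg = night_config(), seed = cfg$seed,
                               record_id = "synthetic") {
  set.seed(seed)
  n <- round(cfg$night_hours * 3600 / EPOCH_LEN)
  geom_bout <- function(mean_min) {
    mean_ep <- max(1, mean_min * 60 / EPOCH_LEN)
    1L + stats::rgeom(1, 1 / mean_ep)
  }
  stage <- character(0)
  cur <- "W"
  stage <- rep(cur, min(geom_bout(cfg$onset_wake_min), n))
  while (length(stage) < n) {
    w <- cfg$transition[[cur]]
    w <- w[w > 0]
    cur <- sample(names(w), 1, prob = w)
    stage <- c(stage, rep(cur, geom_bout(cfg$bout_min[[cur]])))
  }
  hypnogram(stage[seq_len(n)], source = "annotation", record_id = record_id)
}

#' Simulate a stage-conditional RR series for a night
#'
#' Beats are generated sequentially; each interval is the current stage's
#' baseline plus a 0.1-Hz low-frequency sinusoid, a respiratory sinusoid at
#' the stage's breathing frequency (respiratory sinus arrhythmia), and
#' Gaussian jitter. A configured fraction of beats is replaced by
#' out-of-range artifacts (shorter than 350 ms or longer than 2 s) for
#' [clean_rr()] to catch.
#'
#' @param hyp The night's [hypnogram()].
#' @param cfg A [night_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return An [rr_series()] with artifacts flagged `valid = FALSE`.
#' @export
simulate_rr <- function(hyp, cfg = night_config(), seed = cfg$seed) {
  set.seed(seed + 1L)
  dur <- nrow(hyp) * EPOCH_LEN
  n_max <- ceiling(dur / 0.3) + 10L
  noise <- rnorm(n_max)
  art_draw <- runif(n_max)
  art_kind <- runif(n_max)
  art_val <- runif(n_max)
  phi_lf <- runif(1, 0, 2 * pi)
  phi_hf <- runif(1, 0, 2 * pi)

  bt <- numeric(n_max)
  iv <- numeric(n_max)
  ok <- logical(n_max)
  t <- 0
  i <- 0L
  stages <- hyp$stage
  while (t < dur && i < n_max) {
    i <- i + 1L
    s <- stages[min(floor(t / EPOCH_LEN) + 1L, length(stages))]
    x <- cfg$mean_rr[[s]] +
      cfg$lf_amp[[s]] * sin(2 * pi * 0.1 * t + phi_lf) +
      cfg$hf_amp[[s]] * sin(2 * pi * cfg$resp_f[[s]] * t + phi_hf) +
      cfg$jitter_sd[[s]] * noise[i]
    x <- min(max(x, 400), 1900)
    if (art_draw[i] < cfg$artifact_rate) {
      x <- if (art_kind[i] < 0.5) 200 + 130 * art_val[i] else 2050 + 450 * art_val[i]
      ok[i] <- FALSE
    } else {
      ok[i] <- TRUE
    }
    t <- t + x / 1000
    bt[i] <- t
    iv[i] <- x
  }
  out <- rr_series(bt[seq_len(i)], iv[seq_len(i)], record_id = record_id(hyp))
  out$valid <- ok[seq_len(i)]
  out
}

#' Simulate a single-lead ECG from an RR series
#'
#' Places a stereotyped QRS-T template (narrow R spike with Q/S side lobes
#' and a low T wave) at every beat time on a flat baseline, optionally adding
#' white noise. Intended for exercising R-peak detection, not as
#' physiological morphology.
#'
#' @param rr An `rr_series`.
#' @param rate Sampling rate, Hz (default 250).
#' @param noise_sd Additive Gaussian noise SD relative to an R amplitude of 1.
#' @param seed Seed for the noise.
#' @return An `ecg_record` (list of `signal`, `rate`).
#' @export
simulate_ecg <- function(rr, rate = 250, noise_sd = 0, seed = 1) {
  dur <- max(rr$beat_time) + 1
  n <- ceiling(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  sig <- numeric(n)
  bump <- function(center, amp, width) {
    lo <- max(1L, floor((center - 4 * width) * rate))
    hi <- min(n, ceiling((center + 4 * width) * rate))
    idx <- lo:hi
    sig[idx] <<- sig[idx] + amp * exp(-((tt[idx] - center)^2) / (2 * width^2))
  }
  for (b in rr$beat_time) {
    bump(b - 0.04, -0.15, 0.010)
    bump(b, 1, 0.012)
    bump(b + 0.04, -0.20, 0.010)
    bump(b + 0.25, 0.25, 0.060)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + rnorm(n, 0, noise_sd)
  }
  structure(list(signal = sig, rate = rate), class = "ecg_record")
}

#' Configuration for a synthetic cohort
#'
#' Planted sleep-quality labels are linked to night structure: poor sleepers
#' get more and longer awakenings (higher wake transition weight, longer wake
#' bouts, longer sleep onset) and fragmented REM (shorter REM bouts, which
#' raises the transition intensity), hence lower sleep efficiency.
#'
#' @param n_subjects Number of subjects (at least 4; default 40).
#' @param frac_poor Fraction of poor sleepers in `(0, 1)` (default 0.35).
#' @param night Base [night_config()] for good sleepers.
#' @param poor_link Multipliers applied to a poor sleeper's night:
#'   `wake_weight` (transition weight into W), `wake_bout` (wake bout mean),
#'   `onset` (opening wake bout), `rem_bout` (REM bout mean, < 1 fragments
#'   REM) and `rem_weight` (transition weight into R; together with
#'   `rem_bout` this raises the number of REM entries and hence the
#'   transition intensity).
#' @param seed Cohort seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40, frac_poor = 0.35,
                          night = night_config(),
                          poor_link = c(
                            wake_weight = 4, wake_bout = 2,
                            onset = 3, rem_bout = 0.4, rem_weight = 3
                          ),
                          seed = 1) {
  stopifnot(n_subjects >= 4, frac_poor > 0, frac_poor < 1)
  structure(
    list(
      n_subjects = n_subjects, frac_poor = frac_poor, night = night,
      poor_link = poor_link, seed = seed
    ),
    class = "cohort_config"
  )
}

poor_night_config <- function(cfg) {
  night <- cfg$night
  link <- cfg$poor_link
  night$onset_wake_min <- night$onset_wake_min * link[["onset"]]
  night$bout_min[["W"]] <- night$bout_min[["W"]] * link[["wake_bout"]]
  night$bout_min[["R"]] <- night$bout_min[["R"]] * link[["rem_bout"]]
  for (s in c("R", "L", "D")) {
    w <- night$transition[[s]]
    if ("W" %in% names(w)) w[["W"]] <- w[["W"]] * link[["wake_weight"]]
    night$transition[[s]] <- w
  }
  for (s in c("W", "L", "D")) {
    w <- night$transition[[s]]
    if ("R" %in% names(w)) w[["R"]] <- w[["R"]] * link[["rem_weight"]]
    night$transition[[s]] <- w
  }
  night
}

#' Simulate a cohort with planted sleep-quality labels
#'
#' Per subject: a quality label is drawn (`frac_poor`), a questionnaire score
#' consistent with it is sampled (good: 0-6, poor: 7-14), the night structure
#' is biased through `poor_link` for poor sleepers, and a hypnogram plus RR
#' series are generated. The planted labels are the ground truth for
#' end-to-end recovery experiments.
#'
#' @param cfg A [cohort_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return A tibble with `record_id`, `score`, `quality` and list-columns
#'   `hypnogram`, `rr`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n_subjects
  poor <- runif(n) < cfg$frac_poor
  scores <- ifelse(poor, sample(7:14, n, replace = TRUE), sample(0:6, n, replace = TRUE))
  subj_seed <- sample.int(.Machine$integer.max - 10L, n)
  rows <- purrr::map(seq_len(n), function(i) {
    rid <- sprintf("subj%03d", i)
    ncfg <- if (poor[i]) poor_night_config(cfg) else cfg$night
    hyp <- simulate_hypnogram(ncfg, seed = subj_seed[i], record_id = rid)
    rr <- simulate_rr(hyp, ncfg, seed = subj_seed[i])
    tibble(
      record_id = rid, score = scores[i],
      quality = quality_label(scores[i]),
      hypnogram = list(hyp), rr = list(rr)
    )
  })
  bind_rows(rows)
}
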