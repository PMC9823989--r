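test_that("time-domain features match their definitions", {
  const <- rr_from_intervals(rep(1000, 60))
  td <- hrv_time_domain(const)
  expect_equal(td$HR, 60)
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$PNN50, 0)

  two <- hrv_time_domain(rr_from_intervals(c(rep(1000, 9), 1060)), min_beats = 5)
  expect_equal(two$PNN50, 100 / 9) # one of nine diffs exceeds 50 ms

  rr <- random_rr(300, seed = 11)
  td2 <- hrv_time_domain(rr)
  expect_equal(td2$SDSD, oracle_sdsd(rr$interval), tolerance = 1e-12)

  expect_true(all(is.na(hrv_time_domain(rr_from_intervals(rep(900, 4))))))
})

test_that("Poincare axes match the rotate-by-45-degree oracle and SD1 = RMSSD/sqrt(2)", {
  rr <- random_rr(200, seed = 3)
  pc <- hrv_poincare(rr)
  o <- oracle_sd1_sd2(rr$interval)
  expect_equal(pc$SD1, unname(o["SD1"]), tolerance = 1e-12)
  expect_equal(pc$SD2, unname(o["SD2"]), tolerance = 1e-12)

  # exact identity with RMSSD
  expect_equal(pc$SD1, hrv_time_domain(rr)$RMSSD / sqrt(2), tolerance = 1e-12)

  z <- hrv_poincare(rr_from_intervals(rep(800, 50)))
  expect_equal(z$SD1, 0)
  expect_equal(z$SD2, 0)
})

test_that("irreversibility statistics follow their defining formulas", {
  inc <- rr_from_intervals(seq(800, 900, by = 10))
  expect_equal(hrv_irreversibility(inc)$P1, 0)

  # increments +10, +10, -10: G1 = 100 * 200 / 300
  g <- rr_from_intervals(c(800, 810, 820, 810))
  expect_equal(hrv_irreversibility(g)$G1, 100 * 200 / 300, tolerance = 1e-12)

  rr <- random_rr(300, seed = 5)
  ir <- hrv_irreversibility(rr)
  expect_equal(ir$P1, oracle_p1(rr$interval), tolerance = 1e-12)
  expect_equal(ir$G1, oracle_g1(rr$interval), tolerance = 1e-12)

  # time reversal maps P1 to 100 - P1
  rev_rr <- rr_from_intervals(rev(rr$interval))
  expect_equal(hrv_irreversibility(rev_rr)$P1, 100 - ir$P1, tolerance = 1e-9)

  # adding a constant leaves both untouched
  shifted <- rr_from_intervals(rr$interval + 150)
  expect_equal(hrv_irreversibility(shifted)$P1, ir$P1, tolerance = 1e-12)
  expect_equal(hrv_irreversibility(shifted)$G1, ir$G1, tolerance = 1e-12)

  expect_true(all(is.na(hrv_irreversibility(rr_from_intervals(rep(700, 10))))))
})

test_that("corr2 is the lag-2 self-correlation", {
  ramp <- rr_from_intervals(seq(700, 1100, length.out = 50))
  expect_equal(hrv_corr2(ramp)$corr2, 1, tolerance = 1e-9)

  sq <- rr_from_intervals(rep(c(800, 800, 900, 900), 25))
  expect_equal(hrv_corr2(sq)$corr2, -1, tolerance = 1e-9)

  rr <- random_rr(1000, seed = 8)
  expect_equal(hrv_corr2(rr)$corr2, oracle_corr2(rr$interval), tolerance = 1e-12)
  expect_lt(abs(hrv_corr2(rr)$corr2), 0.1)

  expect_true(is.na(hrv_corr2(rr_from_intervals(rep(900, 30)))$corr2))
})

test_that("sample entropy equals the exhaustive template count", {
  set.seed(21)
  x <- rnorm(50)
  expect_equal(sample_entropy(x), oracle_sampen(x), tolerance = 1e-12)
  x2 <- rnorm(80, 900, 30)
  expect_equal(sample_entropy(x2), oracle_sampen(x2), tolerance = 1e-12)

  expect_equal(sample_entropy(rep(5, 120)), 0)

  # regular signals carry less entropy than noise
  set.seed(22)
  noise <- rnorm(300)
  sine <- sin(2 * pi * (1:300) / 20)
  expect_gt(sample_entropy(noise), sample_entropy(sine, r = 0.2 * sd(sine)))
  expect_gt(fuzzy_entropy(noise), fuzzy_entropy(sine, r = 0.2 * sd(sine)))
})

test_that("DFA calibrates on white noise and random walks and is scale-equivariant", {
  slopes_wn <- vapply(1:10, function(s) {
    set.seed(s)
    dfa(rnorm(1000))$alpha1
  }, numeric(1))
  expect_lt(abs(mean(slopes_wn) - 0.5), 0.1)

  slopes_rw <- vapply(1:10, function(s) {
    set.seed(s)
    dfa(cumsum(rnorm(1000)))$alpha1
  }, numeric(1))
  expect_lt(abs(mean(slopes_rw) - 1.5), 0.15)

  set.seed(33)
  x <- rnorm(500, 900, 30)
  base <- dfa(x)
  doubled <- dfa(2 * x)
  expect_equal(doubled$alpha1, base$alpha1, tolerance = 1e-9)
  expect_equal(doubled$alpha2, base$alpha2 + log10(2), tolerance = 1e-9)

  dual <- dfa(x, dual_exponent = TRUE)
  expect_true(is.finite(dual$alpha1) && is.finite(dual$alpha2))
})

test_that("spectral bands recover planted modulations", {
  t <- cumsum(rep(0.9, 320))
  hf_rr <- rr_series(t, 900 + 50 * sin(2 * pi * 0.25 * t))
  fd <- hrv_frequency_domain(hf_rr)
  expect_gt(fd$HF / (fd$LF + fd$HF), 0.9)
  expect_lt(fd$LF_HF, 0.12)
  expect_equal(fd$LFn + fd$HFn, 1, tolerance = 1e-12)

  lf_rr <- rr_series(t, 900 + 50 * sin(2 * pi * 0.10 * t))
  fd2 <- hrv_frequency_domain(lf_rr)
  expect_gt(fd2$LF, fd2$HF)
  expect_equal(fd2$LFn + fd2$HFn, 1, tolerance = 1e-12)

  short <- rr_from_intervals(rep(900, 20))
  expect_true(all(is.na(hrv_frequency_domain(short))))
})

test_that("respiration features recover the breathing frequency", {
  t <- cumsum(rep(0.9, 320))
  rr <- rr_series(t, 900 + 40 * sin(2 * pi * 0.30 * t))
  rf <- hrv_respiration(rr)
  expect_lt(abs(rf$resf - 0.30), 0.02)
  expect_lt(rf$strf, 0.01) # identical modulation in every sub-window

  slow <- rr_series(t, 900 + 80 * sin(2 * pi * 0.02 * t))
  expect_gt(hrv_respiration(slow)$coRR, 0.99)

  # coRR equals the direct correlation with the twice-smoothed sequence
  smooth3 <- function(x) {
    n <- length(x)
    out <- x
    out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
    out
  }
  rr2 <- random_rr(300, seed = 13)
  sm <- smooth3(smooth3(rr2$interval))
  expect_equal(hrv_respiration(rr2)$coRR, cor(rr2$interval, sm), tolerance = 1e-12)
})

test_that("contextual features report planted extrema slopes and ratios", {
  n <- 200
  hr <- rep(60, n)
  resp <- rep(0.25, n)
  # planted V-shape in the 3-min window before epoch 100 (1-based 101):
  # epochs 95..100 smoothed values fall then rise
  hr[95:101] <- c(70, 64, 58, 58, 58, 64, 70)
  ctx <- context_features(hr, resp, epoch_index = 100)
  expect_true(is.finite(ctx$aHRs_t1_b1))
  # constant series: overnight ratio is exactly 1
  ctx2 <- context_features(rep(60, n), rep(0.25, n), epoch_index = 100)
  expect_equal(ctx2$HRm_ma, 1)
  expect_equal(ctx2$resm_m1, 1)

  # monotone window: single max and min, second-extremum slots missing
  hr3 <- seq(60, 80, length.out = n)
  ctx3 <- context_features(hr3, resp, epoch_index = 100)
  expect_gt(ctx3$aHRs_t1_b1, 0)
  expect_true(is.na(ctx3$aHRs_t2_b2))

  # planted V-shape with a strictly highest window start: t1 is the window
  # start, b1 the bottom; slope equals delta value / delta time on the
  # 3-point smoothed series
  hr4 <- rep(60, n)
  hr4[93:102] <- c(99, 97, 95, 55, 45, 55, 70, 80, 85, 60)
  ctx4 <- context_features(hr4, resp, epoch_index = 100)
  s <- rep(NA_real_, n)
  for (j in 2:(n - 1)) s[j] <- (hr4[j - 1] + hr4[j] + hr4[j + 1]) / 3
  win <- 95:100 # 1-based window positions before epoch 100 (0-based)
  t1 <- win[which.max(s[win])]
  b1 <- win[which.min(s[win])]
  expect_equal(ctx4$aHRs_t1_b1, (s[t1] - s[b1]) / ((t1 - b1) * 30), tolerance = 1e-9)
})

test_that("extract_night yields one complete row per epoch, deterministically", {
  cfg <- night_config(night_hours = 1)
  hyp <- simulate_hypnogram(cfg, seed = 2)
  rr <- clean_rr(simulate_rr(hyp, cfg, seed = 2))
  w <- build_windows(rr, hyp, training = TRUE)
  tab <- extract_night(rr, w, hyp = hyp)
  expect_equal(nrow(tab), 120)
  expect_equal(ncol(tab), 4 + 23 + 20)
  expect_setequal(
    setdiff(names(tab), c("record_id", "epoch", "stage", "usable")),
    c(hrv_feature_names("all"), hrv_feature_names("context"))
  )
  # truncated edge windows are flagged unusable, not errors
  expect_false(tab$usable[1])
  expect_false(tab$usable[120])
  # determinism
  tab2 <- extract_night(rr, w, hyp = hyp)
  expect_identical(tab, tab2)
  # no silent infinities
  num <- tab[vapply(tab, is.numeric, logical(1))]
  expect_false(any(vapply(num, function(x) any(is.infinite(x)), logical(1))))
})
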