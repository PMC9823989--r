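test_that("transition intensity implements the printed 1/0/1 labelling", {
  expect_equal(transition_intensity(hypnogram(c("W", "R", "W"))), 2)
  expect_equal(transition_intensity(hypnogram(rep("L", 240))), 0)
  # W <-> L/D transitions are invisible under the printed labelling
  expect_equal(transition_intensity(hypnogram(c("W", "L", "D", "L"))), 0)
  # the signed alternative sees them
  expect_equal(transition_intensity(hypnogram(c("W", "L", "D", "L")), labeling = "signed"), 2)
  # never exceeds n - 1
  set.seed(2)
  h <- hypnogram(sample(c("W", "R", "L", "D"), 100, replace = TRUE))
  expect_lte(transition_intensity(h), 99)
})

test_that("hypnogram features match a hand-counted oracle night", {
  # 8-h night: 20 ep W onset | 100 L | 40 D | 30 R | 10 W | 400 L | 330 W... no:
  stage <- c(
    rep("W", 20), rep("L", 100), rep("D", 40), rep("R", 30),
    rep("W", 10), rep("L", 400), rep("R", 60), rep("L", 240), rep("W", 60)
  )
  hyp <- hypnogram(stage) # 960 epochs = 8 h
  expect_equal(nrow(hyp), 960)
  f <- hypnogram_features(hyp)
  expect_equal(f$sleep_efficiency, 870 / 960)
  expect_equal(f$total_sleep_time, 870 * 0.5)
  expect_equal(f$n_W_bouts, 2) # the mid-night and trailing wake runs
  expect_equal(f$W_duration, 45)
  expect_equal(f$NREM_duration, (100 + 40 + 400 + 240) * 0.5)
  expect_equal(f$R_proportion, 90 / 960)
  expect_equal(f$D_proportion, 40 / 960)
  expect_equal(f$sleep_incubation, 10)
  expect_equal(f$REM_incubation, 140 * 0.5)
  # after 6 h (epoch 720): epochs 721..960 contain 60 R (at 761..820)? count:
  late <- stage[721:960]
  expect_equal(f$freq_WR_after_6h, sum(late %in% c("W", "R")) / (240 * 30 / 3600))
  # transition intensity: R runs bounded by non-R on both sides -> 4 crossings
  expect_equal(f$transition_intensity, 4)

  # 120 W epochs in a 960-epoch night give 60 min of wake
  h2 <- hypnogram(c(rep("L", 840), rep("W", 120)))
  expect_equal(hypnogram_features(h2)$W_duration, 60)

  expect_error(hypnogram_features(hypnogram(rep("L", 10))), "shorter")
  # short nights lose only the post-6h feature
  h3 <- hypnogram(rep(c("L", "W"), each = 240))
  expect_true(is.na(hypnogram_features(h3)$freq_WR_after_6h))
  expect_false(is.na(hypnogram_features(h3)$sleep_efficiency))
})

test_that("quality labels follow the questionnaire threshold", {
  expect_equal(quality_label(c(0, 6, 7, 22)), c("good", "good", "poor", "poor"))
  expect_error(quality_label(25))
})

test_that("SVM-RFE ranks a perfect separator first and tolerates duplicates", {
  set.seed(61)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(
    sep = as.numeric(y) + rnorm(n, 0, 0.05),
    a = rnorm(n), b = rnorm(n), c = rnorm(n)
  )
  rk <- svm_rfe(x, y)
  expect_equal(rk$feature[1], "sep")

  dup <- dplyr::bind_cols(x, tibble::tibble(sep2 = x$sep))
  expect_silent(rk2 <- svm_rfe(dup, y))
  expect_setequal(rk2$feature, names(dup))

  expect_error(svm_rfe(x, rep(TRUE, n)), "two classes")
  expect_error(svm_rfe(x[, 1, drop = FALSE], y), "two features")
})

test_that("SVM-RFE recovers planted informative features across seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    y <- rep(c(TRUE, FALSE), each = n / 2)
    informative <- paste0("inf", 1:3)
    x <- as.data.frame(c(
      setNames(lapply(1:3, function(i) as.numeric(y) * (1 + 0.3 * i) + rnorm(n, 0, 0.4)), informative),
      setNames(lapply(1:7, function(i) rnorm(n)), paste0("noise", 1:7))
    ))
    rk <- svm_rfe(x, y)
    all(informative %in% rk$feature[1:5])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("quality model recovers planted cohort structure", {
  co <- simulate_cohort(cohort_config(n_subjects = 40, seed = 17))
  feats <- dplyr::bind_rows(lapply(co$hypnogram, hypnogram_features))
  m <- train_quality(feats, co$quality, seed = 2)
  expect_gte(m$cv$average_accuracy, 0.75)

  # prediction is deterministic and partitions the cohort
  p1 <- predict_quality(m, feats)
  p2 <- predict_quality(m, feats)
  expect_identical(p1, p2)
  expect_equal(sum(p1$label == "good") + sum(p1$label == "poor"), 40)
  expect_gte(mean(p1$label == co$quality), 0.85)

  # a perfect prediction scores per-class accuracy 1
  rep_perf <- cardiosleep:::quality_report(co$quality, co$quality)
  expect_equal(rep_perf$good_accuracy, 1)
  expect_equal(rep_perf$poor_accuracy, 1)

  expect_error(train_quality(feats, rep("good", 40)), "both")
  expect_error(predict_quality(m, feats[, 1:3]), "missing required")

  # model bundle round trip preserves predictions
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_bundle(m, path)
  back <- read_model_bundle(path)
  p3 <- predict_quality(back, feats)
  expect_identical(p1$label, p3$label)
  expect_equal(p1$decision, p3$decision, tolerance = 1e-9)
})

test_that("permuted quality labels yield chance-level cross-validation", {
  co <- simulate_cohort(cohort_config(n_subjects = 40, seed = 23))
  feats <- dplyr::bind_rows(lapply(co$hypnogram, hypnogram_features))
  set.seed(99)
  shuffled <- sample(co$quality)
  m <- train_quality(feats, shuffled, seed = 3)
  se <- sqrt(0.25 / m$cv$n)
  expect_lt(abs(m$cv$average_accuracy - 0.5), 3 * se + 1e-9)
})
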