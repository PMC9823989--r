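make_night_features <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    record_id = "n1",
    epoch = seq_len(n) - 1L,
    stage = sample(c("W", "R", "L", "D"), n, replace = TRUE),
    usable = TRUE,
    coRR = rnorm(n), HR = rnorm(n, 65, 5), resf = runif(n, 0.2, 0.4),
    alpha1 = rnorm(n, 1), alpha2 = rnorm(n), SE = rnorm(n, 1.5),
    P1 = runif(n, 30, 70), G1 = runif(n, 30, 70), LF = rexp(n),
    corr2 = runif(n, -1, 1)
  )
}

test_that("principal curves reduce to the z-scored feature for one variable", {
  nf <- make_night_features()
  rec <- recognizer("W", features = "HR", small_frame = 1, large_frame = 121)
  cv <- principal_curves(nf, rec)
  z <- (nf$HR - mean(nf$HR)) / sd(nf$HR)
  expect_equal(cv$F1, z, tolerance = 1e-9)
  expect_equal(cv$SF1, cv$F1) # frame 1 smoother is the identity
})

test_that("principal-component loadings match the covariance eigenvector", {
  set.seed(9)
  n <- 300
  latent <- rnorm(n)
  nf <- tibble::tibble(
    epoch = seq_len(n) - 1L,
    HR = 60 + 5 * latent + rnorm(n, 0, 0.5),
    resf = 0.3 + 0.05 * latent + rnorm(n, 0, 0.005)
  )
  rec <- recognizer("W", features = c("HR", "resf"), small_frame = 1, large_frame = 3)
  cv <- principal_curves(nf, rec)
  Z <- scale(cbind(nf$HR, nf$resf))
  ev <- oracle_first_eigvec(Z)
  f1_oracle <- as.numeric(Z %*% ev)
  f1_oracle <- (f1_oracle - mean(f1_oracle)) / sd(f1_oracle)
  expect_gt(abs(cor(cv$F1, f1_oracle)), 1 - 1e-9)
})

test_that("flip-set features are negated before the PCA", {
  nf <- make_night_features()
  plain <- principal_curves(nf, recognizer("W", features = "SE", flip = character(0), small_frame = 1, large_frame = 121))
  flipped <- principal_curves(nf, recognizer("W", features = "SE", flip = "SE", small_frame = 1, large_frame = 121))
  expect_equal(flipped$F1, -plain$F1, tolerance = 1e-9)
})

test_that("principal_curves imputes small gaps and rejects majority-missing features", {
  nf <- make_night_features()
  nf$HR[5:10] <- NA
  rec <- recognizer("W")
  expect_silent(cv <- principal_curves(nf, rec))
  expect_false(anyNA(cv$F1))
  nf$HR[seq_len(150)] <- NA
  expect_error(principal_curves(nf, rec), "missing")
})

test_that("recognizer tags are monotone in the offset and strict at equality", {
  nf <- make_night_features(seed = 3)
  rec <- recognizer("W")
  cv <- principal_curves(nf, rec)
  counts <- vapply(seq(-2, 2, 0.25), function(k) sum(apply_recognizer(cv, rec, k = k)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)] <= counts[1], TRUE)

  rec_d <- recognizer("D")
  cv_d <- principal_curves(nf, rec_d)
  counts_d <- vapply(seq(-2, 2, 0.25), function(k) sum(apply_recognizer(cv_d, rec_d, k = k)), numeric(1))
  expect_true(all(diff(counts_d) >= 0))

  flat <- cv
  flat$SF1 <- flat$BF1
  expect_equal(sum(apply_recognizer(flat, rec, k = 0)), 0)
})

test_that("boundary adjustment is a no-op for c_h = 0 and for non-crossing curves", {
  nf <- make_night_features(seed = 4)
  rec0 <- recognizer("W", c_h = 0)
  cv <- principal_curves(nf, rec0)
  tags <- apply_recognizer(cv, rec0)
  expect_identical(adjust_boundaries(cv, rec0, tags), tags)

  rec <- recognizer("W", k = 10) # threshold never crossed
  tags2 <- apply_recognizer(cv, rec)
  expect_identical(adjust_boundaries(cv, rec, tags2), tags2)
})

test_that("boundary adjustment matches the closed-form ramp on a triangular excursion", {
  # SF1 - BF1 is a symmetric triangle: rises from -1 to +1 over 20 epochs
  n <- 61
  d <- c(seq(-1, 1, length.out = 21), seq(1, -1, length.out = 21)[-1], rep(-1, 20))
  cv <- tibble::tibble(epoch = seq_len(n) - 1L, F1 = d, SF1 = d, BF1 = 0)
  rec <- recognizer("W", k = 0, c_h = 0.25, c_w = 0.5)
  tags <- apply_recognizer(cv, rec)
  out <- adjust_boundaries(cv, rec, tags)

  # direct evaluation of the documented ramp: H - L = 2, ramp height 0.5,
  # width 0.5 * span; the excursion runs where d > 0
  run <- which(d > 0)
  s <- run[1]
  e <- run[length(run)]
  i_min1 <- which.min(d[1:(s - 1)])
  i_max <- s - 1 + which.max(d[s:e])
  ramp1 <- pmax(0.25 * (d[i_max] - d[i_min1]) *
    (1 - (run - s) / (0.5 * (i_max - i_min1))), 0)
  post <- which(seq_len(n) > e)
  i_min2 <- e + which.min(d[post])
  ramp2 <- pmax(0.25 * (d[i_max] - d[i_min2]) *
    (1 - (e - run) / (0.5 * (i_min2 - i_max))), 0)
  expected <- tags
  expected[run] <- d[run] > pmax(ramp1, ramp2)
  expect_identical(out, expected)
  expect_lt(sum(out), sum(tags)) # marginal epochs near crossings were shaved
})

test_that("fusion training separates planted classes and calibrates sanely", {
  sep <- separable_data(150, shift = 3, p = 4, seed = 7)
  stage <- ifelse(sep$y == "A", "W", "L")
  dat <- dplyr::bind_cols(sep$data, tibble::tibble(stage = stage))
  # single classifier route: WR/N on separable data
  bc <- cardiosleep:::fit_binary(dat, stage, "W", "L", paste0("f", 1:4), seed = 1)
  holdout <- separable_data(80, shift = 3, p = 4, seed = 8)
  pr <- cardiosleep:::predict_binary(bc, holdout$data)
  pred <- ifelse(pr$decision > 0, "W", "L")
  truth <- ifelse(holdout$y == "A", "W", "L")
  expect_gte(mean(pred == truth), 0.95)
  # Platt outputs lie in (0,1) and increase with the margin
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  ord <- order(pr$decision)
  expect_true(all(diff(pr$prob[ord]) >= -1e-12))
})

test_that("permuted labels yield near-prior calibrated probabilities", {
  set.seed(15)
  sep <- separable_data(120, shift = 0, p = 4, seed = 15) # no signal at all
  y <- sample(rep(c("W", "L"), each = 120))
  dat <- dplyr::bind_cols(sep$data, tibble::tibble(stage = y))
  bc <- cardiosleep:::fit_binary(dat, y, "W", "L", paste0("f", 1:4), seed = 2)
  pr <- cardiosleep:::predict_binary(bc, sep$data)
  expect_lt(abs(mean(pr$prob) - 0.5), 0.1)
})

test_that("tag fusion follows the routing rules for all sixteen tag sets", {
  p_wr <- 0.9
  p_w <- 0.8
  p_l <- 0.9
  fusion <- stub_fusion(p_wr, p_w, p_l)
  feats <- tibble::tibble(x1 = 0)
  joint <- c(
    W = p_wr * p_w, R = p_wr * (1 - p_w),
    L = (1 - p_wr) * p_l, D = (1 - p_wr) * (1 - p_l)
  )
  stages <- c("W", "R", "L", "D")
  # independent statement of the printed rules
  expected_label <- function(tg) {
    if (length(tg) == 1) {
      return(tg)
    }
    if (setequal(tg, c("W", "R"))) {
      return(if (p_w > 0.5) "W" else "R")
    }
    if (setequal(tg, c("L", "D"))) {
      return(if (p_l > 0.5) "L" else "D")
    }
    if (length(tg) == 2) {
      grp <- if (p_wr > 0.5) c("W", "R") else c("L", "D")
      return(intersect(tg, grp))
    }
    names(joint)[which.max(joint)]
  }
  for (mask in 0:15) {
    tags <- matrix(as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L))),
      nrow = 1, dimnames = list(NULL, stages)
    )
    res <- fuse(tags, fusion, feats)
    lab <- res$hypnogram$stage
    expect_length(lab, 1)
    expect_true(lab %in% stages)
    expect_identical(lab, expected_label(stages[tags[1, ]]), label = sprintf("mask %d", mask))
    # joint products are proper probabilities
    expect_true(all(unlist(res$probs[, c("p_W", "p_R", "p_L", "p_D")]) >= 0))
    expect_true(all(unlist(res$probs[, c("p_W", "p_R", "p_L", "p_D")]) <= 1))
  }
})

test_that("post-hoc corrections enforce the 80-min REM and 30-min deep rules idempotently", {
  # REM at minute 40 after onset becomes wake
  stage <- c(rep("W", 10), rep("L", 80), rep("R", 4), rep("L", 200))
  hyp <- hypnogram(stage, source = "predicted")
  out <- postprocess_hypnogram(hyp)
  expect_true(all(out$stage[91:94] == "W"))

  # REM past the 80-min lockout survives
  stage2 <- c(rep("W", 10), rep("L", 170), rep("R", 4), rep("L", 100))
  out2 <- postprocess_hypnogram(hypnogram(stage2, source = "predicted"))
  expect_true(all(out2$stage[181:184] == "R"))

  # deep sleep 10 min before the final awakening becomes light
  stage3 <- c(rep("W", 10), rep("L", 300), rep("D", 20), rep("W", 30))
  out3 <- postprocess_hypnogram(hypnogram(stage3, source = "predicted"))
  expect_true(all(out3$stage[311:330] == "L"))

  # deep sleep well before the pre-wake window survives
  stage4 <- c(rep("W", 10), rep("D", 20), rep("L", 300), rep("W", 30))
  out4 <- postprocess_hypnogram(hypnogram(stage4, source = "predicted"))
  expect_true(all(out4$stage[11:30] == "D"))

  for (h in list(hyp, hypnogram(stage3, source = "predicted"))) {
    once <- postprocess_hypnogram(h)
    expect_identical(postprocess_hypnogram(once)$stage, once$stage)
  }
})

test_that("staging metrics match their definitions", {
  # Youden from stated sensitivity/specificity: 0.8 + 0.7 - 1 = 0.5
  truth <- hypnogram(c(rep("W", 10), rep("L", 10)))
  pred <- hypnogram(c(rep("W", 8), "L", "L", rep("L", 7), "W", "W", "W"))
  ev <- evaluate_staging(pred, truth)
  w_row <- ev$per_stage[ev$per_stage$stage == "W", ]
  expect_equal(w_row$sensitivity, 0.8)
  expect_equal(w_row$specificity, 0.7)
  expect_equal(w_row$youden, 0.5)

  perfect <- evaluate_staging(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  # fixed 20-epoch confusion, hand-counted
  t20 <- hypnogram(c(rep("W", 5), rep("R", 5), rep("L", 5), rep("D", 5)))
  p20 <- hypnogram(c(
    "W", "W", "W", "R", "L", # W: 3 hit, 1 R, 1 L
    "R", "R", "R", "R", "W", # R: 4 hit, 1 W
    "L", "L", "L", "D", "D", # L: 3 hit, 2 D
    "D", "D", "D", "D", "L" # D: 4 hit, 1 L
  ))
  ev20 <- evaluate_staging(p20, t20)
  expect_equal(ev20$accuracy, 14 / 20)
  expect_equal(unname(ev20$confusion["W", "W"]), 3)
  expect_equal(unname(ev20$confusion["L", "D"]), 2)
  # hand-computed per-class F1: precision and recall from the matrix above
  f1 <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)
  expect_equal(
    ev20$macro_f1,
    mean(c(f1(3, 1, 2), f1(4, 1, 1), f1(3, 2, 2), f1(4, 2, 1)))
  )
  expect_error(evaluate_staging(p20, hypnogram(rep("W", 5))), "length")

  expect_equal(nrow(tidy(ev20)), 4)
  expect_equal(glance(ev20)$accuracy, 0.7)
})

test_that("combination search enumerates, ranks and is deterministic", {
  set.seed(31)
  n <- 120
  target <- rep(rep(c(TRUE, FALSE), each = 10), 6) # 10-epoch wake excursions
  nf <- tibble::tibble(
    record_id = "n1", epoch = seq_len(n) - 1L,
    stage = ifelse(target, "W", "L"), usable = TRUE,
    good = as.numeric(target) * 3 + rnorm(n, 0, 0.1),
    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n)
  )
  ctl <- stager_control(small_frame = 1, large_frame = 121)
  ranked <- search_feature_combinations(
    nf, "W",
    candidates = c("good", "n1", "n2", "n3", "n4"),
    max_size = 2, control = ctl
  )
  expect_equal(nrow(ranked), choose(5, 1) + choose(5, 2))
  expect_true(grepl("good", ranked$combination[1]))
  ranked2 <- search_feature_combinations(
    nf, "W",
    candidates = c("good", "n1", "n2", "n3", "n4"),
    max_size = 2, control = ctl
  )
  expect_identical(ranked$combination, ranked2$combination)
})

test_that("useless-feature elimination removes planted noise but keeps signal", {
  set.seed(41)
  n <- 160
  mk_ranked <- function(stage_lab) {
    target <- rep(rep(c(TRUE, FALSE), each = 10), n / 20)
    nf <- tibble::tibble(
      record_id = "n1", epoch = seq_len(n) - 1L,
      stage = ifelse(target, stage_lab, setdiff(c("W", "L"), stage_lab)[1]),
      usable = TRUE,
      sig = as.numeric(target) * 3 + rnorm(n, 0, 0.2),
      noise = rnorm(n),
      other = as.numeric(target) * 1.5 + rnorm(n, 0, 0.5)
    )
    search_feature_combinations(
      nf, stage_lab,
      candidates = c("sig", "noise", "other"), max_size = 2,
      control = stager_control(small_frame = 1, large_frame = 121)
    )
  }
  ranked <- list(W = mk_ranked("W"), R = NULL, L = mk_ranked("L"), D = NULL)
  ranked$R <- ranked$W
  ranked$D <- ranked$L
  out <- eliminate_useless_features(ranked, top_frac = 1 / 3, bottom_frac = 1 / 3)
  expect_true("sig" %in% out$kept)
  expect_false("sig" %in% out$removed)

  # empty intersection leaves the set unchanged
  r2 <- ranked
  r2$W <- r2$W[nrow(r2$W):1, ] # reverse one stage's ranking
  out2 <- eliminate_useless_features(r2, top_frac = 1 / 3, bottom_frac = 1 / 3)
  expect_true(length(out2$removed) <= length(out$removed))
})

test_that("stager round-trips through the YAML model bundle", {
  set.seed(51)
  # tiny but structured training set: two nights with stage-dependent features
  mk <- function(rid, seed) {
    set.seed(seed)
    n <- 160
    stage <- rep(rep(c("W", "L", "D", "R"), each = 10), 4)
    mu <- c(W = 2, R = 1, L = -1, D = -2)[stage]
    tibble::tibble(
      record_id = rid, epoch = seq_len(n) - 1L, stage = stage, usable = TRUE,
      coRR = mu + rnorm(n, 0, 0.5), HR = 60 + 3 * mu + rnorm(n),
      resf = 0.3 + 0.02 * mu + rnorm(n, 0, 0.01),
      alpha1 = rnorm(n), alpha2 = -mu + rnorm(n, 0, 0.5),
      SE = rnorm(n), P1 = 50 + 5 * mu + rnorm(n), G1 = 50 + rnorm(n),
      LF = exp(mu / 2 + rnorm(n, 0, 0.2)), corr2 = runif(n, -1, 1)
    )
  }
  train <- dplyr::bind_rows(mk("a", 1), mk("b", 2))
  model <- train_stager(train, control = stager_control(
    small_frame = 3, large_frame = 11, max_rows = 500,
    cost_grid = 1, gamma_mult = 1
  ))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_bundle(model, path)
  back <- read_model_bundle(path)
  expect_s3_class(back, "stager")
  expect_equal(back$recognizers$W$k, model$recognizers$W$k)
  res1 <- stage_night(model, mk("c", 3))
  res2 <- stage_night(back, mk("c", 3))
  expect_identical(res1$hypnogram$stage, res2$hypnogram$stage)
  expect_equal(res1$probs$p_wr, res2$probs$p_wr, tolerance = 1e-9)
})
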