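#' Control parameters for the staging model
#'
#' @param small_frame,large_frame,sg_order Smoothing settings passed to every
#'   [recognizer()].
#' @param k_grid Candidate offsets (standardized component units) searched for
#'   the wake, REM and deep recognizers.
#' @param band_grid Candidate offsets for the light-sleep band (all pairs
#'   `k1 < k2` are searched).
#' @param c_h,c_w Boundary-adjustment constants.
#' @param n_keep Features kept per fusion classifier after SVM-RFE.
#' @param max_rows Training-row cap per fusion classifier (stratified
#'   subsample).
#' @param cost_grid,gamma_mult Inner grid for the fusion SVMs.
#' @param seed Seed for the subsampling and inner cross-validation.
#' @return A named list.
#' @export
stager_control <- function(small_frame = 11, large_frame = 121, sg_order = 2,
                           k_grid = seq(-2, 2, length.out = 41),
                           band_grid = seq(-2, 2, length.out = 15),
                           c_h = 0.25, c_w = 0.5,
                           n_keep = 15, max_rows = 3000,
                           cost_grid = c(1, 10), gamma_mult = c(0.5, 2),
                           seed = 1) {
  list(
    small_frame = small_frame, large_frame = large_frame, sg_order = sg_order,
    k_grid = k_grid, band_grid = band_grid, c_h = c_h, c_w = c_w,
    n_keep = n_keep, max_rows = max_rows,
    cost_grid = cost_grid, gamma_mult = gamma_mult, seed = seed
  )
}

recognizer_from_control <- function(stage, control, features = NULL, k = NULL) {
  args <- list(
    stage = stage,
    small_frame = control$small_frame, large_frame = control$large_frame,
    sg_order = control$sg_order, c_h = control$c_h, c_w = control$c_w
  )
  if (!is.null(features)) args$features <- features
  if (!is.null(k)) args$k <- k
  do.call(recognizer, args)
}

binary_score <- function(tags, truth) {
  acc <- mean(tags == truth)
  sens <- if (any(truth)) mean(tags[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!tags[!truth]) else NA_real_
  youden <- sens + spec - 1
  c(accuracy = acc, youden = youden, score = (acc + youden) / 2)
}

# choose the recognizer offset(s) on a grid, maximizing (accuracy + Youden)/2
# pooled over nights; ties break toward the smallest |k|
fit_recognizer_offset <- function(d_list, truth_list, direction, k_grid, band_grid) {
  d <- unlist(d_list)
  truth <- unlist(truth_list)
  if (direction == "band") {
    pairs <- combn(band_grid, 2)
    scores <- apply(pairs, 2, function(kk) {
      binary_score(d > kk[1] & d < kk[2], truth)[["score"]]
    })
    scores[is.na(scores)] <- -Inf
    best <- max(scores)
    cand <- which(scores >= best - 1e-12)
    cand <- cand[which.min(abs(pairs[1, cand]) + abs(pairs[2, cand]))]
    return(pairs[, cand])
  }
  scores <- vapply(k_grid, function(k) {
    tags <- if (direction == "above") d > k else d < k
    binary_score(tags, truth)[["score"]]
  }, numeric(1))
  scores[is.na(scores)] <- -Inf
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  k_grid[cand[which.min(abs(k_grid[cand]))]]
}

#' Train the multi-classifier fusion model
#'
#' Fits the three Platt-calibrated binary SVMs used to resolve ambiguous
#' recognizer tags: WR/N (wake-or-REM vs NREM, all epochs), W/R (within
#' wake/REM epochs) and L/D (within NREM epochs). Features are selected per
#' classifier by linear SVM-RFE before the RBF fit.
#'
#' @param features Feature table with a `stage` truth column (training
#'   epochs).
#' @param feature_names Candidate columns (default: the 13 retained HRV
#'   features plus the 20 contextual features).
#' @param control See [stager_control()].
#' @return A list of class `fusion_model` with classifiers `wrn`, `wr`, `ld`.
#' @export
train_fusion <- function(features,
                         feature_names = c(
                           hrv_feature_names("retained"),
                           hrv_feature_names("context")
                         ),
                         control = stager_control()) {
  stopifnot("stage" %in% names(features))
  feature_names <- intersect(feature_names, names(features))
  stage <- features$stage
  fit_one <- function(data, y, pos, neg, seed_off) {
    present <- unique(y)
    if (!all(c(pos, neg) %in% present)) {
      abort(sprintf("degenerate training data: need both %s and %s epochs.", pos, neg))
    }
    set.seed(control$seed + seed_off)
    sel <- feature_names
    if (length(feature_names) > control$n_keep) {
      sub <- if (nrow(data) > 1500) stratified_sample(y, 1500) else seq_len(nrow(data))
      rfe <- svm_rfe(data[sub, feature_names, drop = FALSE], y[sub] == pos)
      sel <- rfe$feature[seq_len(control$n_keep)]
    }
    fit_binary(data, y, pos, neg, sel,
      kernel = "radial",
      cost_grid = control$cost_grid, gamma_mult = control$gamma_mult,
      max_rows = control$max_rows, seed = control$seed + seed_off
    )
  }
  y_group <- ifelse(stage %in% c("W", "R"), "WR", "N")
  wrn <- fit_one(features, y_group, "WR", "N", 11)
  in_wr <- stage %in% c("W", "R")
  wr <- fit_one(features[in_wr, , drop = FALSE], stage[in_wr], "W", "R", 22)
  in_ld <- stage %in% c("L", "D")
  ld <- fit_one(features[in_ld, , drop = FALSE], stage[in_ld], "L", "D", 33)
  structure(list(wrn = wrn, wr = wr, ld = ld), class = "fusion_model")
}

#' Fuse recognizer tags into a final per-epoch stage
#'
#' Routing rules: an epoch with exactly one tag keeps it; tags `{W, R}` or
#' `{L, D}` are resolved by the corresponding conditional classifier alone
#' (the group probability is not computed); one tag from each group is
#' resolved by the WR/N classifier, the surviving group's tag winning; zero,
#' three or four tags fall through to the arg-max of the four joint
#' probabilities `P(WR)P(W|WR)`, `P(WR)P(R|WR)`, `P(N)P(L|N)`, `P(N)P(D|N)`.
#'
#' @param tags Logical matrix or data frame with columns `W`, `R`, `L`, `D`,
#'   one row per epoch.
#' @param fusion A [train_fusion()] model.
#' @param features Feature table for the same epochs (classifier inputs).
#' @param record_id Identifier for the predicted hypnogram.
#' @return A list of class `staging_result`: `hypnogram` (predicted),
#'   `probs` (per-epoch tibble of tags, probabilities and the final stage).
#' @export
fuse <- function(tags, fusion, features, record_id = "record") {
  tags <- as.matrix(as.data.frame(tags)[, STAGES])
  storage.mode(tags) <- "logical"
  n <- nrow(tags)
  stopifnot(nrow(features) == n)

  p_wr <- predict_binary(fusion$wrn, features)$prob
  p_w <- predict_binary(fusion$wr, features)$prob
  p_l <- predict_binary(fusion$ld, features)$prob
  joint <- cbind(
    W = p_wr * p_w, R = p_wr * (1 - p_w),
    L = (1 - p_wr) * p_l, D = (1 - p_wr) * (1 - p_l)
  )

  n_tags <- rowSums(tags)
  stage <- character(n)
  for (i in seq_len(n)) {
    tg <- STAGES[tags[i, ]]
    stage[i] <- if (n_tags[i] == 1) {
      tg
    } else if (n_tags[i] == 2 && setequal(tg, c("W", "R"))) {
      if (p_w[i] > 0.5) "W" else "R"
    } else if (n_tags[i] == 2 && setequal(tg, c("L", "D"))) {
      if (p_l[i] > 0.5) "L" else "D"
    } else if (n_tags[i] == 2) {
      grp <- if (p_wr[i] > 0.5) c("W", "R") else c("L", "D")
      intersect(tg, grp)
    } else {
      STAGES[which.max(joint[i, ])]
    }
  }
  probs <- bind_cols(
    tibble(epoch = seq_len(n) - 1L),
    as_tibble(tags) %>% rename(tag_W = "W", tag_R = "R", tag_L = "L", tag_D = "D"),
    tibble(p_wr = p_wr, p_w_given_wr = p_w, p_l_given_n = p_l),
    as_tibble(joint) %>% rename(p_W = "W", p_R = "R", p_L = "L", p_D = "D"),
    tibble(stage = stage)
  )
  structure(
    list(
      hypnogram = hypnogram(stage, source = "predicted", record_id = record_id),
      probs = probs
    ),
    class = "staging_result"
  )
}

#' @export
print.staging_result <- function(x, ...) {
  cat("<staging_result>\n")
  print(x$hypnogram)
  invisible(x)
}

#' Physiological post-hoc correction of a predicted hypnogram
#'
#' REM epochs scored within the first 80 min after sleep onset are replaced by
#' wakefulness (sleep-onset REM is implausible in healthy adults), and deep
#' sleep within the 30 min before the final awakening is relabelled light
#' sleep. Sleep onset is taken as the first light- or deep-sleep epoch (so the
#' REM correction cannot move it, making the operation idempotent); the final
#' awakening is the start of the last wake run only when that run reaches the
#' end of the record.
#'
#' @param hyp A predicted `hypnogram`.
#' @param rem_lockout_min,deep_lockout_min Correction spans in minutes
#'   (defaults 80 and 30).
#' @return The corrected `hypnogram`.
#' @export
postprocess_hypnogram <- function(hyp, rem_lockout_min = 80, deep_lockout_min = 30) {
  stage <- hyp$stage
  n <- length(stage)
  onset <- which(stage %in% c("L", "D"))[1]
  if (!is.na(onset)) {
    lock <- rem_lockout_min * 60 / EPOCH_LEN
    fix <- which(stage == "R")
    fix <- fix[fix >= onset & fix < onset + lock]
    stage[fix] <- "W"
  }
  if (stage[n] == "W") {
    runs <- hyp_runs(hyp)
    wake_start <- runs$start_epoch[nrow(runs)] + 1L # 1-based epoch index
    lock <- deep_lockout_min * 60 / EPOCH_LEN
    fix <- which(stage == "D")
    fix <- fix[fix >= wake_start - lock & fix < wake_start]
    stage[fix] <- "L"
  }
  out <- hyp
  out$stage <- stage
  restore_hyp(out, hyp, source = attr(hyp, "source"))
}

#' Evaluate a predicted hypnogram against an annotated one
#'
#' @param pred,truth Hypnograms of equal length.
#' @return A list of class `staging_eval`: `confusion` (truth in rows),
#'   `accuracy`, `macro_f1`, and `per_stage` (sensitivity, specificity,
#'   Youden's index `sensitivity + specificity - 1`, precision and F1 per
#'   stage). Use [tidy()] / [glance()] for tabular access.
#' @export
evaluate_staging <- function(pred, truth) {
  if (nrow(pred) != nrow(truth)) abort("pred and truth differ in length.")
  p <- factor(pred$stage, levels = STAGES)
  t_ <- factor(truth$stage, levels = STAGES)
  cm <- table(truth = t_, pred = p)
  per <- purrr::map_dfr(STAGES, function(s) {
    tp <- cm[s, s]
    fn <- sum(cm[s, ]) - tp
    fp <- sum(cm[, s]) - tp
    tn <- sum(cm) - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else {
      NA_real_
    }
    tibble(
      stage = s, n_truth = tp + fn, sensitivity = sens, specificity = spec,
      youden = sens + spec - 1, precision = prec, f1 = f1
    )
  })
  structure(
    list(
      confusion = cm,
      accuracy = mean(p == t_),
      macro_f1 = mean(per$f1, na.rm = TRUE),
      per_stage = per
    ),
    class = "staging_eval"
  )
}

#' @export
print.staging_eval <- function(x, ...) {
  cat(sprintf(
    "<staging_eval> accuracy %.3f, macro F1 %.3f over %d epochs\n",
    x$accuracy, x$macro_f1, sum(x$confusion)
  ))
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate_staging
#' @param x A `staging_eval`.
#' @param ... Unused.
#' @export
tidy.staging_eval <- function(x, ...) x$per_stage

#' @rdname evaluate_staging
#' @export
glance.staging_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1, n_epochs = sum(x$confusion))
}

#' Exhaustive search over small feature combinations for one recognizer
#'
#' Scores every combination of up to `max_size` candidate features by building
#' a provisional recognizer (within-night PCA, dual smoothing, best offset on
#' the grid) and evaluating binary recognition of `stage` against all usable
#' training epochs, ranking by `(accuracy + Youden)/2`.
#'
#' @param features Training feature table (with `record_id`, `stage`,
#'   `usable`).
#' @param stage Target stage.
#' @param candidates Candidate feature columns.
#' @param max_size Largest combination size (default 3).
#' @param control See [stager_control()].
#' @return A tibble ranked by score: `combination`, `features` (list-column),
#'   `k` (list-column), `accuracy`, `youden`, `score`.
#' @export
search_feature_combinations <- function(features, stage,
                                        candidates = hrv_feature_names("retained"),
                                        max_size = 3,
                                        control = stager_control()) {
  stage <- match.arg(stage, STAGES)
  candidates <- intersect(candidates, names(features))
  usable <- if ("usable" %in% names(features)) features$usable else TRUE
  dat <- features[usable & !is.na(features$stage), , drop = FALSE]
  nights <- split(dat, dat$record_id %||% "record")
  combos <- unlist(
    lapply(seq_len(max_size), function(s) combn(candidates, s, simplify = FALSE)),
    recursive = FALSE
  )
  direction <- switch(stage, W = "above", R = "above", L = "band", D = "below")

  rows <- purrr::map(combos, function(fs) {
    rec <- recognizer_from_control(stage, control, features = fs)
    d_list <- purrr::map(nights, function(nf) {
      cv <- principal_curves(nf, rec)
      cv$SF1 - cv$BF1
    })
    truth_list <- purrr::map(nights, ~ .x$stage == stage)
    k <- fit_recognizer_offset(
      d_list, truth_list, direction,
      control$k_grid, control$band_grid
    )
    d <- unlist(d_list)
    truth <- unlist(truth_list)
    tags <- switch(direction,
      above = d > k,
      below = d < k,
      band = d > k[1] & d < k[2]
    )
    sc <- binary_score(tags, truth)
    tibble(
      combination = paste(fs, collapse = "+"),
      features = list(fs), k = list(k),
      accuracy = sc[["accuracy"]], youden = sc[["youden"]], score = sc[["score"]]
    )
  })
  bind_rows(rows) %>% arrange(dplyr::desc(.data$score))
}

#' Remove globally useless features from the candidate set
#'
#' A feature is useless for one stage when it appears among the bottom-ranked
#' combinations of that stage's search but never among the top-ranked ones.
#' Features useless for all four stages are removed from the candidate set.
#'
#' @param ranked Named list (`W`, `R`, `L`, `D`) of tibbles from
#'   [search_feature_combinations()].
#' @param top_frac,bottom_frac Fractions of the ranking treated as top and
#'   bottom (defaults 0.25).
#' @return A list: `useless` (per-stage character vectors), `removed`
#'   (four-set intersection), `kept`.
#' @export
eliminate_useless_features <- function(ranked, top_frac = 0.25, bottom_frac = 0.25) {
  stopifnot(all(STAGES %in% names(ranked)))
  useless <- purrr::map(ranked[STAGES], function(tb) {
    n <- nrow(tb)
    n_top <- max(1L, ceiling(top_frac * n))
    n_bot <- max(1L, ceiling(bottom_frac * n))
    top_feats <- unique(unlist(tb$features[seq_len(n_top)]))
    bot_feats <- unique(unlist(tb$features[(n - n_bot + 1L):n]))
    setdiff(bot_feats, top_feats)
  })
  removed <- Reduce(intersect, useless)
  all_feats <- unique(unlist(purrr::map(ranked, ~ unique(unlist(.x$features)))))
  list(useless = useless, removed = removed, kept = setdiff(all_feats, removed))
}

#' Train the full staging model
#'
#' Fits, on a set of annotated training nights: the offset `k` of each of the
#' four stage recognizers (grid search maximizing pooled
#' `(accuracy + Youden)/2`), and the three fusion classifiers with their Platt
#' calibration. Only usable epochs (untruncated windows spanning at most two
#' stages) are used.
#'
#' @param features Pooled feature table of the training nights
#'   (from [extract_night()] with hypnograms; must contain `record_id`,
#'   `stage`, `usable`).
#' @param recognizer_features Per-stage feature sets (default
#'   [default_recognizer_features()]).
#' @param control See [stager_control()].
#' @return A list of class `stager`: `recognizers`, `fusion`, `control`.
#' @export
train_stager <- function(features,
                         recognizer_features = default_recognizer_features(),
                         control = stager_control()) {
  stopifnot(all(c("record_id", "stage", "usable") %in% names(features)))
  dat <- features[features$usable & !is.na(features$stage), , drop = FALSE]
  if (nrow(dat) < 50) abort("too few usable training epochs.")
  nights <- split(dat, dat$record_id)

  recognizers <- purrr::map(STAGES, function(s) {
    rec <- recognizer_from_control(s, control, features = recognizer_features[[s]])
    d_list <- purrr::map(nights, function(nf) {
      cv <- principal_curves(nf, rec)
      cv$SF1 - cv$BF1
    })
    truth_list <- purrr::map(nights, ~ .x$stage == s)
    rec$k <- as.numeric(fit_recognizer_offset(
      d_list, truth_list, rec$direction,
      control$k_grid, control$band_grid
    ))
    rec
  })
  names(recognizers) <- STAGES

  fusion <- train_fusion(dat, control = control)
  structure(
    list(recognizers = recognizers, fusion = fusion, control = control),
    class = "stager"
  )
}

#' @export
print.stager <- function(x, ...) {
  cat("<stager> four-stage recognizer + fusion model\n")
  for (r in x$recognizers) print(r)
  invisible(x)
}

#' Stage one night with a trained model
#'
#' Runs the four recognizers (with boundary correction) over the night's
#' feature table, fuses the tags, and optionally applies the physiological
#' post-hoc corrections.
#'
#' @param stager A [train_stager()] model.
#' @param night_features Feature table of one night, ordered by epoch.
#' @param postprocess Apply [postprocess_hypnogram()]? Default `TRUE`.
#' @return A `staging_result` (see [fuse()]); `$hypnogram` is the prediction.
#' @export
stage_night <- function(stager, night_features, postprocess = TRUE) {
  tags <- vapply(STAGES, function(s) {
    rec <- stager$recognizers[[s]]
    cv <- principal_curves(night_features, rec)
    adjust_boundaries(cv, rec, apply_recognizer(cv, rec))
  }, logical(nrow(night_features)))
  tags <- matrix(tags, ncol = 4, dimnames = list(NULL, STAGES))
  rid <- if (!is.null(night_features$record_id)) night_features$record_id[1] else "record"
  res <- fuse(tags, stager$fusion, night_features, record_id = rid)
  if (postprocess) {
    res$hypnogram <- postprocess_hypnogram(res$hypnogram)
    res$probs$stage <- res$hypnogram$stage
  }
  res
}
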