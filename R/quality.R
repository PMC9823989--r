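#' Intensity of sleep-stage transitions
#'
#' Stages are mapped to numeric labels and the absolute differences of
#' neighbouring epochs summed. The default `"printed"` labelling assigns
#' W -> 1, R -> 0 and L/D -> 1, under which only transitions into and out of
#' REM are visible; the `"signed"` alternative (W -> 1, R -> 0, L/D -> -1)
#' also counts wake/NREM changes.
#'
#' @param hyp A `hypnogram`.
#' @param labeling `"printed"` (default) or `"signed"`.
#' @return A non-negative number, at most `n_epochs - 1`.
#' @export
transition_intensity <- function(hyp, labeling = c("printed", "signed")) {
  labeling <- match.arg(labeling)
  num <- switch(labeling,
    printed = c(W = 1, R = 0, L = 1, D = 1),
    signed = c(W = 1, R = 0, L = -1, D = -1)
  )
  sum(abs(diff(num[hyp$stage])))
}

#' Hypnogram-level sleep-quality features
#'
#' One row of night-structure descriptors used by the quality classifier.
#' Sleep onset is the first non-wake epoch. The nine primary features:
#' `sleep_efficiency` (non-W epochs over all epochs), `total_sleep_time`
#' (min), `n_W_bouts` (maximal wake runs after onset), `transition_intensity`
#' (see [transition_intensity()]), `freq_WR_after_6h` (W or R epochs beyond
#' 6 h, per hour of record beyond 6 h; `NA` for shorter records),
#' `NREM_duration`, `W_duration` (min), `R_proportion`, `D_proportion`.
#' Auxiliary candidates: `sleep_incubation` and `REM_incubation` latencies
#' (min), `L_duration`, `R_duration`, `D_duration`, `L_proportion`.
#'
#' @param hyp A `hypnogram` (at least 2 h unless `min_hours` is lowered).
#' @param min_hours Minimum record length in hours (default 2).
#' @return A one-row tibble, keyed by `record_id`.
#' @export
hypnogram_features <- function(hyp, min_hours = 2) {
  n <- nrow(hyp)
  if (n * EPOCH_LEN / 3600 < min_hours) {
    abort(sprintf("hypnogram shorter than %g h.", min_hours))
  }
  stage <- hyp$stage
  ep_min <- EPOCH_LEN / 60
  onset <- which(stage != "W")[1]

  n_stage <- function(s) sum(stage == s)
  runs <- hyp_runs(hyp)
  w_bouts_after <- if (is.na(onset)) 0L else {
    sum(runs$stage == "W" & runs$start_epoch + 1L > onset)
  }

  six_h <- 6 * 3600 / EPOCH_LEN # epochs in 6 h
  freq_wr <- if (n > six_h) {
    late <- stage[(six_h + 1):n]
    sum(late %in% c("W", "R")) / ((n - six_h) * EPOCH_LEN / 3600)
  } else {
    NA_real_
  }

  first_r <- which(stage == "R")[1]
  tibble(
    record_id = record_id(hyp),
    sleep_efficiency = mean(stage != "W"),
    total_sleep_time = sum(stage != "W") * ep_min,
    n_W_bouts = w_bouts_after,
    transition_intensity = transition_intensity(hyp),
    freq_WR_after_6h = freq_wr,
    NREM_duration = (n_stage("L") + n_stage("D")) * ep_min,
    W_duration = n_stage("W") * ep_min,
    R_proportion = n_stage("R") / n,
    D_proportion = n_stage("D") / n,
    sleep_incubation = if (is.na(onset)) NA_real_ else (onset - 1) * ep_min,
    REM_incubation = if (is.na(onset) || is.na(first_r)) NA_real_ else (first_r - onset) * ep_min,
    L_duration = n_stage("L") * ep_min,
    R_duration = n_stage("R") * ep_min,
    D_duration = n_stage("D") * ep_min,
    L_proportion = n_stage("L") / n
  )
}

#' The nine primary sleep-quality feature names
#' @return A character vector.
#' @export
quality_feature_names <- function() {
  c(
    "sleep_efficiency", "total_sleep_time", "n_W_bouts",
    "transition_intensity", "freq_WR_after_6h", "NREM_duration",
    "W_duration", "R_proportion", "D_proportion"
  )
}

#' Label a questionnaire score as good or poor sleep
#'
#' Scores run 0-22 (lower is better); a score of 6 or less is `"good"`,
#' above 6 `"poor"`.
#'
#' @param score Integer vector in `[0, 22]`.
#' @return Character vector of `"good"` / `"poor"`.
#' @export
quality_label <- function(score) {
  stopifnot(all(score >= 0 & score <= 22, na.rm = TRUE))
  ifelse(score <= 6, "good", "poor")
}

#' Train the good/poor sleep-quality classifier
#'
#' A third-order polynomial-kernel SVM on standardized hypnogram features,
#' with the regularization constant chosen by an inner grid search and a
#' 5-fold cross-validation report (per-class accuracy, average accuracy and
#' macro F1).
#'
#' @param features Feature table (one row per subject), e.g. rows of
#'   [hypnogram_features()].
#' @param label Character vector `"good"`/`"poor"` (or a 0-22 score vector,
#'   thresholded through [quality_label()]).
#' @param feature_names Columns used (default the nine primary features).
#' @param cost_grid Inner grid for the SVM cost.
#' @param cv_folds Folds for the CV report (default 5).
#' @param seed Seed for fold assignment.
#' @return A list of class `quality_model` with the fitted classifier and a
#'   `cv` report; see [tidy()] / [glance()].
#' @export
train_quality <- function(features, label,
                          feature_names = quality_feature_names(),
                          cost_grid = c(0.1, 1, 10), cv_folds = 5, seed = 1) {
  if (is.numeric(label)) label <- quality_label(label)
  stopifnot(nrow(features) == length(label))
  feature_names <- intersect(feature_names, names(features))
  if (!all(c("good", "poor") %in% label)) {
    abort("both good and poor subjects are needed for training.")
  }
  set.seed(seed)
  bc <- fit_binary(features, label, "poor", "good", feature_names,
    kernel = "polynomial", degree = 3,
    cost_grid = cost_grid, max_rows = 10000, seed = seed
  )

  # cross-validated performance report
  folds <- sample(rep_len(seq_len(cv_folds), nrow(features)))
  pred <- rep(NA_character_, nrow(features))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    if (length(unique(label[tr])) < 2) next
    m <- fit_binary(features[tr, , drop = FALSE], label[tr], "poor", "good",
      feature_names,
      kernel = "polynomial", degree = 3,
      cost_grid = cost_grid, max_rows = 10000, seed = seed + f
    )
    dv <- predict_binary(m, features[!tr, , drop = FALSE])$decision
    pred[!tr] <- ifelse(dv > 0, "poor", "good")
  }
  cv <- quality_report(pred, label)

  structure(
    list(classifier = bc, cv = cv, feature_names = feature_names),
    class = "quality_model"
  )
}

quality_report <- function(pred, truth) {
  ok <- !is.na(pred)
  pred <- pred[ok]
  truth <- truth[ok]
  per_class <- vapply(c("good", "poor"), function(cl) {
    if (!any(truth == cl)) {
      return(NA_real_)
    }
    mean(pred[truth == cl] == cl)
  }, numeric(1))
  f1 <- vapply(c("good", "poor"), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else NA_real_
    rec <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else NA_real_
    if (is.na(prec) || is.na(rec) || prec + rec == 0) {
      return(NA_real_)
    }
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(
    good_accuracy = per_class[["good"]],
    poor_accuracy = per_class[["poor"]],
    average_accuracy = mean(pred == truth),
    macro_f1 = mean(f1, na.rm = TRUE),
    n = length(pred)
  )
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf(
    "<quality_model> poly-3 SVM on %d features | CV accuracy %.3f, macro F1 %.3f (n=%d)\n",
    length(x$feature_names), x$cv$average_accuracy, x$cv$macro_f1, x$cv$n
  ))
  invisible(x)
}

#' @rdname train_quality
#' @param x A `quality_model`.
#' @param ... Unused.
#' @export
glance.quality_model <- function(x, ...) {
  tibble(
    good_accuracy = x$cv$good_accuracy,
    poor_accuracy = x$cv$poor_accuracy,
    average_accuracy = x$cv$average_accuracy,
    macro_f1 = x$cv$macro_f1,
    n = x$cv$n
  )
}

#' @rdname train_quality
#' @export
tidy.quality_model <- function(x, ...) {
  tibble(feature = x$feature_names)
}

#' Classify nights as good or poor sleep
#'
#' @param model A [train_quality()] model.
#' @param features Feature rows to classify (must contain the model's
#'   features; missing values are an error for required columns).
#' @return A tibble: `record_id` (when present), `label`, `decision` (margin;
#'   positive favours poor sleep) and `prob_poor` (Platt-calibrated).
#' @export
predict_quality <- function(model, features) {
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required feature(s): %s", paste(missing_cols, collapse = ", ")))
  }
  pr <- predict_binary(model$classifier, features)
  out <- tibble(
    label = ifelse(pr$decision > 0, "poor", "good"),
    decision = pr$decision,
    prob_poor = pr$prob
  )
  if ("record_id" %in% names(features)) {
    out <- bind_cols(tibble(record_id = features$record_id), out)
  }
  out
}
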