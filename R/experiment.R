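#' End-to-end synthetic recovery experiment
#'
#' Runs the whole pipeline on a simulated cohort with planted sleep-quality
#' labels: nights are split at the subject level into a training and a test
#' half; RR series are cleaned, per-epoch features extracted, the staging
#' model (recognizer offsets + fusion classifiers) trained on the training
#' nights and applied to the test nights; hypnogram-level quality features are
#' computed from the *predicted* test hypnograms, and a quality model trained
#' on the predicted training hypnograms is scored against the planted labels.
#'
#' @param cfg A [cohort_config()].
#' @param seed Seed controlling simulation, splits and model fitting.
#' @param features Window features to extract (default: the 13 retained HRV
#'   features; contextual features are always added).
#' @param train_frac Fraction of subjects used for training (default 0.5).
#' @param progress Print per-stage timing messages?
#' @return A list of class `cohort_experiment`:
#'   `staging` (pooled test-set [evaluate_staging()] result),
#'   `per_night` (tibble of per-night staging accuracies),
#'   `quality_recovery` (test-set accuracy against planted labels),
#'   `quality_model`, `stager`, and `cohort` (without the raw RR series).
#' @export
cohort_experiment <- function(cfg = cohort_config(), seed = cfg$seed,
                              features = hrv_feature_names("retained"),
                              train_frac = 0.5, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  cfg$seed <- seed
  cohort <- simulate_cohort(cfg, seed = seed)
  n <- nrow(cohort)
  set.seed(seed + 101L)
  train_ids <- sort(sample.int(n, round(train_frac * n)))
  test_ids <- setdiff(seq_len(n), train_ids)

  say("extracting features for %d nights...", n)
  tabs <- purrr::map(seq_len(n), function(i) {
    rr <- clean_rr(cohort$rr[[i]])
    hyp <- cohort$hypnogram[[i]]
    w <- build_windows(rr, hyp, training = i %in% train_ids)
    extract_night(rr, w, features = features, hyp = hyp)
  })

  say("training staging model on %d nights...", length(train_ids))
  control <- stager_control(seed = seed)
  stager <- train_stager(bind_rows(tabs[train_ids]), control = control)

  say("staging %d test nights...", length(test_ids))
  staged <- purrr::map(seq_len(n), function(i) stage_night(stager, tabs[[i]])$hypnogram)
  pooled_pred <- hypnogram(unlist(purrr::map(staged[test_ids], "stage")))
  pooled_truth <- hypnogram(unlist(purrr::map(cohort$hypnogram[test_ids], "stage")))
  staging_eval <- evaluate_staging(pooled_pred, pooled_truth)
  per_night <- purrr::map_dfr(test_ids, function(i) {
    tibble(
      record_id = cohort$record_id[i],
      accuracy = mean(staged[[i]]$stage == cohort$hypnogram[[i]]$stage)
    )
  })

  say("training quality model...")
  qfeat <- bind_rows(purrr::map(staged, hypnogram_features))
  qmodel <- train_quality(
    qfeat[train_ids, , drop = FALSE], cohort$quality[train_ids],
    seed = seed
  )
  qpred <- predict_quality(qmodel, qfeat[test_ids, , drop = FALSE])
  recovery <- mean(qpred$label == cohort$quality[test_ids])

  structure(
    list(
      staging = staging_eval,
      per_night = per_night,
      quality_recovery = recovery,
      quality_model = qmodel,
      stager = stager,
      n_train = length(train_ids), n_test = length(test_ids),
      cohort = cohort[, c("record_id", "score", "quality")]
    ),
    class = "cohort_experiment"
  )
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat(sprintf(
    "<cohort_experiment> %d train / %d test nights\n  staging accuracy %.3f (macro F1 %.3f)\n  planted quality recovery %.3f\n",
    x$n_train, x$n_test, x$staging$accuracy, x$staging$macro_f1, x$quality_recovery
  ))
  invisible(x)
}

#' @rdname cohort_experiment
#' @param x A `cohort_experiment`.
#' @param ... Unused.
#' @export
glance.cohort_experiment <- function(x, ...) {
  tibble(
    staging_accuracy = x$staging$accuracy,
    staging_macro_f1 = x$staging$macro_f1,
    quality_recovery = x$quality_recovery,
    n_train = x$n_train, n_test = x$n_test
  )
}
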