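#' Plot a recognizer's detection curves
#'
#' Shows the standardized first principal component `F1` with its small- and
#' large-frame smoothings (`SF1`, `BF1`); epochs where `SF1` exceeds the
#' offset threshold are the recognizer's tags.
#'
#' @param curves From [principal_curves()].
#' @param rec The [recognizer()] (used for the offset and title).
#' @return A ggplot object.
#' @export
plot_principal_curves <- function(curves, rec) {
  long <- tidyr::pivot_longer(curves, c("F1", "SF1", "BF1"),
    names_to = "curve", values_to = "value"
  )
  thr <- tibble(
    k = rec$k,
    label = if (length(rec$k) == 2) c("BF1 + k1", "BF1 + k2") else "BF1 + k"
  )
  base <- curves
  p <- ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$curve)) +
    geom_line(linewidth = 0.3) +
    labs(
      x = "epoch", y = "standardized component",
      title = sprintf("%s recognizer curves", rec$stage)
    ) +
    theme_minimal()
  for (i in seq_len(nrow(thr))) {
    p <- p + geom_line(
      data = tibble(
        epoch = base$epoch, value = base$BF1 + thr$k[i],
        curve = thr$label[i]
      ),
      aes(x = .data$epoch, y = .data$value), linetype = 2, colour = "grey40"
    )
  }
  p
}

#' Plot per-stage evaluation metrics
#'
#' @param object A `staging_eval` from [evaluate_staging()].
#' @param ... Unused.
#' @return A ggplot object (sensitivity, specificity, Youden and F1 by
#'   stage).
#' @export
autoplot.staging_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_stage,
    c("sensitivity", "specificity", "youden", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot(long, aes(x = factor(.data$stage, levels = STAGES), y = .data$value)) +
    geom_point(size = 2) +
    facet_wrap(~metric) +
    labs(x = "stage", y = NULL, title = "Staging performance by stage") +
    theme_minimal()
}

#' Plot the overnight course of one feature against the hypnogram
#'
#' @param features A feature table from [extract_night()].
#' @param feature Column to plot.
#' @return A ggplot object.
#' @export
plot_feature_course <- function(features, feature = "HR") {
  stopifnot(feature %in% names(features))
  df <- tibble(
    hours = features$epoch * EPOCH_LEN / 3600,
    value = features[[feature]],
    stage = features$stage
  )
  ggplot(df, aes(x = .data$hours, y = .data$value)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    labs(x = "time (h)", y = feature, title = sprintf("Overnight course of %s", feature)) +
    theme_minimal()
}
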