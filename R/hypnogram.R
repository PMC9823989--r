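#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels over a night,
#' scored in contiguous 30-s epochs. Labels use the four-class alphabet
#' `W` (wake), `R` (REM), `L` (light sleep, N1+N2 collapsed) and `D` (deep
#' sleep, N3). Epochs are 0-based and half-open in time: epoch `i` covers
#' `[30*i, 30*(i+1))` seconds.
#'
#' @param stage Character vector of labels in `{W, R, L, D}` (or a vector
#'   mappable through `label_map`).
#' @param label_map Named character vector collapsing five-class AASM labels;
#'   defaults to `N1, N2 -> L` and `N3 -> D`, `REM -> R`.
#' @param source `"annotation"` or `"predicted"`.
#' @param record_id Identifier carried through downstream tables.
#'
#' @return A tibble of class `hypnogram` with columns `epoch` (0-based) and
#'   `stage`.
#' @examples
#' hypnogram(c("W", "N1", "N2", "N3", "REM"))
#' @export
hypnogram <- function(stage, label_map = default_label_map(),
                      source = c("annotation", "predicted"),
                      record_id = "record") {
  source <- match.arg(source)
  stage <- as.character(stage)
  if (length(stage) < 1) abort("a hypnogram needs at least one epoch.")
  mapped <- ifelse(stage %in% names(label_map), unname(label_map[stage]), stage)
  unknown <- setdiff(unique(mapped), STAGES)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown sleep-stage label(s): %s (expected W/R/L/D or a mapped five-class label).",
      paste(unknown, collapse = ", ")
    ))
  }
  out <- tibble(epoch = seq_along(mapped) - 1L, stage = mapped)
  attr(out, "record_id") <- record_id
  attr(out, "epoch_len") <- EPOCH_LEN
  attr(out, "source") <- source
  class(out) <- c("hypnogram", class(out))
  out
}

#' Default five-class to four-class label collapse
#'
#' N1 and N2 collapse to light sleep `L`, N3 to deep sleep `D`, REM to `R`.
#' @return A named character vector.
#' @export
default_label_map <- function() {
  c(W = "W", N1 = "L", N2 = "L", N3 = "D", REM = "R", R = "R", L = "L", D = "D")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stage, levels = STAGES))
  cat(sprintf(
    "<hypnogram '%s'> %d epochs (%.1f h), %s | W:%d R:%d L:%d D:%d\n",
    record_id(x), nrow(x), nrow(x) * EPOCH_LEN / 3600,
    attr(x, "source") %||% "annotation",
    tab[["W"]], tab[["R"]], tab[["L"]], tab[["D"]]
  ))
  NextMethod()
}

restore_hyp <- function(out, template, source = NULL) {
  attr(out, "record_id") <- record_id(template)
  attr(out, "epoch_len") <- EPOCH_LEN
  attr(out, "source") <- source %||% attr(template, "source") %||% "annotation"
  out$epoch <- seq_len(nrow(out)) - 1L
  if (!inherits(out, "hypnogram")) class(out) <- c("hypnogram", class(out))
  out
}

# run-length view of a hypnogram: one row per maximal bout
hyp_runs <- function(hyp) {
  r <- rle(hyp$stage)
  end <- cumsum(r$lengths)
  tibble(
    stage = r$values,
    start_epoch = c(0L, head(end, -1)),
    n_epochs = r$lengths
  )
}

#' Plot a hypnogram as the conventional staircase
#'
#' Stages are ordered top-to-bottom W, R, L, D as on a polysomnography report.
#'
#' @param object A `hypnogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypnogram <- function(object, ...) {
  df <- tibble(
    hours = object$epoch * EPOCH_LEN / 3600,
    stage = factor(object$stage, levels = rev(STAGES))
  )
  ggplot(df, aes(x = .data$hours, y = .data$stage, group = 1)) +
    geom_step(linewidth = 0.4) +
    labs(x = "time since record start (h)", y = NULL,
         title = sprintf("Hypnogram: %s", record_id(object))) +
    theme_minimal()
}
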