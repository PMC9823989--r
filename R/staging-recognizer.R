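#' Construct a sleep-stage recognizer
#'
#' A recognizer detects one stage from the relative position of two smoothed
#' versions of the first principal component of a small feature combination.
#' The night-level component `F1` is smoothed at a small frame (`SF1`, tracks
#' epoch-scale variation) and a large frame (`BF1`, tracks the sleep-cycle
#' scale); wake and REM are tagged where `SF1 > BF1 + k`, deep sleep where
#' `SF1 < BF1 + k`, and light sleep inside the band
#' `BF1 + k1 < SF1 < BF1 + k2`. Features whose overnight course runs opposite
#' to the majority (`SE`, `alpha2`) are negated before the PCA.
#'
#' @param stage One of `"W"`, `"R"`, `"L"`, `"D"`.
#' @param features Feature combination; defaults to the per-stage sets in
#'   [default_recognizer_features()].
#' @param flip Features negated before PCA (default: `SE`, `alpha2` when
#'   present).
#' @param small_frame,large_frame Odd Savitzky-Golay frame lengths in epochs
#'   (defaults 11 and 121).
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param k Offset in standardized component units (`k1`, `k2` with
#'   `k1 < k2` for the light-sleep band).
#' @param c_h,c_w Boundary-adjustment proportionality constants for the ramp
#'   height and width (see [adjust_boundaries()]).
#' @return A list of class `recognizer`.
#' @export
recognizer <- function(stage, features = default_recognizer_features()[[stage]],
                       flip = intersect(features, c("SE", "alpha2")),
                       small_frame = 11, large_frame = 121, sg_order = 2,
                       k = if (stage == "L") c(-0.5, 0.5) else 0,
                       c_h = 0.25, c_w = 0.5) {
  stage <- match.arg(stage, STAGES)
  direction <- switch(stage, W = "above", R = "above", L = "band", D = "below")
  if (small_frame >= large_frame) abort("small_frame must be below large_frame.")
  if (small_frame %% 2 == 0 || large_frame %% 2 == 0) abort("frame lengths must be odd.")
  if (direction == "band") {
    if (length(k) != 2 || k[1] >= k[2]) abort("light-sleep recognizer needs k1 < k2.")
  } else if (length(k) != 1) {
    abort("recognizer needs a single offset k.")
  }
  structure(
    list(
      stage = stage, features = features, flip = flip,
      small_frame = as.integer(small_frame), large_frame = as.integer(large_frame),
      sg_order = as.integer(sg_order), k = as.numeric(k),
      direction = direction, c_h = c_h, c_w = c_w
    ),
    class = "recognizer"
  )
}

#' @export
print.recognizer <- function(x, ...) {
  cat(sprintf(
    "<recognizer %s> features: %s | frames %d/%d | k = %s | %s\n",
    x$stage, paste(x$features, collapse = ", "), x$small_frame, x$large_frame,
    paste(signif(x$k, 3), collapse = ", "), x$direction
  ))
  invisible(x)
}

#' Default recognizer feature combinations
#'
#' The per-stage default combinations: wake uses `coRR, HR, resf, alpha2`;
#' REM adds `alpha1` and `G1`; light sleep uses `HR, resf, SE, alpha2, P1`;
#' deep sleep uses `resf, LF, alpha1, corr2`. These are the combinations an
#' exhaustive accuracy/Youden search over the candidate features settles on
#' for polysomnography-annotated training data; rerun
#' [search_feature_combinations()] to refit them for other cohorts.
#'
#' @return A named list of character vectors.
#' @export
default_recognizer_features <- function() {
  list(
    W = c("coRR", "HR", "resf", "alpha2"),
    R = c("coRR", "HR", "resf", "alpha1", "alpha2", "G1"),
    L = c("HR", "resf", "SE", "alpha2", "P1"),
    D = c("resf", "LF", "alpha1", "corr2")
  )
}

#' Principal-component curves of a night for one recognizer
#'
#' Builds the recognizer's detection curves from a night's feature table:
#' the flip-set features are negated, every column is z-scored within the
#' night, the first principal component is extracted (oriented so the first
#' listed feature loads positively) and standardized, then Savitzky-Golay
#' smoothed at the recognizer's two frame lengths.
#'
#' @param night_features Feature table of one night (one row per epoch,
#'   ordered), containing the recognizer's feature columns.
#' @param rec A [recognizer()].
#' @param max_missing Error when any feature column exceeds this missing
#'   fraction (default 0.5); remaining gaps are imputed by the night median.
#' @return A tibble with `epoch`, `F1`, `SF1`, `BF1`.
#' @export
principal_curves <- function(night_features, rec, max_missing = 0.5) {
  miss <- vapply(rec$features, function(f) {
    if (!f %in% names(night_features)) abort(sprintf("feature '%s' absent from table.", f))
    mean(is.na(night_features[[f]]))
  }, numeric(1))
  if (any(miss > max_missing)) {
    abort(sprintf(
      "feature(s) over %.0f%% missing: %s", 100 * max_missing,
      paste(names(miss)[miss > max_missing], collapse = ", ")
    ))
  }
  X <- vapply(rec$features, function(f) {
    x <- night_features[[f]]
    x[is.na(x)] <- median(x, na.rm = TRUE)
    if (f %in% rec$flip) x <- -x
    s <- sd(x)
    if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  }, numeric(nrow(night_features)))
  X <- matrix(X, nrow = nrow(night_features))

  if (ncol(X) == 1) {
    f1 <- X[, 1]
  } else {
    pc <- prcomp(X, center = FALSE, scale. = FALSE)
    load1 <- pc$rotation[, 1]
    anchor <- which(load1 != 0)[1]
    if (!is.na(anchor) && load1[anchor] < 0) load1 <- -load1
    f1 <- as.numeric(X %*% load1)
  }
  if (sd(f1) > 0) f1 <- (f1 - mean(f1)) / sd(f1)

  tibble(
    epoch = night_features$epoch %||% (seq_len(nrow(night_features)) - 1L),
    F1 = f1,
    SF1 = sg_smooth(f1, rec$small_frame, rec$sg_order),
    BF1 = sg_smooth(f1, rec$large_frame, rec$sg_order)
  )
}

# Savitzky-Golay smoothing tolerant of short series: the frame shrinks to the
# largest odd length not exceeding the series; frame 1 is the identity.
sg_smooth <- function(x, frame, order = 2) {
  n <- length(x)
  frame <- min(frame, if (n %% 2 == 1) n else n - 1L)
  if (frame <= 1) {
    return(x)
  }
  order <- min(order, frame - 1L)
  as.numeric(signal::sgolayfilt(x, p = order, n = frame))
}

#' Apply a recognizer's threshold criterion
#'
#' @param curves Curves from [principal_curves()].
#' @param rec The [recognizer()].
#' @param k Optional offset override.
#' @return A logical vector: does each epoch carry this recognizer's tag?
#'   Inequalities are strict, so `SF1 == BF1 + k` never tags.
#' @export
apply_recognizer <- function(curves, rec, k = rec$k) {
  d <- curves$SF1 - curves$BF1
  switch(rec$direction,
    above = d > k,
    below = d < k,
    band = d > k[1] & d < k[2]
  )
}

#' Variable-threshold boundary correction
#'
#' Epochs near a crossing of `SF1` and the offset threshold are the likeliest
#' misclassifications. For every excursion of `SF1` beyond the threshold
#' (minimum, up-crossing, maximum, down-crossing), the threshold is ramped on
#' the medial side of each crossing: ramp height `c_h * (H - L)` and ramp
#' width `c_w * (H - L) / |slope|` epochs, where `H` and `L` are the high and
#' low point on that side of the crossing and `slope` their mean slope. The
#' threshold is raised for the wake and REM recognizers and lowered for the
#' deep-sleep recognizer, shaving marginal epochs off the excursion edges.
#' Band (light-sleep) recognizers are returned unchanged. With `c_h = 0` the
#' tags are returned unchanged.
#'
#' @inheritParams apply_recognizer
#' @param tags Tags from [apply_recognizer()].
#' @return Corrected logical tags.
#' @export
adjust_boundaries <- function(curves, rec, tags, k = rec$k) {
  if (rec$direction == "band" || rec$c_h == 0) {
    return(tags)
  }
  d <- curves$SF1 - curves$BF1 - k
  if (rec$direction == "below") d <- -d
  n <- length(d)
  pos <- d > 0
  if (!any(pos) || all(pos)) {
    return(tags)
  }
  adj <- numeric(n) # threshold raise, in d units
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    s <- starts[j]
    e <- ends[j]
    i_max <- s - 1L + which.max(d[s:e])
    # rising side: low point on the preceding sub-threshold run
    if (j > 1) {
      ps <- starts[j - 1]
      pe <- ends[j - 1]
      i_min <- ps - 1L + which.min(d[ps:pe])
      adj_side(d, s, e, i_min, i_max, rec, from_start = TRUE) -> ramp
      adj[s:e] <- pmax(adj[s:e], ramp)
    }
    # falling side: low point on the following sub-threshold run
    if (j < length(r$values)) {
      ns <- starts[j + 1]
      ne <- ends[j + 1]
      i_min <- ns - 1L + which.min(d[ns:ne])
      adj_side(d, s, e, i_min, i_max, rec, from_start = FALSE) -> ramp
      adj[s:e] <- pmax(adj[s:e], ramp)
    }
  }
  out <- d > adj
  keep <- tags
  excur <- pos
  keep[excur] <- out[excur]
  keep
}

# linear ramp over one side of an excursion; returns the per-epoch threshold
# raise across the excursion run [s, e]
adj_side <- function(d, s, e, i_min, i_max, rec, from_start) {
  height_diff <- d[i_max] - d[i_min]
  span <- abs(i_max - i_min)
  if (height_diff <= 0 || span == 0) {
    return(numeric(e - s + 1L))
  }
  slope <- height_diff / span
  w <- rec$c_w * height_diff / slope # = c_w * span epochs
  h <- rec$c_h * height_diff
  idx <- s:e
  dist <- if (from_start) idx - s else e - idx
  ramp <- h * (1 - dist / w)
  pmax(ramp, 0)
}
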