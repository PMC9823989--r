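#' Recursive feature elimination with a linear SVM
#'
#' Repeatedly fits a linear-kernel SVM on standardized features, scores each
#' feature by its squared weight `w_j^2` in the primal hyperplane, and drops
#' the lowest-scoring feature until none remain. The elimination order (last
#' dropped = most important) is the ranking.
#'
#' @param x Data frame or matrix of features (missing values median-imputed).
#' @param y Binary labels (logical, or any two-level vector).
#' @param cost SVM cost parameter (default 1).
#' @return A tibble ranked by importance: `rank`, `feature`, `weight2` (the
#'   feature's squared weight in the iteration where it was dropped).
#' @export
svm_rfe <- function(x, y, cost = 1) {
  x <- as.data.frame(x)
  if (is.logical(y)) y <- ifelse(y, "pos", "neg")
  y <- factor(as.character(y))
  if (nlevels(y) != 2) abort("svm_rfe needs exactly two classes.")
  if (ncol(x) < 2) abort("svm_rfe needs at least two features.")
  X <- vapply(x, function(col) {
    col <- as.numeric(col)
    col[is.na(col)] <- median(col, na.rm = TRUE)
    col[is.na(col)] <- 0
    s <- sd(col)
    if (s > 0) (col - mean(col)) / s else col * 0
  }, numeric(nrow(x)))
  colnames(X) <- names(x)

  remaining <- colnames(X)
  dropped <- character(0)
  dropped_w2 <- numeric(0)
  while (length(remaining) > 1) {
    fit <- e1071::svm(X[, remaining, drop = FALSE], y,
      kernel = "linear", cost = cost, scale = FALSE
    )
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    w2 <- w^2
    worst <- which.min(w2)
    dropped <- c(dropped, remaining[worst])
    dropped_w2 <- c(dropped_w2, w2[worst])
    remaining <- remaining[-worst]
  }
  order_best_first <- c(remaining, rev(dropped))
  tibble(
    rank = seq_along(order_best_first),
    feature = order_best_first,
    weight2 = c(NA_real_, rev(dropped_w2))
  )
}
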