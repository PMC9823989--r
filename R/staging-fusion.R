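# ---- calibrated binary margin models -------------------------------------
#
# Each binary classifier is an SVM whose support vectors, kernel parameters
# and Platt sigmoid are extracted into a plain list at fit time, so models
# serialize to text and prediction does not depend on the fitting object.

#' Fit Platt's sigmoid to classifier margins
#'
#' Maps decision values `f` to probabilities `1 / (1 + exp(A f + B))` by
#' minimizing the cross-entropy against Platt's regularized targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, which keeps the fit finite even for
#' separable data.
#'
#' @param f Numeric decision values.
#' @param y Logical: is each case the positive class?
#' @return Named numeric `c(A, B)`.
#' @export
platt_fit <- function(f, y) {
  stopifnot(length(f) == length(y), any(y), any(!y))
  np <- sum(y)
  nn <- sum(!y)
  t_ <- ifelse(y, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- pmin(pmax(par[1] * f + par[2], -30), 30)
    p <- 1 / (1 + exp(z))
    -sum(t_ * log(p) + (1 - t_) * log(1 - p))
  }
  fit <- optim(c(A = -1, B = log((nn + 1) / (np + 1))), nll, method = "BFGS")
  setNames(fit$par, c("A", "B"))
}

#' @rdname platt_fit
#' @param platt Coefficients from `platt_fit()`.
#' @return `platt_prob()` returns calibrated probabilities in `(0, 1)`.
#' @export
platt_prob <- function(f, platt) {
  1 / (1 + exp(pmin(pmax(platt[["A"]] * f + platt[["B"]], -30), 30)))
}

# median-impute then standardize with stored statistics
bc_design <- function(bc, data) {
  X <- vapply(bc$features, function(f) {
    x <- data[[f]]
    if (is.null(x)) abort(sprintf("classifier feature '%s' missing from data.", f))
    x[is.na(x)] <- bc$impute[[f]]
    (x - bc$center[[f]]) / bc$scale[[f]]
  }, numeric(nrow(data)))
  matrix(X, nrow = nrow(data))
}

svm_kernel <- function(U, V, kernel, gamma, coef0 = 0, degree = 3) {
  if (kernel == "linear") {
    return(U %*% t(V))
  }
  if (kernel == "polynomial") {
    return((gamma * (U %*% t(V)) + coef0)^degree)
  }
  # radial
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * U %*% t(V)
  exp(-gamma * pmax(d2, 0))
}

# fit one calibrated binary classifier (positive class `pos`)
fit_binary <- function(data, y, pos, neg, features,
                       kernel = "radial", degree = 3,
                       cost_grid = c(1, 10), gamma_mult = c(0.5, 2),
                       max_rows = 3000, cv_folds = 3, seed = 1) {
  keep <- y %in% c(pos, neg)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) abort("both classes must be present.")
  bc <- list(
    pos = pos, neg = neg, features = features,
    kernel = kernel, degree = degree
  )
  bc$impute <- lapply(features, function(f) {
    m <- median(data[[f]], na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  names(bc$impute) <- features
  raw <- vapply(features, function(f) {
    x <- data[[f]]
    x[is.na(x)] <- bc$impute[[f]]
    x
  }, numeric(nrow(data)))
  raw <- matrix(raw, nrow = nrow(data))
  bc$center <- setNames(as.list(colMeans(raw)), features)
  scl <- apply(raw, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  bc$scale <- setNames(as.list(scl), features)
  X <- sweep(sweep(raw, 2, unlist(bc$center)), 2, unlist(bc$scale), "/")

  set.seed(seed)
  if (nrow(X) > max_rows) {
    idx <- stratified_sample(y, max_rows)
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
  }
  yf <- factor(y == pos, levels = c(TRUE, FALSE))

  # small inner grid search for cost / gamma
  p <- ncol(X)
  coef0 <- if (kernel == "polynomial") 1 else 0
  gammas <- if (kernel == "linear") 1 / p else gamma_mult / p
  grid <- expand.grid(cost = cost_grid, gamma = gammas)
  if (nrow(grid) > 1 && nrow(X) >= 20) {
    folds <- sample(rep_len(seq_len(cv_folds), nrow(X)))
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(seq_len(cv_folds), function(fold) {
        tr <- folds != fold
        fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr],
          kernel = kernel, degree = degree, cost = grid$cost[g],
          gamma = grid$gamma[g], coef0 = coef0, scale = FALSE
        )
        mean(predict(fit, X[!tr, , drop = FALSE]) == yf[!tr])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- grid[which.max(cv_acc), ]
  } else {
    best <- grid[1, ]
  }

  fit <- e1071::svm(X, yf,
    kernel = kernel, degree = degree,
    cost = best$cost, gamma = best$gamma, coef0 = coef0, scale = FALSE
  )
  bc$gamma <- best$gamma
  bc$cost <- best$cost
  bc$coef0 <- coef0
  bc$sv <- unname(as.matrix(fit$SV))
  bc$sv_coefs <- as.numeric(fit$coefs)
  bc$rho <- fit$rho
  # orient margins so positive decision values favour the positive class
  dv <- bc_raw_decision(bc, X)
  bc$flip <- if (mean(dv[yf == "TRUE"]) < mean(dv[yf == "FALSE"])) -1 else 1

  # Platt sigmoid on cross-validated margins
  folds <- sample(rep_len(seq_len(cv_folds), nrow(X)))
  cv_dv <- rep(NA_real_, nrow(X))
  for (fold in seq_len(cv_folds)) {
    tr <- folds != fold
    if (length(unique(yf[tr])) < 2) next
    f2 <- e1071::svm(X[tr, , drop = FALSE], yf[tr],
      kernel = kernel, degree = degree,
      cost = best$cost, gamma = best$gamma, coef0 = coef0, scale = FALSE
    )
    tmp <- list(
      sv = unname(as.matrix(f2$SV)), sv_coefs = as.numeric(f2$coefs),
      rho = f2$rho, kernel = kernel, gamma = best$gamma,
      coef0 = coef0, degree = degree
    )
    d2 <- bc_raw_decision(tmp, X[!tr, , drop = FALSE])
    # orient fold margins so the positive class sits on the positive side
    yo <- yf[!tr] == "TRUE"
    if (any(yo) && any(!yo) && mean(d2[yo]) < mean(d2[!yo])) d2 <- -d2
    cv_dv[!tr] <- d2
  }
  ok <- !is.na(cv_dv)
  bc$platt <- if (sum(ok) > 10 && length(unique(yf[ok])) == 2) {
    platt_fit(cv_dv[ok], yf[ok] == "TRUE")
  } else {
    platt_fit(bc$flip * dv, yf == "TRUE")
  }
  structure(bc, class = "binary_classifier")
}

bc_raw_decision <- function(bc, X) {
  K <- svm_kernel(X, bc$sv, bc$kernel, bc$gamma, bc$coef0, bc$degree)
  as.numeric(K %*% bc$sv_coefs) - bc$rho
}

# decision values (oriented) and calibrated probability of the positive class
predict_binary <- function(bc, data) {
  X <- bc_design(bc, data)
  dv <- bc$flip * bc_raw_decision(bc, X)
  tibble(decision = dv, prob = platt_prob(dv, bc$platt))
}

stratified_sample <- function(y, size) {
  idx <- split(seq_along(y), y)
  per <- ceiling(size * lengths(idx) / length(y))
  out <- unlist(purrr::map2(idx, per, function(i, k) {
    if (length(i) <= k) i else sample(i, k)
  }))
  sort(out[seq_len(min(length(out), size))])
}
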