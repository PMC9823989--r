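# A degenerate calibrated classifier returning a fixed probability for every
# input row: decision value 0, Platt intercept tuned to the target.
stub_bc <- function(p) {
  structure(
    list(
      pos = "pos", neg = "neg", features = "x1",
      kernel = "linear", degree = 3,
      impute = list(x1 = 0), center = list(x1 = 0), scale = list(x1 = 1),
      gamma = 1, cost = 1, coef0 = 0,
      sv = matrix(0, 1, 1), sv_coefs = 0, rho = 0, flip = 1,
      platt = c(A = -1, B = log(1 / p - 1))
    ),
    class = "binary_classifier"
  )
}

# fusion model with fixed P(WR), P(W|WR), P(L|N)
stub_fusion <- function(p_wr, p_w, p_l) {
  structure(
    list(wrn = stub_bc(p_wr), wr = stub_bc(p_w), ld = stub_bc(p_l)),
    class = "fusion_model"
  )
}

# linearly separable two-class feature table
separable_data <- function(n_per_class, shift = 3, p = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per_class * p), ncol = p),
    matrix(rnorm(n_per_class * p, mean = shift), ncol = p)
  )
  colnames(X) <- paste0("f", seq_len(p))
  list(
    data = tibble::as_tibble(as.data.frame(X)),
    y = rep(c("A", "B"), each = n_per_class)
  )
}
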