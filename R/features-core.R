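# Internal plain-vector feature kernels. The exported hrv_* wrappers and
# extract_night() both call these; the wrappers add the tibble interface,
# extract_night() fills a preallocated matrix for speed.

ft_time <- function(iv, d, min_beats = 10) {
  out <- c(HR = NA_real_, SDNN = NA_real_, RMSSD = NA_real_, SDSD = NA_real_, PNN50 = NA_real_)
  if (length(iv) < min_beats) {
    return(out)
  }
  out[["HR"]] <- 60000 / mean(iv)
  out[["SDNN"]] <- sd(iv)
  if (length(d) > 0) {
    out[["RMSSD"]] <- sqrt(mean(d^2))
    out[["PNN50"]] <- 100 * mean(abs(d) > 50)
  }
  if (length(d) > 1) out[["SDSD"]] <- sd(d)
  out
}

# Dispersion about (SD1) and along (SD2) the line of identity of the lag-1
# Poincare plot, as population second moments, so SD1 = RMSSD/sqrt(2) exactly.
ft_poincare <- function(iv, d, min_beats = 10) {
  out <- c(SD1 = NA_real_, SD2 = NA_real_)
  if (length(iv) < min_beats || length(d) < 2) {
    return(out)
  }
  sd1_sq <- mean(d^2) / 2
  var_pop <- mean((iv - mean(iv))^2)
  out[["SD1"]] <- sqrt(sd1_sq)
  out[["SD2"]] <- sqrt(max(2 * var_pop - sd1_sq, 0))
  out
}

ft_irrev <- function(iv, d, min_beats = 3) {
  out <- c(P1 = NA_real_, G1 = NA_real_)
  if (length(iv) < min_beats) {
    return(out)
  }
  pos <- d[d > 0]
  neg <- d[d < 0]
  if (length(pos) + length(neg) == 0) {
    return(out)
  }
  out[["P1"]] <- 100 * length(neg) / (length(neg) + length(pos))
  out[["G1"]] <- 100 * sum(pos^2) / (sum(pos^2) + sum(neg^2))
  out
}

ft_corr2 <- function(iv, min_beats = 4) {
  n <- length(iv)
  if (n < min_beats) {
    return(c(corr2 = NA_real_))
  }
  s1 <- iv[1:(n - 2)]
  s2 <- iv[3:n]
  if (sd(s1) == 0 || sd(s2) == 0) {
    return(c(corr2 = NA_real_))
  }
  c(corr2 = cor(s1, s2))
}

ft_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2) {
    return(NA_real_)
  }
  if (sd(x) == 0) {
    return(0)
  }
  nt <- n - m
  i1 <- seq_len(nt)
  dm <- abs(outer(x[i1], x[i1], "-"))
  for (k in seq_len(m - 1)) {
    dm <- pmax(dm, abs(outer(x[i1 + k], x[i1 + k], "-")))
  }
  dm1 <- pmax(dm, abs(outer(x[i1 + m], x[i1 + m], "-")))
  ut <- upper.tri(dm)
  B <- sum(dm[ut] <= r)
  A <- sum(dm1[ut] <= r)
  if (B == 0 || A == 0) {
    return(NA_real_)
  }
  -log(A / B)
}

ft_fuzzen <- function(x, m = 2, r = 0.2 * sd(x), p = 2) {
  n <- length(x)
  if (n < m + 2) {
    return(NA_real_)
  }
  if (sd(x) == 0 || r == 0) {
    return(0)
  }
  phi <- function(mm) {
    nt <- n - m
    emb <- vapply(seq_len(mm), function(k) x[seq_len(nt) + k - 1L], numeric(nt))
    emb <- emb - rowMeans(emb)
    dmat <- abs(outer(emb[, 1], emb[, 1], "-"))
    if (mm > 1) {
      for (k in 2:mm) dmat <- pmax(dmat, abs(outer(emb[, k], emb[, k], "-")))
    }
    mu <- exp(-(dmat / r)^p)
    (sum(mu) - nt) / (nt * (nt - 1))
  }
  log(phi(m) / phi(m + 1))
}

# spline-resampled tachogram from valid beat vectors
make_tachogram <- function(bt, iv, fs = 4, min_span = 60, min_beats = 10) {
  if (length(bt) < min_beats) {
    return(NULL)
  }
  span <- bt[length(bt)] - bt[1]
  if (span < min_span) {
    return(NULL)
  }
  xout <- seq(bt[1], bt[length(bt)], by = 1 / fs)
  list(y = spline(bt, iv, xout = xout, method = "fmm")$y, fs = fs)
}

welch_core <- function(x, fs, seg_len = 512, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  norm <- fs * sum(w^2)
  nfreq <- floor(seg_len / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg)[seq_len(nfreq)])^2 / norm
    inner <- 2:(nfreq - if (seg_len %% 2 == 0) 1L else 0L)
    p[inner] <- 2 * p[inner]
    acc <- acc + p
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / seg_len, psd = acc / length(starts))
}

band_power_core <- function(sp, lo, hi) {
  sel <- sp$freq > lo & sp$freq <= hi
  if (!any(sel)) {
    return(0)
  }
  sum(sp$psd[sel]) * (sp$freq[2] - sp$freq[1])
}

ft_bands <- function(sp) {
  out <- c(
    VLF = NA_real_, LF = NA_real_, HF = NA_real_,
    LF_HF = NA_real_, LFn = NA_real_, HFn = NA_real_
  )
  if (is.null(sp)) {
    return(out)
  }
  vlf <- band_power_core(sp, 0.0033, 0.04)
  lf <- band_power_core(sp, 0.04, 0.15)
  hf <- band_power_core(sp, 0.15, 0.4)
  out[["VLF"]] <- vlf
  out[["LF"]] <- lf
  out[["HF"]] <- hf
  if (hf > 0) out[["LF_HF"]] <- lf / hf
  if (lf + hf > 0) {
    out[["LFn"]] <- lf / (lf + hf)
    out[["HFn"]] <- hf / (lf + hf)
  }
  out
}

dominant_freq_core <- function(y, fs, lo = 0.15, hi = 0.5, sp = NULL) {
  if (is.null(sp)) sp <- welch_core(y, fs, seg_len = min(length(y), 128 * fs))
  sel <- sp$freq >= lo & sp$freq <= hi
  if (!any(sel)) {
    return(NA_real_)
  }
  sp$freq[sel][which.max(sp$psd[sel])]
}

ft_resp <- function(tg, iv, sp = NULL) {
  out <- c(coRR = NA_real_, resf = NA_real_, strf = NA_real_)
  if (!is.null(tg)) {
    out[["resf"]] <- dominant_freq_core(tg$y, tg$fs, sp = sp)
    sub_len <- 90 * tg$fs
    if (length(tg$y) >= sub_len) {
      offsets <- round(seq(0, length(tg$y) - sub_len, length.out = 5))
      sub_resf <- vapply(offsets, function(o) {
        dominant_freq_core(tg$y[(o + 1):(o + sub_len)], tg$fs)
      }, numeric(1))
      out[["strf"]] <- sd(sub_resf, na.rm = TRUE)
    }
  }
  if (length(iv) >= 3 && sd(iv) > 0) {
    sm <- ma3(ma3(iv))
    if (sd(sm) > 0) out[["coRR"]] <- cor(iv, sm)
  }
  out
}

ft_dfa <- function(iv, scales = dfa_scales(), min_beats = 100) {
  out <- c(alpha1 = NA_real_, alpha2 = NA_real_)
  if (length(iv) < min_beats || sd(iv) == 0) {
    return(out)
  }
  scales <- scales[scales <= floor(length(iv) / 2)]
  if (length(scales) < 4) {
    return(out)
  }
  y <- cumsum(iv - mean(iv))
  fn <- vapply(scales, function(n) {
    nw <- floor(length(y) / n)
    m <- matrix(y[seq_len(nw * n)], nrow = n)
    tt <- seq_len(n)
    X <- cbind(1, tt)
    resid <- m - X %*% solve(crossprod(X), crossprod(X, m))
    sqrt(mean(resid^2))
  }, numeric(1))
  lx <- log10(scales)
  ly <- log10(fn)
  # least-squares slope/intercept without lm() overhead
  mx <- mean(lx)
  my <- mean(ly)
  slope <- sum((lx - mx) * (ly - my)) / sum((lx - mx)^2)
  out[["alpha1"]] <- slope
  out[["alpha2"]] <- my - slope * mx
  out
}
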