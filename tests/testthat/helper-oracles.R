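# Independent brute-force oracles used to validate the package
# implementations on small inputs. These deliberately use naive loops and
# different algorithms from the package code paths.

# Sample entropy by explicit double loop over template pairs.
oracle_sampen <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  tol <- r_frac * sqrt(mean((x - mean(x))^2))
  nt <- n - m
  a <- 0L
  b <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in seq(i + 1L, nt)) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= tol) {
        b <- b + 1L
        d1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (d1 <= tol) a <- a + 1L
      }
    }
  }
  if (a == 0L || b == 0L) return(NA_real_)
  -log(a / b)
}

# Approximate entropy by explicit loops, self-matches included.
oracle_apen <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  tol <- r_frac * sqrt(mean((x - mean(x))^2))
  phi <- function(mm) {
    nt <- n - mm + 1L
    ci <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= tol) {
          cnt <- cnt + 1L
        }
      }
      ci[i] <- cnt / nt
    }
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

# Recurrence quantification by explicit matrix construction and diagonal
# scanning (both triangles, line of identity excluded).
oracle_rqa <- function(x, m = 10L, tau = 1L, lmin = 2L,
                       r_factor = sqrt(m)) {
  n <- length(x) - (m - 1L) * tau
  emb <- t(sapply(seq_len(n), function(i) x[i + (seq_len(m) - 1L) * tau]))
  tol <- r_factor * sqrt(mean((x - mean(x))^2))
  rec <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rec[i, j] <- sqrt(sum((emb[i, ] - emb[j, ])^2)) <= tol
    }
  }
  lens <- integer(0)
  off_pts <- 0L
  for (k in seq_len(n - 1L)) {
    v <- rec[cbind(seq_len(n - k), seq_len(n - k) + k)]
    off_pts <- off_pts + sum(v)
    run <- 0L
    for (val in c(v, FALSE)) {
      if (val) {
        run <- run + 1L
      } else {
        if (run > 0L) lens <- c(lens, run)
        run <- 0L
      }
    }
  }
  lines_ <- lens[lens >= lmin]
  p <- table(lines_) / length(lines_)
  list(
    REC = 100 * mean(rec),
    RPadet = if (off_pts > 0L) 100 * sum(lines_) / off_pts else NA_real_,
    RPlmean = if (length(lines_)) mean(lines_) else NA_real_,
    RPlmax = if (length(lines_)) max(lines_) else NA_real_,
    ShanEn = if (length(lines_)) -sum(p * log(p)) else NA_real_
  )
}

# Exact two-sided Wilcoxon signed-rank p-value via the generating-function
# convolution of the rank distribution (a different algorithm from the
# package's subset enumeration).
oracle_wilcoxon_exact <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  # distribution of W+ over all sign assignments by polynomial convolution
  # on a half-unit lattice (ranks can be half-integers under ties)
  lattice <- round(2 * r)
  coefs <- 1
  for (rk in lattice) {
    shifted <- c(rep(0, rk), coefs)
    coefs <- c(coefs, rep(0, rk)) + shifted
  }
  support <- (seq_along(coefs) - 1L) / 2
  probs <- coefs / sum(coefs)
  p_lo <- sum(probs[support <= w + 1e-9])
  p_hi <- sum(probs[support >= w - 1e-9])
  min(1, 2 * min(p_lo, p_hi))
}

# Spearman rho: rank then product-moment correlation, from scratch.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# AUC by explicit pair counting (ties count 1/2).
oracle_auc <- function(truth, score) {
  pos <- score[truth == "stress"]
  neg <- score[truth != "stress"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Periodogram band power of an evenly resampled, linearly detrended
# tachogram (ms^2): an FFT-based cross-check of the AR band powers.
oracle_periodogram_band <- function(nn_ms, time_ms, fs, lo, hi) {
  t_s <- time_ms / 1000
  grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / fs)
  y <- spline(t_s, nn_ms, xout = grid)$y
  y <- residuals(lm(y ~ seq_along(y)))
  n <- length(y)
  spec <- Mod(fft(y))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq > 0 & freq <= fs / 2
  # one-sided PSD, power per Hz
  psd <- 2 * spec[half] / fs
  sum(psd[freq[half] >= lo & freq[half] <= hi]) * fs / n
}

# Small deterministic RR tibble builder for tests.
make_rr <- function(rr_ms, label = "N", subject = "t01", condition = "rest") {
  tibble::tibble(
    subject = subject,
    condition = condition,
    time_ms = cumsum(rr_ms),
    rr_ms = rr_ms,
    label = rep_len(label, length(rr_ms))
  )
}
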