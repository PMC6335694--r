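# Non-linear HRV features: sample/approximate entropy, detrended
# fluctuation analysis, Grassberger-Procaccia correlation dimension and
# recurrence quantification.

# Delay embedding: rows are the (n - (m-1)*tau) state vectors.
embed_delay <- function(x, m, tau = 1L) {
  n <- length(x) - (m - 1L) * tau
  if (n < 1L) return(NULL)
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, `+`)
  matrix(x[idx], nrow = n, ncol = m)
}

# Chebyshev (max-norm) distance matrix between embedded vectors.
cheb_dist <- function(emb) {
  n <- nrow(emb)
  d <- matrix(0, n, n)
  for (k in seq_len(ncol(emb))) {
    d <- pmax(d, abs(outer(emb[, k], emb[, k], `-`)))
  }
  d
}

eucl_dist <- function(emb) {
  as.matrix(stats::dist(emb))
}

#' Sample entropy of an NN excerpt
#'
#' `SampEn = -log(A / B)` where `B` counts pairs of templates of length `m`
#' within Chebyshev distance `r` of each other, and `A` the corresponding
#' pairs of length `m + 1`; self-matches are excluded. Both counts use
#' templates starting at positions `1 .. N - m` so the two are comparable.
#'
#' @inheritParams time_features
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the excerpt's population SD
#'   (default 0.2).
#' @return Sample entropy in nats, or `NA` if no template pairs match.
#' @export
sample_entropy <- function(nn, m = 2L, r = 0.2) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < m + 2L) return(NA_real_)
  tol <- r * pop_sd(x)
  emb1 <- embed_delay(x, m + 1L)       # N - m templates of length m+1
  embm <- embed_delay(x, m)[seq_len(nrow(emb1)), , drop = FALSE]
  dm <- cheb_dist(embm)
  d1 <- cheb_dist(emb1)
  b <- sum(dm[upper.tri(dm)] <= tol)
  a <- sum(d1[upper.tri(d1)] <= tol)
  if (a == 0L || b == 0L) return(NA_real_)
  -log(a / b)
}

#' Approximate entropy of an NN excerpt
#'
#' `ApEn = Phi_m(r) - Phi_{m+1}(r)` with `Phi_m` the mean log fraction of
#' templates within tolerance, self-matches included (the standard
#' definition, which makes ApEn biased but always defined).
#'
#' @inheritParams sample_entropy
#' @return Approximate entropy in nats.
#' @export
approximate_entropy <- function(nn, m = 2L, r = 0.2) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < m + 2L) return(NA_real_)
  tol <- r * pop_sd(x)
  phi <- function(mm) {
    emb <- embed_delay(x, mm)
    d <- cheb_dist(emb)
    ci <- rowMeans(d <= tol)   # self-match included
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

#' Detrended fluctuation analysis exponents
#'
#' DFA on the integrated, mean-centred NN series with linear detrending in
#' non-overlapping boxes: `dfa1` is the least-squares slope of
#' `log F(n) ~ log n` over short box sizes (4-16 beats by default) and
#' `dfa2` over long box sizes (16-64 beats). Raw linear-detrend DFA
#' over-estimates the exponent at small boxes (uncorrelated noise scales
#' with an effective slope near 0.58, not 0.5, over boxes 4-16), so each
#' `F(n)` is normalised by the analytic white-noise expectation for that
#' box size (finite-size correction), which calibrates the white-noise
#' exponent to 0.5 without affecting the ordering of signals. `dfa2` is
#' `NA` when fewer than three long box sizes fit into the excerpt.
#'
#' @inheritParams time_features
#' @param short_range,long_range Two-element integer vectors giving the box
#'   ranges (beats) for the two exponents.
#' @return One-row tibble with `dfa1` and `dfa2`.
#' @export
dfa <- function(nn, short_range = c(4L, 16L), long_range = c(16L, 64L)) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < 2L * short_range[1L]) return(tibble(dfa1 = NA_real_, dfa2 = NA_real_))
  y <- cumsum(x - mean(x))
  fluct <- function(box) {
    n_box <- floor(n / box)
    if (n_box < 1L) return(NA_real_)
    ym <- matrix(y[seq_len(n_box * box)], nrow = box)
    tt <- seq_len(box)
    xm <- cbind(1, tt)
    # per-box linear detrend via one shared projection
    hat <- xm %*% solve(crossprod(xm), t(xm))
    res <- ym - hat %*% ym
    # finite-size correction: scale by the exact white-noise expectation
    # of the mean squared residual in a box of this size, relative to the
    # large-box asymptote box/15
    sqrt(mean(res^2) * (box / 15) / dfa_wn_expectation(box))
  }
  slope_over <- function(range) {
    sizes <- seq(range[1L], range[2L])
    sizes <- sizes[floor(n / sizes) >= 1L]
    f <- vapply(sizes, fluct, numeric(1L))
    ok <- is.finite(f) & f > 0
    if (sum(ok) < 3L) return(NA_real_)
    unname(coef(lm(log(f[ok]) ~ log(sizes[ok])))[2L])
  }
  tibble(dfa1 = slope_over(short_range), dfa2 = slope_over(long_range))
}

# Exact E[mean squared linear-detrend residual] of an integrated
# unit-variance white noise within one box: tr((I - H) C) / box with
# C_ij = min(i, j). Cached per box size.
dfa_wn_expectation <- local({
  cache <- new.env(parent = emptyenv())
  function(box) {
    key <- as.character(box)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tt <- seq_len(box)
    xm <- cbind(1, tt)
    hat <- xm %*% solve(crossprod(xm), t(xm))
    cc <- outer(tt, tt, pmin)
    val <- sum(diag((diag(box) - hat) %*% cc)) / box
    cache[[key]] <- val
    val
  }
})

#' Correlation dimension (Grassberger-Procaccia D2)
#'
#' Estimates D2 as the slope of `log C(r)` versus `log r`, where `C(r)` is
#' the fraction of pairs of delay-embedded points (dimension `m`, delay 1,
#' Euclidean norm) closer than `r`. The scaling region is selected
#' automatically: among sliding windows on a log-spaced `r` grid restricted
#' to the unsaturated part of the correlation sum (`C(r) <= 0.5`), the
#' window with the best linear fit is used.
#'
#' @inheritParams time_features
#' @param m Embedding dimension (default 10).
#' @return The D2 estimate, or `NA` when the correlation sum is degenerate
#'   (e.g. a constant series) or no linear region is found.
#' @export
correlation_dimension <- function(nn, m = 10L) {
  x <- nn_intervals(nn)
  emb <- embed_delay(x, m)
  if (is.null(emb) || nrow(emb) < 20L) return(NA_real_)
  d <- stats::dist(emb)
  d <- d[d > 0]
  if (length(d) < 100L) return(NA_real_)
  r_lo <- as.numeric(quantile(d, 0.005))
  r_hi <- as.numeric(quantile(d, 0.75))
  if (!is.finite(r_lo) || r_lo <= 0 || r_hi <= r_lo) return(NA_real_)
  r_grid <- exp(seq(log(r_lo), log(r_hi), length.out = 30L))
  cr <- vapply(r_grid, function(r) mean(d <= r), numeric(1L))
  keep <- cr > 0 & cr <= 0.5
  lr <- log(r_grid[keep])
  lc <- log(cr[keep])
  win <- 10L
  if (length(lr) < win) return(NA_real_)
  best <- NULL
  for (i in seq_len(length(lr) - win + 1L)) {
    xs <- lr[i:(i + win - 1L)]
    ys <- lc[i:(i + win - 1L)]
    if (pop_sd(ys) < 1e-12) next
    fit <- lm(ys ~ xs)
    r2 <- summary(fit)$r.squared
    sl <- unname(coef(fit)[2L])
    if (sl <= 0.05) next
    if (is.null(best) || r2 > best$r2) best <- list(r2 = r2, slope = sl)
  }
  if (is.null(best)) return(NA_real_)
  best$slope
}

#' Recurrence quantification analysis
#'
#' Builds the recurrence matrix `R(i, j) = [dist(X_i, X_j) <= r]` over
#' delay-embedded state vectors (Euclidean norm) and quantifies its
#' diagonal-line structure. The line of identity is excluded from all
#' diagonal statistics.
#'
#' @inheritParams time_features
#' @param m Embedding dimension (default 10).
#' @param tau Embedding delay in beats (default 1).
#' @param lmin Minimum diagonal line length counted as a line (default 2).
#' @param r_factor Recurrence threshold as a multiple of the excerpt SD
#'   (default `sqrt(m)`).
#' @param shanen_base `"nats"` or `"bits"` for the line-length entropy.
#' @return One-row tibble: `REC` (% recurrent points), `RPadet`
#'   (determinism, % of off-diagonal recurrent points on lines of length
#'   `>= lmin`), `RPlmean` and `RPlmax` (mean/max line length, beats) and
#'   `ShanEn` (Shannon entropy of the line-length distribution). Line
#'   statistics are `NA` when no diagonal line exists.
#' @export
rqa <- function(nn, m = 10L, tau = 1L, lmin = 2L, r_factor = sqrt(m),
                shanen_base = c("nats", "bits")) {
  shanen_base <- match.arg(shanen_base)
  x <- nn_intervals(nn)
  emb <- embed_delay(x, m, tau)
  empty <- tibble(RPlmean = NA_real_, RPlmax = NA_real_, REC = NA_real_,
                  RPadet = NA_real_, ShanEn = NA_real_)
  if (is.null(emb) || nrow(emb) < lmin + 1L) return(empty)
  r <- r_factor * pop_sd(x)
  d <- eucl_dist(emb)
  rec <- d <= r
  n <- nrow(rec)
  out <- empty
  out$REC <- 100 * mean(rec)
  # diagonal line lengths in the upper triangle (doubles to the lower by
  # symmetry; ratios and the length distribution are unaffected)
  lens <- integer(0)
  off_diag_points <- 0L
  for (k in seq_len(n - 1L)) {
    diag_vals <- rec[cbind(seq_len(n - k), seq_len(n - k) + k)]
    off_diag_points <- off_diag_points + sum(diag_vals)
    rl <- rle(diag_vals)
    lens <- c(lens, rl$lengths[rl$values])
  }
  lines_ <- lens[lens >= lmin]
  if (off_diag_points > 0L) {
    out$RPadet <- 100 * sum(lines_) / off_diag_points
  }
  if (length(lines_) > 0L) {
    out$RPlmean <- mean(lines_)
    out$RPlmax <- as.numeric(max(lines_))
    p <- table(lines_) / length(lines_)
    h <- -sum(p * log(p))
    out$ShanEn <- if (shanen_base == "bits") h / log(2) else h
  }
  out
}
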