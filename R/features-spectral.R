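# Autoregressive spectral estimation of the tachogram. The NN series is
# resampled on an even time grid (cubic spline), linearly detrended, and an
# AR model is fitted by Burg's method; band powers are numerical integrals
# of the one-sided AR power spectral density.

#' Autoregressive power spectral density of an NN tachogram
#'
#' Resamples the tachogram at `fs` Hz with cubic-spline interpolation,
#' removes a linear trend, fits an AR model of order `order` by Burg's
#' method and evaluates the one-sided PSD (ms^2/Hz) on a frequency grid.
#' The grid is refined around the AR pole frequencies so that the very
#' narrow peaks produced by almost-periodic tachograms integrate accurately.
#'
#' @param nn NN tibble (columns `time_ms`, `nn_ms`) or numeric vector of NN
#'   intervals in ms (beat times then taken as their cumulative sum).
#' @param order AR model order (default 16).
#' @param fs Resampling rate in Hz (default 4).
#' @return A tibble with columns `freq` (Hz) and `psd` (ms^2/Hz), class
#'   `"hrv_psd"`, carrying the resampled-signal variance
#'   (`attr(, "variance")`), the innovation variance, the AR coefficients
#'   and `fs` as attributes. `NULL` if fewer than `order + 1` resampled
#'   points are available.
#' @examples
#' nn <- derive_nn(generate_rr_series(a_hf = 40, seed = 2)) |> clip_nn()
#' psd <- ar_psd(nn)
#' band_powers(psd, excerpt_length_s = 300)
#' @export
ar_psd <- function(nn, order = 16L, fs = 4) {
  x <- nn_intervals(nn)
  t_s <- nn_times(nn) / 1000
  grid <- seq(t_s[1L], t_s[length(t_s)], by = 1 / fs)
  if (length(grid) < order + 1L) return(NULL)
  y <- spline(t_s, x, xout = grid)$y
  # linear detrend
  tt <- seq_along(y)
  fit <- lm.fit(cbind(1, tt), y)
  y <- fit$residuals
  v <- pop_var(y)
  if (!is.finite(v) || v < 1e-12) {
    # flat tachogram: zero spectrum
    freq <- seq(0, fs / 2, length.out = 512L)
    return(new_hrv_psd(freq, rep(0, 512L), variance = 0, var_pred = 0,
                       ar = numeric(order), fs = fs))
  }
  mod <- ar.burg(y, aic = FALSE, order.max = order, demean = TRUE)
  a <- as.numeric(mod$ar)
  var_pred <- as.numeric(mod$var.pred)
  freq <- psd_freq_grid(a, fs)
  psd <- ar_psd_eval(freq, a, var_pred, fs)
  new_hrv_psd(freq, psd, variance = v, var_pred = var_pred, ar = a, fs = fs)
}

new_hrv_psd <- function(freq, psd, variance, var_pred, ar, fs) {
  out <- tibble(freq = freq, psd = psd)
  attr(out, "variance") <- variance
  attr(out, "var_pred") <- var_pred
  attr(out, "ar") <- ar
  attr(out, "fs") <- fs
  class(out) <- c("hrv_psd", class(out))
  out
}

# One-sided AR PSD: S(f) = 2 * sigma2 / fs / |1 - sum a_k exp(-i 2 pi f k / fs)|^2.
ar_psd_eval <- function(freq, a, var_pred, fs) {
  k <- seq_along(a)
  denom <- vapply(freq, function(f) {
    z <- exp(-2i * pi * f / fs * k)
    Mod(1 - sum(a * z))^2
  }, numeric(1L))
  2 * var_pred / fs / denom
}

# Frequency grid: uniform over [0, fs/2] plus log-spaced refinements around
# each AR pole frequency, with local spacing tied to the pole's distance
# from the unit circle (the Lorentzian half-width).
psd_freq_grid <- function(a, fs, n_uniform = 2048L) {
  base <- seq(0, fs / 2, length.out = n_uniform)
  poles <- polyroot(c(1, -a))
  # poles of the AR transfer function are reciprocals of the roots of A(z)
  p <- 1 / poles
  p <- p[Mod(p) < 1 & Mod(p) > 0.8]
  extra <- numeric(0)
  for (pi_ in p) {
    f0 <- abs(Arg(pi_)) * fs / (2 * pi)
    if (f0 <= 0 || f0 >= fs / 2) next
    hw <- max((1 - Mod(pi_)) * fs / (2 * pi), 1e-12)
    offs <- hw * 10^seq(-2, 3, length.out = 40L)
    extra <- c(extra, f0, f0 + offs, f0 - offs)
  }
  sort(unique(pmin(pmax(c(base, extra), 0), fs / 2)))
}

#' Spectral band powers with per-scale computability masking
#'
#' Integrates the PSD over the standard bands: LF `[0.04, 0.15]` Hz,
#' HF `[0.15, 0.4]` Hz and total power `[0, 0.4]` Hz, plus the LF/HF ratio.
#' Spectral estimates need recordings at least ten times the wavelength of
#' the band's lower frequency edge, so LF, LF/HF and TotPow are masked
#' (`NA`) for excerpts shorter than 120 s and HF for excerpts shorter than
#' 60 s; masking is not an error.
#'
#' @param psd `"hrv_psd"` object from [ar_psd()], or `NULL`.
#' @param excerpt_length_s Nominal excerpt length in seconds, which drives
#'   the masking rules.
#' @return One-row tibble with `LF`, `HF`, `TotPow` (ms^2) and `LF/HF`.
#' @export
band_powers <- function(psd, excerpt_length_s) {
  out <- tibble(
    LF = NA_real_, HF = NA_real_, TotPow = NA_real_, `LF/HF` = NA_real_
  )
  lf_ok <- excerpt_length_s >= 120
  hf_ok <- excerpt_length_s >= 60
  if (is.null(psd) || (!lf_ok && !hf_ok)) return(out)
  stopifnot(inherits(psd, "hrv_psd"))
  if (hf_ok) out$HF <- band_integral(psd, 0.15, 0.4)
  if (lf_ok) {
    out$LF <- band_integral(psd, 0.04, 0.15)
    out$TotPow <- band_integral(psd, 0, 0.4)
    out$`LF/HF` <- if (is.finite(out$HF) && out$HF > 0) out$LF / out$HF else NA_real_
  }
  out
}

band_integral <- function(psd, lo, hi) {
  f <- psd$freq
  y <- psd$psd
  keep <- f >= lo & f <= hi
  fk <- f[keep]
  yk <- y[keep]
  # pin the exact band edges by linear interpolation
  for (edge in c(lo, hi)) {
    if (!edge %in% fk && edge > min(f) && edge < max(f)) {
      fk <- c(fk, edge)
      yk <- c(yk, approx(f, y, xout = edge)$y)
    }
  }
  o <- order(fk)
  trapz(fk[o], yk[o])
}

#' @exportS3Method ggplot2::autoplot
autoplot.hrv_psd <- function(object, ...) {
  bands <- tibble(
    band = factor(c("VLF", "LF", "HF"), levels = c("VLF", "LF", "HF")),
    lo = c(0, 0.04, 0.15), hi = c(0.04, 0.15, 0.4)
  )
  ggplot(object, aes(x = .data$freq, y = .data$psd)) +
    geom_rect(
      data = bands, inherit.aes = FALSE,
      aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf,
          fill = .data$band),
      alpha = 0.15
    ) +
    geom_line() +
    coord_cartesian(xlim = c(0, 0.5)) +
    labs(
      x = "Frequency (Hz)", y = expression(PSD ~ (ms^2 / Hz)),
      fill = "Band", title = "AR tachogram spectrum"
    ) +
    theme_minimal()
}
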