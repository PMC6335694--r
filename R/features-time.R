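#' Analysis parameters for the HRV feature extractor
#'
#' Bundles every tunable numerical choice of the 23-feature extractor, with
#' the package defaults. All variances and standard deviations use the
#' population (divide-by-N) convention so that `SD1 == RMSSD / sqrt(2)`
#' holds exactly.
#'
#' @param ar_order Autoregressive model order for spectral estimation.
#' @param resample_hz Even resampling rate of the tachogram (Hz) before AR
#'   fitting; cubic-spline interpolation is used.
#' @param entropy_m Template length for sample/approximate entropy.
#' @param entropy_r Entropy tolerance as a fraction of the excerpt SD.
#' @param dfa_short,dfa_long Box-size ranges (beats) for the short- and
#'   long-range detrended-fluctuation exponents `dfa1` and `dfa2`.
#' @param d2_m Embedding dimension for the correlation dimension estimate.
#' @param rqa_m,rqa_tau,rqa_lmin Recurrence embedding dimension, delay and
#'   minimum diagonal line length.
#' @param rqa_r_factor Recurrence threshold as a multiple of the excerpt SD;
#'   the default `sqrt(rqa_m)` scales the Euclidean-norm threshold with the
#'   embedding dimension.
#' @param shanen_base Logarithm base for the recurrence line-length entropy:
#'   `"nats"` (natural log, default) or `"bits"`.
#' @return A named list of parameters, class `"hrv_params"`.
#' @export
hrv_params <- function(ar_order = 16L, resample_hz = 4, entropy_m = 2L,
                       entropy_r = 0.2, dfa_short = c(4L, 16L),
                       dfa_long = c(16L, 64L), d2_m = 10L,
                       rqa_m = 10L, rqa_tau = 1L, rqa_lmin = 2L,
                       rqa_r_factor = sqrt(rqa_m),
                       shanen_base = c("nats", "bits")) {
  shanen_base <- match.arg(shanen_base)
  structure(
    list(
      ar_order = as.integer(ar_order), resample_hz = resample_hz,
      entropy_m = as.integer(entropy_m), entropy_r = entropy_r,
      dfa_short = as.integer(dfa_short), dfa_long = as.integer(dfa_long),
      d2_m = as.integer(d2_m), rqa_m = as.integer(rqa_m),
      rqa_tau = as.integer(rqa_tau), rqa_lmin = as.integer(rqa_lmin),
      rqa_r_factor = rqa_r_factor, shanen_base = shanen_base
    ),
    class = "hrv_params"
  )
}

#' Time-domain HRV features
#'
#' Computes the seven guideline time-domain features from an NN excerpt:
#' `MeanNN`/`StdNN` (ms), `MeanHR`/`StdHR` (bpm, from the instantaneous rate
#' `60000 / NN_i`), `RMSSD` (ms), `NN50` (count of successive differences
#' exceeding 50 ms) and `pNN50 = 100 * NN50 / (N - 1)` (%).
#'
#' @param nn NN tibble (column `nn_ms`) or a bare numeric vector of NN
#'   intervals in milliseconds.
#' @return One-row tibble of the seven features; all `NA` when fewer than
#'   two intervals are available.
#' @examples
#' time_features(c(800, 810, 800, 790))
#' @export
time_features <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 2L) {
    return(tibble(
      MeanNN = NA_real_, StdNN = NA_real_, MeanHR = NA_real_,
      StdHR = NA_real_, RMSSD = NA_real_, NN50 = NA_real_, pNN50 = NA_real_
    ))
  }
  d <- diff(x)
  hr <- 60000 / x
  nn50 <- sum(abs(d) > 50)
  tibble(
    MeanNN = mean(x),
    StdNN = pop_sd(x),
    MeanHR = mean(hr),
    StdHR = pop_sd(hr),
    RMSSD = sqrt(mean(d^2)),
    NN50 = as.numeric(nn50),
    pNN50 = 100 * nn50 / (length(x) - 1L)
  )
}

#' Poincare plot dispersions SD1 and SD2
#'
#' Minor- and major-axis dispersions of the lagged Poincare scatter
#' (`NN_i` vs `NN_{i+1}`): `SD1^2 = mean(d^2) / 2` with `d` the successive
#' differences, and `SD2^2 = 2 * var(NN) - mean(d^2) / 2` (population
#' variance, floored at zero). Under this convention `SD1 == RMSSD/sqrt(2)`
#' is an exact identity.
#'
#' @inheritParams time_features
#' @return One-row tibble with `SD1` and `SD2` in milliseconds.
#' @export
poincare <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 3L) return(tibble(SD1 = NA_real_, SD2 = NA_real_))
  msd <- mean(diff(x)^2)
  sd2sq <- 2 * pop_var(x) - msd / 2
  tibble(SD1 = sqrt(msd / 2), SD2 = sqrt(max(sd2sq, 0)))
}

# Accept an NN tibble or a bare numeric vector of intervals.
nn_intervals <- function(nn) {
  if (is.data.frame(nn)) {
    col <- intersect(c("nn_ms", "rr_ms"), names(nn))
    if (length(col) == 0L) abort("`nn` must contain an `nn_ms` (or `rr_ms`) column.")
    as.numeric(nn[[col[1L]]])
  } else {
    as.numeric(nn)
  }
}

nn_times <- function(nn) {
  if (is.data.frame(nn) && "time_ms" %in% names(nn)) {
    as.numeric(nn$time_ms)
  } else {
    cumsum(nn_intervals(nn))
  }
}
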