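# Synthetic paired rest/stress RR cohorts with known spectral and
# variability structure: a sinusoid-plus-noise tachogram with LF (0.10 Hz)
# and HF (0.25 Hz) oscillations whose amplitudes, mean interval and noise
# level differ between conditions in the directions mental stress is known
# to produce (shorter MeanNN, lower StdNN and HF power, higher MeanHR and
# StdHR).

#' Configuration of the synthetic rest/stress cohort
#'
#' Condition-level means plus between-subject SDs for every generator
#' parameter. Defaults describe a healthy young adult cohort: resting mean
#' RR 850 ms dropping to 700 ms under stress, and HF (respiratory)
#' oscillation amplitude shrinking from 30 ms to 13 ms with vagal
#' withdrawal, with proportionally reduced beat-to-beat noise.
#'
#' @param rest,stress Named lists with elements `mean_rr` (ms), `a_lf` and
#'   `a_hf` (oscillation amplitudes, ms) and `sd_noise` (ms).
#' @param between Named list of between-subject SDs for the same four
#'   parameters (shared by both conditions).
#' @param duration_s Recording length in seconds (330 by default so a full
#'   300-s excerpt survives any edge trimming).
#' @param artifact_rate Fraction of beats relabelled non-normal by
#'   [inject_non_nn_beats()]; must lie in `[0, 0.5]`.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(rest = list(mean_rr = 850, a_lf = 35, a_hf = 30,
                                      sd_noise = 25),
                          stress = list(mean_rr = 700, a_lf = 40, a_hf = 13,
                                        sd_noise = 18),
                          between = list(mean_rr = 60, a_lf = 8, a_hf = 7,
                                         sd_noise = 5),
                          duration_s = 330, artifact_rate = 0) {
  for (cond in list(rest, stress)) {
    if (cond$mean_rr < 400 || cond$mean_rr > 1500) {
      abort("`mean_rr` must lie in the physiological range 400-1500 ms.")
    }
    if (any(unlist(cond) < 0)) abort("Amplitudes and SDs must be >= 0.")
  }
  if (any(unlist(between) < 0)) abort("Between-subject SDs must be >= 0.")
  if (artifact_rate < 0 || artifact_rate > 0.5) {
    abort("`artifact_rate` must lie in [0, 0.5].")
  }
  structure(
    list(rest = rest, stress = stress, between = between,
         duration_s = duration_s, artifact_rate = artifact_rate),
    class = "cohort_config"
  )
}

#' Generate one synthetic RR-interval series
#'
#' Beat-by-beat tachogram `RR_i = mean_rr + a_lf sin(2 pi 0.10 t + phi_lf)
#' + a_hf sin(2 pi 0.25 t + phi_hf) + e_i`, `e ~ N(0, sd_noise)`, with the
#' modulators evaluated at the start of each interval and beat times the
#' cumulative interval sum. All beats are labelled `"N"`.
#'
#' @param mean_rr,a_lf,a_hf,sd_noise Tachogram parameters in ms.
#' @param f_lf,f_hf Oscillation frequencies in Hz.
#' @param phase_lf,phase_hf Oscillation phases (radians); drawn uniformly
#'   when `NULL`.
#' @param duration_s Series duration in seconds.
#' @param subject_id,condition Identifiers stored on the series.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return A tidy RR-series tibble (see [read_rr_table()]).
#' @examples
#' generate_rr_series(a_hf = 40, sd_noise = 0, seed = 1)
#' @export
generate_rr_series <- function(mean_rr = 850, a_lf = 35, a_hf = 30,
                               sd_noise = 25, f_lf = 0.10, f_hf = 0.25,
                               phase_lf = NULL, phase_hf = NULL,
                               duration_s = 330, subject_id = "synthetic",
                               condition = "rest", seed = 1) {
  with_seed(seed, {
    phase_lf <- phase_lf %||% runif(1L, 0, 2 * pi)
    phase_hf <- phase_hf %||% runif(1L, 0, 2 * pi)
    n_max <- ceiling(duration_s * 1000 / max(mean_rr - 3 * sd_noise - a_lf - a_hf, 200)) + 8L
    eps <- rnorm(n_max, 0, sd_noise)
    rr <- numeric(n_max)
    t_ms <- 0
    i <- 0L
    while (t_ms < duration_s * 1000 && i < n_max) {
      i <- i + 1L
      t_s <- t_ms / 1000
      rr_i <- mean_rr +
        a_lf * sin(2 * pi * f_lf * t_s + phase_lf) +
        a_hf * sin(2 * pi * f_hf * t_s + phase_hf) +
        eps[i]
      if (rr_i < 1) {
        # below 1 ms the beat sequence degenerates (cumulative time stalls)
        abort("Generator parameters produced a non-positive RR interval.")
      }
      rr[i] <- rr_i
      t_ms <- t_ms + rr_i
    }
    rr <- rr[seq_len(i)]
    new_rr_series(
      time_ms = cumsum(rr), rr_ms = rr, label = "N",
      subject_id = subject_id, condition = condition
    )
  })
}

#' Generate a paired rest/stress synthetic cohort
#'
#' For each subject, per-condition generator parameters are drawn around
#' the condition means with the configured between-subject SDs (amplitudes
#' and noise truncated at zero, mean RR at the physiological range), then
#' one rest and one stress series are emitted. Fully deterministic under
#' `seed`.
#'
#' @param n_subjects Number of subjects (>= 10, default 42).
#' @param seed Integer seed.
#' @param config [cohort_config()].
#' @return One tidy RR tibble with `2 * n_subjects` series stacked
#'   (`subject`, `condition`, `time_ms`, `rr_ms`, `label`).
#' @export
generate_cohort <- function(n_subjects = 42, seed = 1,
                            config = cohort_config()) {
  if (n_subjects < 10L) abort("`n_subjects` must be at least 10.")
  draws <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      lapply(c(rest = "rest", stress = "stress"), function(cond) {
        p <- config[[cond]]
        b <- config$between
        list(
          mean_rr = min(max(rnorm(1L, p$mean_rr, b$mean_rr), 400), 1500),
          a_lf = max(rnorm(1L, p$a_lf, b$a_lf), 0),
          a_hf = max(rnorm(1L, p$a_hf, b$a_hf), 0),
          sd_noise = max(rnorm(1L, p$sd_noise, b$sd_noise), 0),
          seed = sample.int(2^30, 1L)
        )
      })
    })
  })
  purrr::imap(draws, function(subj, i) {
    id <- sprintf("s%03d", i)
    purrr::imap(subj, function(p, cond) {
      s <- generate_rr_series(
        mean_rr = p$mean_rr, a_lf = p$a_lf, a_hf = p$a_hf,
        sd_noise = p$sd_noise, duration_s = config$duration_s,
        subject_id = id, condition = cond, seed = p$seed
      )
      if (config$artifact_rate > 0) {
        s <- inject_non_nn_beats(s, config$artifact_rate, seed = p$seed + 1L)
      }
      s
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Relabel a fraction of beats as non-normal
#'
#' Randomly marks beats non-normal (`"V"`) and perturbs each marked beat
#' into a premature short-long couplet (the beat arrives 30% early; the
#' following interval absorbs the difference), preserving cumulative-time
#' consistency and monotonicity. Exercises the NN/RR quality gate: because
#' an interval is NN only when both delimiting beats are normal, a beat
#' relabel rate `q` removes roughly `2q` of the intervals.
#'
#' @param series Tidy RR series.
#' @param rate Fraction of beats to relabel, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return The perturbed RR series tibble.
#' @export
inject_non_nn_beats <- function(series, rate, seed = 1) {
  assert_cols(series, c("time_ms", "rr_ms", "label"), "series")
  if (rate < 0 || rate > 0.5) abort("`rate` must lie in [0, 0.5].")
  if (rate == 0) return(series)
  n <- nrow(series)
  out <- series
  with_seed(seed, {
    k <- rbinom(1L, n, rate)
    idx <- sort(sample.int(n, k))
    for (i in idx) {
      out$label[i] <- "V"
      if (i < n) {
        delta <- 0.3 * out$rr_ms[i]
        out$rr_ms[i] <- out$rr_ms[i] - delta
        out$time_ms[i] <- out$time_ms[i] - delta
        out$rr_ms[i + 1L] <- out$rr_ms[i + 1L] + delta
      }
    }
  })
  out
}
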