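# Window segmentation of a 5-min NN excerpt: a central window per time scale
# plus consecutive non-overlapping windows at one scale. Windows are defined
# on cumulative time relative to the excerpt onset (start of its first
# interval); an interval belongs to a window iff its *ending* beat time falls
# in the half-open window [start, end). This convention is deterministic and
# makes consecutive windows an exact partition.

#' Clip an NN excerpt to its nominal duration
#'
#' Keeps intervals whose ending beat time falls within the half-open window
#' `[onset, onset + duration_s)`. Used to cut the leading 5 minutes out of a
#' slightly longer recording before feature extraction.
#'
#' @param nn NN tibble from [derive_nn()] (columns `time_ms`, `nn_ms`).
#' @param duration_s Nominal excerpt duration in seconds (default 300).
#' @return The clipped NN tibble with a `scale_s` column set to `duration_s`.
#' @export
clip_nn <- function(nn, duration_s = 300) {
  assert_cols(nn, c("time_ms", "nn_ms"), "nn")
  onset <- excerpt_onset(nn)
  t_rel <- nn$time_ms - onset
  out <- nn[t_rel < duration_s * 1000, , drop = FALSE]
  out$scale_s <- as.integer(duration_s)
  out
}

#' Central window of an NN excerpt at a shorter time scale
#'
#' Extracts the window of `scale_s` seconds centred in the nominal
#' `excerpt_s`-second excerpt: `[(excerpt_s - scale_s)/2,
#' (excerpt_s + scale_s)/2)` on cumulative time. `scale_s == excerpt_s`
#' returns the excerpt unchanged (identity).
#'
#' @param nn NN tibble (columns `time_ms`, `nn_ms`).
#' @param scale_s Window length in seconds; must not exceed `excerpt_s`.
#' @param excerpt_s Nominal parent excerpt length in seconds (default 300).
#' @return NN tibble restricted to the window, with `scale_s` set and
#'   `window` set to `"central"`.
#' @examples
#' nn <- derive_nn(generate_rr_series(seed = 1)) |> clip_nn()
#' central_window(nn, 60)
#' @export
central_window <- function(nn, scale_s, excerpt_s = 300) {
  assert_cols(nn, c("time_ms", "nn_ms"), "nn")
  if (scale_s > excerpt_s) {
    abort(sprintf("`scale_s` (%s s) exceeds the excerpt length (%s s).", scale_s, excerpt_s))
  }
  onset <- excerpt_onset(nn)
  lo <- (excerpt_s - scale_s) / 2 * 1000
  hi <- (excerpt_s + scale_s) / 2 * 1000
  t_rel <- nn$time_ms - onset
  out <- nn[t_rel >= lo & t_rel < hi, , drop = FALSE]
  out$scale_s <- as.integer(scale_s)
  out$window <- "central"
  out
}

#' Consecutive non-overlapping windows at one time scale
#'
#' Splits the excerpt into `floor(excerpt_s / scale_s)` disjoint windows
#' `[k * scale_s, (k + 1) * scale_s)` in order; any trailing remainder
#' shorter than a full window is discarded.
#'
#' @inheritParams central_window
#' @return NN tibble with `scale_s` and an integer `window` index (1-based);
#'   the windows partition the covered part of the excerpt.
#' @export
consecutive_windows <- function(nn, scale_s, excerpt_s = 300) {
  assert_cols(nn, c("time_ms", "nn_ms"), "nn")
  if (scale_s > excerpt_s) {
    abort(sprintf("`scale_s` (%s s) exceeds the excerpt length (%s s).", scale_s, excerpt_s))
  }
  n_win <- floor(excerpt_s / scale_s)
  onset <- excerpt_onset(nn)
  t_rel <- nn$time_ms - onset
  idx <- floor(t_rel / (scale_s * 1000)) + 1
  keep <- idx >= 1 & idx <= n_win & t_rel >= 0
  out <- nn[keep, , drop = FALSE]
  out$scale_s <- as.integer(scale_s)
  out$window <- as.character(idx[keep])
  out
}
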