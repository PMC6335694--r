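# Internal helpers shared across modules.

# Canonical feature catalogue order (23 features).
HRV_FEATURES <- c(
  "MeanNN", "StdNN", "MeanHR", "StdHR", "RMSSD", "NN50", "pNN50",
  "LF", "HF", "LF/HF", "TotPow",
  "SD1", "SD2", "ApEn", "SampEn", "D2", "dfa1", "dfa2",
  "RPlmean", "RPlmax", "REC", "RPadet", "ShanEn"
)

HRV_SCALES <- c(300L, 180L, 120L, 60L, 30L)

# Population (divide-by-N) variance and SD: the package-wide convention, so
# that SD1 == RMSSD/sqrt(2) holds exactly (see the methods vignette).
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

assert_cols <- function(df, cols, what = "data") {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scale <- function(scale_s) {
  if (length(scale_s) != 1L || !scale_s %in% HRV_SCALES) {
    abort(sprintf(
      "`scale_s` must be one of %s seconds, got: %s.",
      paste(HRV_SCALES, collapse = ", "), paste(scale_s, collapse = ", ")
    ))
  }
  as.integer(scale_s)
}

# Carry identifying columns (subject, condition, scale_s, window) from a
# per-excerpt tibble into a one-row result.
excerpt_id_cols <- function(df) {
  keep <- intersect(c("subject", "condition", "scale_s", "window"), names(df))
  if (length(keep) == 0L) return(tibble(.rows = 1L))
  as_tibble(lapply(df[keep], function(col) col[[1L]]))
}

# Onset (ms) of an interval tibble: start of its first interval.
excerpt_onset <- function(df, time_col = "time_ms", int_col = "nn_ms") {
  if (nrow(df) == 0L) return(NA_real_)
  df[[time_col]][1L] - df[[int_col]][1L]
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}
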