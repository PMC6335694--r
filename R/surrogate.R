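# Surrogate validation engine: paired Wilcoxon trend coding per scale,
# short-vs-ultra-short Spearman screening per condition, Bland-Altman
# agreement, and the surrogate gate that combines them.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped; with `n <= 15`
#' effective pairs the p-value comes from exact enumeration of all `2^n`
#' sign assignments of the (tie-averaged) ranks, otherwise from the normal
#' approximation with continuity and tie corrections. All pairs identical
#' gives `p = 1` with a warning.
#'
#' @param x,y Paired numeric vectors (e.g. rest and stress values of one
#'   feature across subjects).
#' @return One-row tibble: `statistic` (rank sum of positive differences),
#'   `p_value`, `n_eff` (pairs after dropping zeros), `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))  # p = 2/64
#' @export
wilcoxon_signed_rank <- function(x, y) {
  ok <- complete.cases(x, y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("All paired differences are zero; returning p = 1.")
    return(tibble(statistic = NA_real_, p_value = 1, n_eff = 0L,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 15L) {
    sums <- signed_rank_sums(r)
    p_lo <- mean(sums <= w + 1e-9)
    p_hi <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    tibble(statistic = w, p_value = p, n_eff = n, method = "exact")
  } else {
    ht <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE)
    )
    tibble(statistic = w, p_value = unname(ht$p.value), n_eff = n,
           method = "normal")
  }
}

# All 2^n subset sums of the rank vector (exact null distribution of W+).
signed_rank_sums <- function(r) {
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  sums
}

#' Encode a feature's stress-vs-rest trend
#'
#' Maps a paired-test p-value and the rest/stress medians onto the arrow
#' codes used in multiscale trend tables: `SIG_DOWN`/`SIG_UP` when
#' `p < alpha`, `NS_DOWN`/`NS_UP` otherwise, and `NC` when the feature is
#' not computable. Direction is the sign of `median_stress - median_rest`;
#' an exact tie counts as "up" by convention.
#'
#' @param p P-value(s) from [wilcoxon_signed_rank()].
#' @param median_rest,median_stress Feature medians in the two conditions.
#' @param computable Logical; `FALSE` yields `NC`.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of codes.
#' @export
encode_trend <- function(p, median_rest, median_stress, computable = TRUE,
                         alpha = 0.05) {
  n <- max(length(p), length(median_rest), length(median_stress))
  p <- rep_len(p, n)
  median_rest <- rep_len(median_rest, n)
  median_stress <- rep_len(median_stress, n)
  computable <- rep_len(computable, n)
  dir_up <- median_stress >= median_rest
  sig <- !is.na(p) & p < alpha
  code <- ifelse(dir_up,
                 ifelse(sig, "SIG_UP", "NS_UP"),
                 ifelse(sig, "SIG_DOWN", "NS_DOWN"))
  code[!computable | is.na(median_rest) | is.na(median_stress)] <- "NC"
  code
}

trend_arrows <- c(SIG_DOWN = "\u2193\u2193", SIG_UP = "\u2191\u2191",
                  NS_DOWN = "\u2193", NS_UP = "\u2191", NC = "-")

#' Per-feature, per-scale trend table
#'
#' For every feature and scale, pairs subjects across the rest and stress
#' conditions, runs the paired Wilcoxon signed-rank test and encodes the
#' median trend ([encode_trend()]). Only central windows enter the table.
#'
#' @param features_long Long feature tibble from [cohort_features()].
#' @param alpha Significance level for the trend codes.
#' @return Tibble: `feature`, `scale_s`, `median_rest`, `median_stress`,
#'   `p_value`, `direction`, `code`, `arrow`, `n`.
#' @export
trend_table <- function(features_long, alpha = 0.05) {
  assert_cols(features_long,
              c("subject", "condition", "scale_s", "feature", "value"),
              "features_long")
  df <- features_long
  if ("window" %in% names(df)) df <- filter(df, .data$window == "central")
  df |>
    select(all_of(c("subject", "condition", "scale_s", "feature", "value"))) |>
    pivot_wider(names_from = "condition", values_from = "value") |>
    group_by(.data$feature, .data$scale_s) |>
    group_modify(function(g, key) {
      ok <- complete.cases(g$rest, g$stress)
      if (sum(ok) < 5L) {
        return(tibble(
          median_rest = NA_real_, median_stress = NA_real_,
          p_value = NA_real_, direction = NA_character_, code = "NC",
          n = sum(ok)
        ))
      }
      wt <- suppressWarnings(wilcoxon_signed_rank(g$rest[ok], g$stress[ok]))
      m_r <- median(g$rest[ok])
      m_s <- median(g$stress[ok])
      tibble(
        median_rest = m_r, median_stress = m_s,
        p_value = wt$p_value,
        direction = if (m_s < m_r) "down" else "up",
        code = encode_trend(wt$p_value, m_r, m_s, alpha = alpha),
        n = sum(ok)
      )
    }) |>
    ungroup() |>
    mutate(
      feature = factor(.data$feature, levels = HRV_FEATURES),
      arrow = unname(trend_arrows[.data$code])
    ) |>
    arrange(.data$feature, desc(.data$scale_s)) |>
    mutate(feature = as.character(.data$feature))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation. A vector with zero rank variance yields
#' `NA` (flagged, not an error).
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: `rho`, `p_rho`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5L || pop_sd(rank(x)) == 0 || pop_sd(rank(y)) == 0) {
    return(tibble(rho = NA_real_, p_rho = NA_real_, n = n))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ht$estimate), p_rho = unname(ht$p.value), n = n)
}

#' Ultra-short vs short correlation table
#'
#' Correlates each feature at each ultra-short scale against the same
#' feature at the benchmark scale, separately within the rest and stress
#' phases, across subjects.
#'
#' @param features_long Long feature tibble from [cohort_features()]
#'   containing the benchmark scale and at least one shorter scale.
#' @param benchmark_scale Benchmark scale in seconds (default 300).
#' @return Tibble: `feature`, `scale_s`, `phase`, `rho`, `p_rho`, `n`.
#' @export
correlation_table <- function(features_long, benchmark_scale = 300) {
  assert_cols(features_long,
              c("subject", "condition", "scale_s", "feature", "value"),
              "features_long")
  df <- features_long
  if ("window" %in% names(df)) df <- filter(df, .data$window == "central")
  bench <- df |>
    filter(.data$scale_s == benchmark_scale) |>
    select(all_of(c("subject", "condition", "feature")), bench_value = "value")
  df |>
    filter(.data$scale_s != benchmark_scale) |>
    inner_join(bench, by = c("subject", "condition", "feature")) |>
    group_by(.data$feature, .data$scale_s, phase = .data$condition) |>
    group_modify(\(g, key) spearman(g$value, g$bench_value)) |>
    ungroup() |>
    mutate(feature = factor(.data$feature, levels = HRV_FEATURES)) |>
    arrange(.data$feature, desc(.data$scale_s), .data$phase) |>
    mutate(feature = as.character(.data$feature))
}

#' Bland-Altman agreement between short and ultra-short measurements
#'
#' Differences are `short - ultra`. The bias is the *median* difference
#' while the 95% limits of agreement are `mean(d) +/- 1.96 * sd(d)`
#' (sample SD); both are reported. Agreement is advisory evidence and is
#' never part of the surrogate pass/fail gate.
#'
#' @param short,ultra Paired numeric vectors (benchmark first).
#' @return One-row tibble (`bias`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`), class `"hrv_agreement"`; the paired values are kept
#'   as an attribute for plotting (benchmark on the x-axis).
#' @export
bland_altman <- function(short, ultra) {
  ok <- complete.cases(short, ultra)
  short <- short[ok]
  ultra <- ultra[ok]
  if (length(short) < 3L) abort("Bland-Altman needs at least 3 paired values.")
  d <- short - ultra
  out <- tibble(
    bias = median(d),
    mean_diff = mean(d),
    sd_diff = sd(d),
    loa_low = mean(d) - 1.96 * sd(d),
    loa_high = mean(d) + 1.96 * sd(d),
    n = length(d)
  )
  attr(out, "pairs") <- tibble(short = short, ultra = ultra, diff = d)
  class(out) <- c("hrv_agreement", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.hrv_agreement <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot(pairs, aes(x = .data$short, y = .data$diff)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = object$bias, linetype = "solid") +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dashed") +
    labs(
      x = "Benchmark (5-min) value", y = "Difference (5-min - ultra-short)",
      title = "Bland-Altman agreement",
      subtitle = sprintf("bias (median) = %.3g; 95%% LoA [%.3g, %.3g]",
                         object$bias, object$loa_low, object$loa_high)
    ) +
    theme_minimal()
}

#' Bland-Altman agreement summaries for every feature, scale and phase
#'
#' @inheritParams correlation_table
#' @return Tibble with one row per feature x ultra-short scale x phase and
#'   the [bland_altman()] columns.
#' @export
agreement_table <- function(features_long, benchmark_scale = 300) {
  assert_cols(features_long,
              c("subject", "condition", "scale_s", "feature", "value"),
              "features_long")
  df <- features_long
  if ("window" %in% names(df)) df <- filter(df, .data$window == "central")
  bench <- df |>
    filter(.data$scale_s == benchmark_scale) |>
    select(all_of(c("subject", "condition", "feature")), bench_value = "value")
  df |>
    filter(.data$scale_s != benchmark_scale) |>
    inner_join(bench, by = c("subject", "condition", "feature")) |>
    group_by(.data$feature, .data$scale_s, phase = .data$condition) |>
    group_modify(function(g, key) {
      ok <- complete.cases(g$bench_value, g$value)
      if (sum(ok) < 3L) {
        return(tibble(bias = NA_real_, mean_diff = NA_real_, sd_diff = NA_real_,
                      loa_low = NA_real_, loa_high = NA_real_, n = sum(ok)))
      }
      ba <- bland_altman(g$bench_value[ok], g$value[ok])
      as_tibble(unclass(ba)[names(ba)])
    }) |>
    ungroup()
}
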