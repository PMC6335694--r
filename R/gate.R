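# The surrogate gate: combine the per-scale trend codes with the
# short-vs-ultra-short correlation screen into a per-feature verdict, plus
# the data-driven retention rule that decides which ultra-short scales are
# worth keeping at all.

corr_is_significant <- function(df, alpha) {
  if ("p_rho" %in% names(df) && any(is.finite(df$p_rho))) {
    df$p_rho < alpha
  } else if ("significant" %in% names(df)) {
    df$significant
  } else {
    abort("Correlation table needs a `p_rho` or `significant` column.")
  }
}

#' Surrogate gate: which ultra-short features stand in for the 5-min ones
#'
#' A feature passes iff (a) its trend is significant at the benchmark scale
#' and significant *with the same direction* at every retained ultra-short
#' scale, and (b) its correlation with the benchmark feature exceeds
#' `rho_min` with a significant correlation p-value at every retained scale
#' in *both* rest and stress phases. Bland-Altman agreement is advisory and
#' never enters the pass/fail decision.
#'
#' @param trends Trend table ([trend_table()] or [reference_trend_codes()]):
#'   columns `feature`, `scale_s`, `code`.
#' @param correlations Correlation table ([correlation_table()] or
#'   [reference_rho_table()]): columns `feature`, `scale_s`, `phase`, `rho`
#'   and either `p_rho` or a logical `significant`.
#' @param retained_scales Ultra-short scales (seconds) a surrogate must
#'   survive; defaults to `c(180, 120, 60)`, the scales kept by the
#'   retention rule ([scale_retention()]).
#' @param rho_min Correlation threshold (strict, `rho > rho_min`).
#' @param alpha Significance level for both criteria.
#' @param benchmark_scale Benchmark scale in seconds (default 300).
#' @return A verdict tibble of class `"surrogate_gate"`: `feature`, `pass`
#'   (`NA` when entries needed for the decision are missing), `trend_ok`,
#'   `corr_ok` and a `reasons` string naming every failed criterion.
#' @examples
#' gate <- surrogate_gate(reference_trend_codes(), reference_rho_table())
#' dplyr::filter(gate, pass)
#' @export
surrogate_gate <- function(trends, correlations,
                           retained_scales = c(180, 120, 60),
                           rho_min = 0.7, alpha = 0.05,
                           benchmark_scale = 300) {
  assert_cols(trends, c("feature", "scale_s", "code"), "trends")
  assert_cols(correlations, c("feature", "scale_s", "phase", "rho"),
              "correlations")
  correlations$sig <- corr_is_significant(correlations, alpha)
  feats <- unique(trends$feature)
  verdicts <- purrr::map(feats, function(f) {
    tr <- trends[trends$feature == f, ]
    co <- correlations[correlations$feature == f, ]
    reasons <- character(0)
    undetermined <- FALSE

    bench <- tr$code[tr$scale_s == benchmark_scale]
    if (length(bench) != 1L) {
      undetermined <- TRUE
      reasons <- c(reasons, sprintf("missing trend entry at %d s", benchmark_scale))
      bench <- NA_character_
    }
    trend_ok <- !is.na(bench) && bench %in% c("SIG_DOWN", "SIG_UP")
    if (!is.na(bench) && !trend_ok) {
      reasons <- c(reasons, sprintf("trend not significant at %d s", benchmark_scale))
    }
    for (s in retained_scales) {
      code <- tr$code[tr$scale_s == s]
      if (length(code) != 1L) {
        undetermined <- TRUE
        reasons <- c(reasons, sprintf("missing trend entry at %d s", s))
        next
      }
      if (is.na(bench)) next
      if (code == "NC") {
        trend_ok <- FALSE
        reasons <- c(reasons, sprintf("not computable at %d s", s))
      } else if (code != bench) {
        trend_ok <- FALSE
        reasons <- c(reasons, sprintf("trend differs from benchmark at %d s", s))
      }
    }

    corr_ok <- TRUE
    for (s in retained_scales) {
      for (ph in c("rest", "stress")) {
        row <- co[co$scale_s == s & co$phase == ph, ]
        if (nrow(row) != 1L) {
          undetermined <- TRUE
          reasons <- c(reasons, sprintf("missing correlation at %d s (%s)", s, ph))
          next
        }
        if (!is.finite(row$rho)) {
          corr_ok <- FALSE
          reasons <- c(reasons, sprintf("correlation not computable at %d s (%s)", s, ph))
        } else if (row$rho <= rho_min) {
          corr_ok <- FALSE
          reasons <- c(reasons, sprintf("rho %.3f <= %.2f at %d s (%s)", row$rho, rho_min, s, ph))
        } else if (!isTRUE(row$sig)) {
          corr_ok <- FALSE
          reasons <- c(reasons, sprintf("correlation not significant at %d s (%s)", s, ph))
        }
      }
    }

    tibble(
      feature = f,
      pass = if (undetermined) NA else trend_ok && corr_ok,
      trend_ok = if (undetermined) NA else trend_ok,
      corr_ok = if (undetermined) NA else corr_ok,
      reasons = paste(reasons, collapse = "; ")
    )
  }) |> list_rbind()

  structure(
    verdicts,
    retained_scales = retained_scales,
    rho_min = rho_min,
    alpha = alpha,
    benchmark_scale = benchmark_scale,
    class = c("surrogate_gate", class(verdicts))
  )
}

#' Data-driven retention of ultra-short scales
#'
#' A candidate scale is retained iff at least `min_pass` features behave
#' coherently with the benchmark there: trend significant with the same
#' direction as the (significant) benchmark trend, and correlation above
#' `rho_min` and significant in both phases at that scale.
#'
#' @inheritParams surrogate_gate
#' @param candidate_scales Scales to evaluate (default 180, 120, 60, 30).
#' @param min_pass Minimum number of coherent features (default 3).
#' @return Tibble `scale_s`, `n_pass`, `retained`, with the retained scale
#'   vector in `attr(, "retained_scales")`. Warns when nothing is retained.
#' @export
scale_retention <- function(trends, correlations,
                            candidate_scales = c(180, 120, 60, 30),
                            min_pass = 3, rho_min = 0.7, alpha = 0.05,
                            benchmark_scale = 300) {
  assert_cols(trends, c("feature", "scale_s", "code"), "trends")
  assert_cols(correlations, c("feature", "scale_s", "phase", "rho"),
              "correlations")
  correlations$sig <- corr_is_significant(correlations, alpha)
  counts <- purrr::map_int(candidate_scales, function(s) {
    per_feat <- purrr::map_lgl(unique(trends$feature), function(f) {
      bench <- trends$code[trends$feature == f & trends$scale_s == benchmark_scale]
      code <- trends$code[trends$feature == f & trends$scale_s == s]
      if (length(bench) != 1L || length(code) != 1L) return(FALSE)
      if (!bench %in% c("SIG_DOWN", "SIG_UP") || code != bench) return(FALSE)
      co <- correlations[correlations$feature == f & correlations$scale_s == s, ]
      all(c("rest", "stress") %in% co$phase) &&
        all(is.finite(co$rho) & co$rho > rho_min & co$sig)
    })
    sum(per_feat)
  })
  out <- tibble(
    scale_s = as.integer(candidate_scales),
    n_pass = counts,
    retained = counts >= min_pass
  )
  if (!any(out$retained)) {
    warn("No candidate scale reaches `min_pass` coherent features; nothing retained.")
  }
  attr(out, "retained_scales") <- out$scale_s[out$retained]
  out
}

#' @exportS3Method generics::tidy
tidy.surrogate_gate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "surrogate_gate")
  attr(out, "retained_scales") <- NULL
  attr(out, "rho_min") <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "benchmark_scale") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.surrogate_gate <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_pass = sum(x$pass, na.rm = TRUE),
    n_fail = sum(!x$pass, na.rm = TRUE),
    n_undetermined = sum(is.na(x$pass)),
    rho_min = attr(x, "rho_min"),
    alpha = attr(x, "alpha"),
    retained_scales = paste(attr(x, "retained_scales"), collapse = ",")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.surrogate_gate <- function(object, ...) {
  df <- tibble(
    feature = factor(object$feature,
                     levels = rev(intersect(HRV_FEATURES, object$feature))),
    trend = object$trend_ok,
    correlation = object$corr_ok,
    overall = object$pass
  ) |>
    pivot_longer(-"feature", names_to = "criterion", values_to = "ok") |>
    mutate(criterion = factor(.data$criterion,
                              levels = c("trend", "correlation", "overall")))
  ggplot(df, aes(x = .data$criterion, y = .data$feature, fill = .data$ok)) +
    geom_tile(colour = "white") +
    scale_fill_manual(
      values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828"),
      na.value = "grey70", name = "passes"
    ) +
    labs(x = NULL, y = NULL, title = "Surrogate gate verdicts") +
    theme_minimal()
}

#' Reference multiscale trend codes (published 42-subject stress study)
#'
#' Trend codes for all 23 HRV features at 300/180/120/60/30 s transcribed
#' from a published academic-examination mental-stress study of 42 healthy
#' subjects, shipped so the gate can be exercised against real published
#' evidence without the (undeposited) ECGs.
#'
#' @return Tibble `feature`, `scale_s`, `code` (115 rows).
#' @export
reference_trend_codes <- function() {
  path <- system.file("extdata", "reference_trend_codes.csv", package = "ushrv")
  out <- as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
  out$scale_s <- as.integer(out$scale_s)
  out
}

#' Reference Spearman correlation table (published 42-subject stress study)
#'
#' Ultra-short vs 5-min Spearman coefficients for all 23 features at
#' 180/120/60/30 s in both phases, from the same published study as
#' [reference_trend_codes()]. All computable coefficients were reported as
#' significant (`p_rho < 0.05`) in the source, encoded in the `significant`
#' column; `rho` is `NA` where the feature is not computable at that scale.
#'
#' @return Tibble `feature`, `scale_s`, `phase`, `rho`, `significant`.
#' @export
reference_rho_table <- function() {
  path <- system.file("extdata", "reference_spearman_rho.csv", package = "ushrv")
  out <- as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
  out$scale_s <- as.integer(out$scale_s)
  out$significant <- as.logical(out$significant)
  out
}
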