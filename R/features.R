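#' The 23-feature HRV catalogue
#'
#' @return A tibble with one row per feature: `feature`, `domain`
#'   (time / frequency / nonlinear) and `units`.
#' @export
hrv_feature_catalog <- function() {
  tibble(
    feature = HRV_FEATURES,
    domain = c(
      rep("time", 7L), rep("frequency", 4L), rep("nonlinear", 12L)
    ),
    units = c(
      "ms", "ms", "bpm", "bpm", "ms", "count", "%",
      "ms^2", "ms^2", "ratio", "ms^2",
      "ms", "ms", "nats", "nats", "dimensionless", "exponent", "exponent",
      "beats", "beats", "%", "%", "nats"
    )
  )
}

#' Per-scale computability mask
#'
#' Which of the 23 features are computable at a nominal excerpt length.
#' Spectral features need excerpts at least ten times the wavelength of the
#' band's lower frequency edge (LF, LF/HF and TotPow need >= 120 s, HF
#' >= 60 s); approximate entropy is unreliable below 3 min and the
#' remaining non-linear features below 1 min. At 30 s only the seven
#' time-domain features plus SD1 and SD2 remain.
#'
#' @param scale_s Nominal scale in seconds, one of 300, 180, 120, 60, 30.
#' @return Tibble with columns `feature` and `computable` (23 rows).
#' @examples
#' sum(computability_mask(60)$computable)  # 19
#' @export
computability_mask <- function(scale_s) {
  scale_s <- assert_scale(scale_s)
  ok <- rep(TRUE, length(HRV_FEATURES))
  names(ok) <- HRV_FEATURES
  if (scale_s < 180) ok["ApEn"] <- FALSE
  if (scale_s < 120) ok[c("LF", "LF/HF", "TotPow")] <- FALSE
  if (scale_s < 60) ok["HF"] <- FALSE
  if (scale_s < 60) {
    ok[c("SampEn", "D2", "dfa1", "dfa2",
         "RPlmean", "RPlmax", "REC", "RPadet", "ShanEn")] <- FALSE
  }
  tibble(feature = HRV_FEATURES, computable = unname(ok))
}

#' Extract the full HRV feature vector from one NN excerpt
#'
#' Dispatches to the time-domain, AR-spectral and non-linear feature
#' functions and assembles one long feature vector, applying the per-scale
#' computability mask ([computability_mask()]). Masked or individually
#' degenerate features are reported as `NA` with `computable = FALSE`,
#' never as silent zeros, and a failing feature never aborts the vector.
#'
#' @param nn NN excerpt tibble (columns `nn_ms`, optionally `time_ms`,
#'   `subject`, `condition`, `scale_s`, `window`) or numeric vector.
#' @param scale_s Nominal scale in seconds; taken from the `scale_s` column
#'   when omitted.
#' @param features Optional character vector restricting which features are
#'   computed (the remaining rows are still returned, as `NA`).
#' @param params [hrv_params()] bundle of numerical settings.
#' @return Long tibble with identifying columns plus `feature`, `value`,
#'   `computable` (23 rows, catalogue order).
#' @examples
#' nn <- derive_nn(generate_rr_series(seed = 1)) |> clip_nn()
#' extract_features(nn)
#' @export
extract_features <- function(nn, scale_s = NULL, features = NULL,
                             params = hrv_params()) {
  if (is.null(scale_s)) {
    if (is.data.frame(nn) && "scale_s" %in% names(nn)) {
      scale_s <- nn$scale_s[[1L]]
    } else {
      abort("`scale_s` must be given (or present as a column of `nn`).")
    }
  }
  scale_s <- assert_scale(scale_s)
  mask <- computability_mask(scale_s)
  wanted <- features %||% HRV_FEATURES
  unknown <- setdiff(wanted, HRV_FEATURES)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown feature(s): %s.", paste(unknown, collapse = ", ")))
  }
  active <- function(set) {
    any(set %in% wanted & mask$computable[match(set, mask$feature)])
  }
  vals <- setNames(rep(NA_real_, length(HRV_FEATURES)), HRV_FEATURES)

  time_set <- c("MeanNN", "StdNN", "MeanHR", "StdHR", "RMSSD", "NN50", "pNN50")
  if (active(time_set)) {
    tf <- time_features(nn)
    vals[time_set] <- as.numeric(tf[1L, time_set])
  }
  spec_set <- c("LF", "HF", "LF/HF", "TotPow")
  if (active(spec_set)) {
    psd <- ar_psd(nn, order = params$ar_order, fs = params$resample_hz)
    bp <- band_powers(psd, excerpt_length_s = scale_s)
    vals[spec_set] <- as.numeric(bp[1L, spec_set])
  }
  if (active(c("SD1", "SD2"))) {
    pc <- poincare(nn)
    vals[c("SD1", "SD2")] <- c(pc$SD1, pc$SD2)
  }
  if (active("ApEn")) {
    vals["ApEn"] <- approximate_entropy(nn, m = params$entropy_m, r = params$entropy_r)
  }
  if (active("SampEn")) {
    vals["SampEn"] <- sample_entropy(nn, m = params$entropy_m, r = params$entropy_r)
  }
  if (active(c("dfa1", "dfa2"))) {
    df_ <- dfa(nn, short_range = params$dfa_short, long_range = params$dfa_long)
    vals[c("dfa1", "dfa2")] <- c(df_$dfa1, df_$dfa2)
  }
  if (active("D2")) {
    vals["D2"] <- correlation_dimension(nn, m = params$d2_m)
  }
  rqa_set <- c("RPlmean", "RPlmax", "REC", "RPadet", "ShanEn")
  if (active(rqa_set)) {
    rq <- rqa(nn, m = params$rqa_m, tau = params$rqa_tau,
              lmin = params$rqa_lmin, r_factor = params$rqa_r_factor,
              shanen_base = params$shanen_base)
    vals[rqa_set] <- as.numeric(rq[1L, rqa_set])
  }
  vals[mask$feature[!mask$computable]] <- NA_real_
  vals[setdiff(HRV_FEATURES, wanted)] <- NA_real_

  id <- if (is.data.frame(nn)) excerpt_id_cols(nn) else tibble(.rows = 1L)
  id$scale_s <- scale_s
  if (!"window" %in% names(id)) id$window <- "central"
  out <- bind_cols(
    id[rep(1L, length(HRV_FEATURES)), , drop = FALSE],
    tibble(
      feature = HRV_FEATURES,
      value = unname(vals),
      computable = mask$computable & !is.na(vals)
    )
  )
  as_tibble(out)
}

#' Multiscale feature extraction over a cohort of RR series
#'
#' Runs the whole per-recording pipeline for every subject/condition pair in
#' a tidy RR cohort: NN/RR quality gating, NN derivation, clipping to the
#' leading 5-min excerpt, window segmentation at each requested scale and
#' feature extraction.
#'
#' @param rr Tidy RR cohort (columns `subject`, `condition`, `time_ms`,
#'   `rr_ms`, `label`), e.g. from [generate_cohort()].
#' @param scales Nominal window scales in seconds (subset of
#'   300, 180, 120, 60, 30).
#' @param placement `"central"` (one centred window per scale) or
#'   `"consecutive"` (all disjoint windows per scale).
#' @param features Optional restriction of computed features (see
#'   [extract_features()]).
#' @param params [hrv_params()] settings.
#' @param threshold NN/RR quality-gate threshold.
#' @return Long feature tibble: `subject`, `condition`, `scale_s`, `window`,
#'   `feature`, `value`, `computable`.
#' @export
cohort_features <- function(rr, scales = c(300, 180, 120, 60, 30),
                            placement = c("central", "consecutive"),
                            features = NULL, params = hrv_params(),
                            threshold = 0.90) {
  placement <- match.arg(placement)
  assert_cols(rr, c("subject", "condition", "time_ms", "rr_ms", "label"), "rr")
  for (s in scales) assert_scale(s)
  groups <- rr |>
    group_by(.data$subject, .data$condition) |>
    group_split()
  purrr::map(groups, function(g) {
    nn5 <- clip_nn(derive_nn(g, threshold = threshold), duration_s = 300)
    purrr::map(scales, function(s) {
      if (placement == "central") {
        win <- if (s == 300) {
          w <- nn5
          w$window <- "central"
          w
        } else {
          central_window(nn5, s)
        }
        extract_features(win, scale_s = s, features = features, params = params)
      } else {
        cw <- consecutive_windows(nn5, s)
        purrr::map(
          split(cw, cw$window),
          \(w) extract_features(w, scale_s = s, features = features, params = params)
        ) |> list_rbind()
      }
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Pivot a long feature table to wide (one column per feature)
#'
#' @param features_long Long feature tibble from [cohort_features()] or
#'   [extract_features()].
#' @return Wide tibble keyed by `subject`, `condition`, `scale_s`, `window`;
#'   masked features appear as `NA`.
#' @export
widen_features <- function(features_long) {
  assert_cols(features_long, c("feature", "value"), "features_long")
  id_cols <- intersect(c("subject", "condition", "scale_s", "window"),
                       names(features_long))
  features_long |>
    select(all_of(c(id_cols, "feature", "value"))) |>
    pivot_wider(names_from = "feature", values_from = "value")
}
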