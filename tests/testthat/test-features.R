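test_that("computability mask reproduces the per-scale pattern", {
  counts <- vapply(c(300, 180, 120, 60, 30),
                   function(s) sum(computability_mask(s)$computable),
                   numeric(1))
  expect_equal(counts, c(23, 23, 22, 19, 9))

  m60 <- computability_mask(60)
  masked60 <- m60$feature[!m60$computable]
  expect_setequal(masked60, c("LF", "LF/HF", "TotPow", "ApEn"))

  m30 <- computability_mask(30)
  expect_setequal(
    m30$feature[m30$computable],
    c("MeanNN", "StdNN", "MeanHR", "StdHR", "RMSSD", "NN50", "pNN50",
      "SD1", "SD2")
  )
  expect_error(computability_mask(90), "scale_s")
})

test_that("extract_features returns all 23 features and honours the mask", {
  nn <- clip_nn(derive_nn(generate_rr_series(seed = 6)), 300)
  fv <- extract_features(nn, 300)
  expect_equal(nrow(fv), 23L)
  expect_equal(fv$feature, hrv_feature_catalog()$feature)
  expect_true(all(fv$computable))
  expect_true(all(is.finite(fv$value)))

  w30 <- central_window(nn, 30)
  fv30 <- extract_features(w30)
  expect_equal(sum(fv30$computable), 9L)
  expect_true(all(is.na(fv30$value[!fv30$computable])))

  # deterministic: same excerpt twice gives identical vectors
  expect_identical(extract_features(nn, 300), fv)
})

test_that("feature restriction computes only what is asked but keeps shape", {
  nn <- central_window(clip_nn(derive_nn(generate_rr_series(seed = 6))), 60)
  fv <- extract_features(nn, features = c("MeanNN", "HF"))
  expect_equal(nrow(fv), 23L)
  expect_true(is.finite(fv$value[fv$feature == "MeanNN"]))
  expect_true(is.finite(fv$value[fv$feature == "HF"]))
  expect_true(is.na(fv$value[fv$feature == "RMSSD"]))
  expect_error(extract_features(nn, features = "NotAFeature"), "Unknown")
})

test_that("cohort_features carries ids and windows through the pipeline", {
  coh <- generate_cohort(10, seed = 2)
  fl <- cohort_features(coh, scales = c(300, 60),
                        features = c("MeanNN", "MeanHR"))
  expect_setequal(unique(fl$scale_s), c(300, 60))
  expect_equal(nrow(fl), 10 * 2 * 2 * 23)
  wide <- widen_features(fl)
  expect_true(all(c("subject", "condition", "scale_s", "MeanNN") %in% names(wide)))

  cons <- cohort_features(dplyr::filter(coh, subject == "s001"),
                          scales = 60, placement = "consecutive",
                          features = "MeanNN")
  expect_setequal(unique(cons$window), as.character(1:5))
})
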