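test_that("the generator is deterministic and degenerates cleanly", {
  a <- generate_rr_series(seed = 13)
  b <- generate_rr_series(seed = 13)
  expect_identical(a, b)
  expect_false(identical(a, generate_rr_series(seed = 14)))

  const <- generate_rr_series(a_lf = 0, a_hf = 0, sd_noise = 0,
                              mean_rr = 1000, seed = 1)
  expect_equal(unique(const$rr_ms), 1000)
  tf <- time_features(derive_nn(const))
  expect_equal(tf$StdNN, 0)

  expect_error(
    generate_rr_series(mean_rr = 500, a_lf = 600, sd_noise = 0, seed = 1),
    "non-positive RR"
  )
})

test_that("programmed parameters are recovered by the extractor", {
  s <- generate_rr_series(mean_rr = 900, a_lf = 0, a_hf = 40, sd_noise = 0,
                          seed = 17)
  nn <- clip_nn(derive_nn(s), 300)
  fv <- widen_features(extract_features(nn, 300,
                                        features = c("MeanNN", "HF")))
  expect_equal(fv$MeanNN, 900, tolerance = 0.01)
  expect_equal(fv$HF, 800, tolerance = 0.15)
})

test_that("cohort generation is paired, deterministic and physiologic", {
  coh <- generate_cohort(12, seed = 3)
  counts <- dplyr::count(dplyr::distinct(coh, subject, condition), subject)
  expect_equal(nrow(counts), 12L)
  expect_true(all(counts$n == 2L))
  expect_identical(coh, generate_cohort(12, seed = 3))
  expect_true(all(coh$rr_ms > 0))
  expect_error(generate_cohort(5, seed = 1), "at least 10")
})

test_that("artifact injection drives the quality gate as designed", {
  s <- generate_rr_series(seed = 23)
  expect_identical(inject_non_nn_beats(s, 0), s)

  heavy <- inject_non_nn_beats(s, 0.2, seed = 2)
  expect_lt(nn_ratio(heavy), 0.9)
  expect_false(quality_gate(heavy))
  # time bookkeeping survives the perturbation
  expect_true(all(diff(heavy$time_ms) > 0))
  expect_equal(diff(heavy$time_ms), heavy$rr_ms[-1], tolerance = 1e-9)

  light <- inject_non_nn_beats(s, 0.03, seed = 2)
  expect_true(quality_gate(light))
  expect_gt(nn_ratio(light), 0.9)
})

test_that("condition contrasts point the way mental stress does", {
  coh <- generate_cohort(42, seed = 29)
  fl <- cohort_features(coh, scales = 300,
                        features = c("MeanNN", "StdNN", "MeanHR", "StdHR", "HF"))
  tt <- trend_table(fl)
  codes <- setNames(tt$code, tt$feature)
  expect_equal(unname(codes["MeanNN"]), "SIG_DOWN")
  expect_equal(unname(codes["StdNN"]), "SIG_DOWN")
  expect_equal(unname(codes["HF"]), "SIG_DOWN")
  expect_equal(unname(codes["MeanHR"]), "SIG_UP")
  expect_equal(unname(codes["StdHR"]), "SIG_UP")
})
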