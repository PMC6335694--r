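test_that("read_rr_table parses delimited files, with and without header", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,rr_ms,label", "800,800,N", "1600,800,N", "2400,800,N"), f)
  s <- read_rr_table(f, subject_id = "s1", condition = "rest")
  expect_equal(nrow(s), 3L)
  expect_true(all(s$label == "N"))
  expect_equal(s$rr_ms, rep(800, 3))

  # headerless, label column absent -> labels default to N
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("900\t900", "1800\t900"), f2)
  s2 <- read_rr_table(f2, subject_id = "s2", condition = "stress")
  expect_equal(s2$label, c("N", "N"))
  expect_equal(s2$condition, c("stress", "stress"))
})

test_that("read_rr_table rejects invalid rows, naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,rr_ms", "800,800", "700,800"), f)
  expect_error(read_rr_table(f), "line 3")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("800,800", "1600,-5"), f2)
  expect_error(read_rr_table(f2), "Non-positive")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("800,800", "1600,abc"), f3)
  expect_error(read_rr_table(f3), "line 2")
})

test_that("write/read round-trips a valid series exactly", {
  s <- generate_rr_series(seed = 3, duration_s = 60)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rr_table(s, f)
  s2 <- read_rr_table(f, subject_id = s$subject[1], condition = s$condition[1])
  expect_equal(s2$time_ms, s$time_ms)
  expect_equal(s2$rr_ms, s$rr_ms)
  expect_equal(s2$label, s$label)
})

test_that("nn_ratio counts intervals with both delimiting beats normal", {
  all_n <- make_rr(rep(800, 100))
  expect_identical(nn_ratio(all_n), 1)

  # one interior non-N beat affects its two adjacent intervals
  lab <- rep("N", 10)
  lab[5] <- "V"
  s <- make_rr(rep(800, 10), label = lab)
  expect_identical(nn_ratio(s), 0.8)

  none <- make_rr(rep(800, 5), label = "V")
  expect_identical(nn_ratio(none), 0)

  expect_error(nn_ratio(make_rr(numeric(0))), "empty")
})

test_that("quality gate boundary is inclusive and threshold validated", {
  lab <- rep("N", 20)
  lab[10] <- "V"     # ratio 0.9 exactly
  s <- make_rr(rep(800, 20), label = lab)
  expect_identical(nn_ratio(s), 0.9)
  expect_true(quality_gate(s, 0.90))
  expect_false(quality_gate(s, 0.95))
  expect_error(quality_gate(s, 0), "threshold")
  expect_error(quality_gate(s, 1.2), "threshold")
})

test_that("derive_nn drops both intervals around a non-N beat and is idempotent", {
  s <- make_rr(rep(800, 30))
  expect_equal(derive_nn(s)$nn_ms, s$rr_ms)

  lab <- rep("N", 30)
  lab[15] <- "V"
  s2 <- make_rr(rep(800, 30), label = lab)
  nn <- derive_nn(s2)
  expect_equal(nrow(nn), 28L)
  expect_false(any(nn$time_ms %in% s2$time_ms[c(15, 16)]))

  # idempotent, and the derived series is all-NN by construction
  expect_identical(derive_nn(nn), nn)
  renn <- make_rr(nn$nn_ms)
  expect_identical(nn_ratio(renn), 1)

  bad <- make_rr(rep(800, 10), label = c(rep("V", 3), rep("N", 7)))
  expect_error(derive_nn(bad), "ratio")
})
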