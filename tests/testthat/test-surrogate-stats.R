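test_that("Wilcoxon exact branch matches enumeration, including the 6-pair case", {
  p <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(p$p_value, 2 / 64)
  expect_equal(p$method, "exact")

  x <- c(3, 1, 4, 1, 5)
  expect_warning(out <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(out$p_value, 1)

  set.seed(41)
  for (n in 5:12) {
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(
      wilcoxon_signed_rank(x, y)$p_value,
      oracle_wilcoxon_exact(x, y),
      tolerance = 1e-12
    )
    # tied |differences| still enumerate exactly
    xt <- round(rnorm(n), 0)
    yt <- round(rnorm(n), 0)
    d <- xt - yt
    if (sum(d != 0) >= 1) {
      expect_equal(
        wilcoxon_signed_rank(xt, yt)$p_value,
        oracle_wilcoxon_exact(xt, yt),
        tolerance = 1e-12
      )
    }
  }
})

test_that("exact branch agrees with stats::wilcox.test when tie-free", {
  set.seed(42)
  x <- rnorm(10)
  y <- rnorm(10)
  expect_equal(
    wilcoxon_signed_rank(x, y)$p_value,
    wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  )
  # large-n branch uses the corrected normal approximation
  x2 <- rnorm(30)
  y2 <- rnorm(30)
  out <- wilcoxon_signed_rank(x2, y2)
  expect_equal(out$method, "normal")
  expect_equal(out$p_value,
               wilcox.test(x2 - y2, exact = FALSE, correct = TRUE)$p.value)
})

test_that("Spearman matches the rank-then-product-moment oracle", {
  x <- 1:8
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, rev(x))$rho, -1)
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(2, 1, 3, 3, 5, 4)
  expect_equal(spearman(xt, yt)$rho, oracle_spearman(xt, yt), tolerance = 1e-12)
  expect_true(is.na(spearman(rep(1, 6), 1:6)$rho))
})

test_that("trend codes follow the stated mapping", {
  expect_equal(encode_trend(0.03, 10, 8), "SIG_DOWN")
  expect_equal(encode_trend(0.20, 10, 12), "NS_UP")
  expect_equal(encode_trend(0.03, 10, 12), "SIG_UP")
  expect_equal(encode_trend(0.20, 10, 8), "NS_DOWN")
  expect_equal(encode_trend(0.03, 10, 10), "SIG_UP")   # tie counts as up
  expect_equal(encode_trend(0.03, 10, 8, computable = FALSE), "NC")
})

test_that("Bland-Altman reports median bias and mean +/- 1.96 SD limits", {
  x <- c(10, 12, 14, 16)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba5 <- bland_altman(x, x - 5)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$loa_high - ba5$loa_low, 0)

  s <- c(100, 110, 120, 130, 140)
  u <- c(98, 113, 118, 135, 137)
  d <- s - u
  ba <- bland_altman(s, u)
  expect_equal(ba$bias, median(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})
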