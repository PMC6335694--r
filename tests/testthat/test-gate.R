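test_that("the gate on the published reference tables keeps exactly six features", {
  g <- surrogate_gate(reference_trend_codes(), reference_rho_table())
  passing <- g$feature[which(g$pass)]
  expect_setequal(passing,
                  c("MeanNN", "StdNN", "MeanHR", "StdHR", "HF", "SD2"))
  expect_equal(sum(g$pass, na.rm = TRUE), 6L)
  expect_false(any(is.na(g$pass)))

  # failure reasons are informative
  expect_match(g$reasons[g$feature == "RMSSD"], "not significant")
  expect_match(g$reasons[g$feature == "LF"], "not computable at 60 s")

  gl <- glance(g)
  expect_equal(gl$n_pass, 6L)
  td <- tidy(g)
  expect_false(inherits(td, "surrogate_gate"))
})

test_that("the reference trend column at 5 min shows 18 significant, 12 down, 6 up", {
  tc <- reference_trend_codes()
  five <- tc[tc$scale_s == 300, ]
  expect_equal(nrow(five), 23L)
  expect_equal(sum(five$code %in% c("SIG_DOWN", "SIG_UP")), 18L)
  expect_equal(sum(five$code == "SIG_DOWN"), 12L)
  expect_setequal(
    five$feature[five$code == "SIG_UP"],
    c("MeanHR", "StdHR", "RPlmean", "REC", "RPadet", "ShanEn")
  )
})

test_that("scale retention keeps 180/120/60 and drops 30 on the reference tables", {
  ret <- scale_retention(reference_trend_codes(), reference_rho_table())
  expect_equal(attr(ret, "retained_scales"), c(180L, 120L, 60L))
  expect_equal(ret$n_pass[ret$scale_s == 60], 6L)
  expect_equal(ret$n_pass[ret$scale_s == 30], 2L)

  # min_pass 1 retains everything; an unreachable min_pass retains nothing
  ret1 <- scale_retention(reference_trend_codes(), reference_rho_table(),
                          min_pass = 1)
  expect_true(all(ret1$retained))
  expect_warning(
    ret99 <- scale_retention(reference_trend_codes(), reference_rho_table(),
                             min_pass = 99),
    "nothing retained"
  )
  expect_false(any(ret99$retained))
})

test_that("missing gate inputs yield undetermined verdicts naming the gap", {
  tc <- reference_trend_codes()
  rt <- reference_rho_table()
  tc_miss <- tc[!(tc$feature == "MeanNN" & tc$scale_s == 120), ]
  g <- surrogate_gate(tc_miss, rt)
  row <- g[g$feature == "MeanNN", ]
  expect_true(is.na(row$pass))
  expect_match(row$reasons, "missing trend entry at 120 s")
})

test_that("borderline StdHR correlation at 30 s fails that scale only", {
  rt <- reference_rho_table()
  row <- rt[rt$feature == "StdHR" & rt$scale_s == 30 & rt$phase == "rest", ]
  expect_equal(row$rho, 0.635)
  g30 <- surrogate_gate(reference_trend_codes(), rt,
                        retained_scales = c(180, 120, 60, 30))
  expect_false(g30$pass[g30$feature == "StdHR"])
  expect_match(g30$reasons[g30$feature == "StdHR"], "0.635")
  g <- surrogate_gate(reference_trend_codes(), rt)
  expect_true(g$pass[g$feature == "StdHR"])
})
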