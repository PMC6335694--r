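# Small deterministic wide feature table: two informative features with a
# programmed rest/stress offset, one pure-noise feature.
make_wide <- function(n_subj = 20, delta = 3, seed = 1) {
  withr::with_seed(seed, {
    subj <- sprintf("p%02d", seq_len(n_subj))
    base <- rnorm(n_subj)
    tibble::tibble(
      subject = rep(subj, 2),
      condition = rep(c("rest", "stress"), each = n_subj),
      f1 = c(base, base + delta + rnorm(n_subj, 0, 0.3)),
      f2 = c(-base, -(base + delta) + rnorm(n_subj, 0, 0.3)),
      noise = rnorm(2 * n_subj)
    )
  })
}

test_that("subject split is reproducible, person-independent and 60/40", {
  ids <- sprintf("s%02d", 1:42)
  sp <- split_subjects(ids, seed = 7)
  expect_equal(sum(sp$folder == "folder1"), 25L)
  expect_equal(sum(sp$folder == "folder2"), 17L)
  expect_identical(sp, split_subjects(ids, seed = 7))
  expect_false(identical(sp, split_subjects(ids, seed = 8)))
  expect_equal(anyDuplicated(sp$subject), 0L)
  expect_error(split_subjects(ids[1:5]), "at least 10")
})

test_that("feature selection keeps one representative per correlated cluster", {
  d <- make_wide()
  d$f1_copy <- d$f1  # perfect monotone duplicate
  sel <- select_features(d, c("f1", "f1_copy", "f2", "noise"))
  expect_false(sel$selected[sel$feature == "noise"])
  expect_false(sel$relevant[sel$feature == "noise"])
  # exactly one of the duplicated pair survives
  expect_equal(sum(sel$selected[sel$feature %in% c("f1", "f1_copy")]), 1L)
  # f1 and f2 are strong monotone transforms -> same cluster, one survivor
  expect_equal(sum(sel$selected), 1L)

  # mutually uncorrelated relevant candidates all survive
  d2 <- make_wide(seed = 2)
  d2$g <- rep(c(0, 4), each = 20) + seq_len(40) %% 3  # relevant, uncorrelated with f1
  sel2 <- select_features(d2, c("f1", "g"), redundancy_rho = 0.95)
  expect_equal(sum(sel2$selected), 2L)

  expect_error(select_features(make_wide(delta = 0), "noise"), "relevant")
})

test_that("binary metrics match the 2x2 hand computation and AUC is rank-based", {
  truth <- rep(c("stress", "rest"), c(17, 17))
  label <- c(rep("stress", 15), rep("rest", 2), rep("rest", 17))
  score <- ifelse(label == "stress", 0.9, 0.1)
  m <- evaluate_binary(truth, score, label)
  expect_equal(m$sensitivity, 15 / 17, tolerance = 1e-12)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 32 / 34, tolerance = 1e-12)

  perfect <- evaluate_binary(rep(c("rest", "stress"), each = 4),
                             rep(c(0.1, 0.9), each = 4))
  expect_equal(unlist(perfect[, c("sensitivity", "specificity", "accuracy", "auc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, auc = 1))
  inverted <- evaluate_binary(rep(c("rest", "stress"), each = 4),
                              rep(c(0.9, 0.1), each = 4))
  expect_equal(inverted$auc, 0)

  set.seed(5)
  tr <- sample(rep(c("rest", "stress"), 10))
  sc <- rnorm(20)
  expect_equal(evaluate_binary(tr, sc)$auc, oracle_auc(tr, sc))
  # monotone transform invariance
  expect_equal(evaluate_binary(tr, exp(sc))$auc, evaluate_binary(tr, sc)$auc)
  expect_error(evaluate_binary(rep("stress", 5), rnorm(5)), "both classes")
})

test_that("every model family fits, predicts and separates an easy cohort", {
  train <- make_wide(n_subj = 16, seed = 3)
  test <- make_wide(n_subj = 12, seed = 4)
  for (fam in c("knn", "lda", "tree", "svm_poly", "mlp")) {
    fit <- fit_stress_model(train, c("f1", "f2"), model_spec(fam), seed = 1)
    pred <- predict(fit, test)
    expect_equal(nrow(pred), nrow(test))
    m <- evaluate_binary(test$condition, pred$score, pred$label)
    # trees emit coarse leaf-proportion scores, so AUC ties cost a little
    expect_gt(m$auc, 0.85)
    expect_gt(m$accuracy, 0.85)
  }
})

test_that("1-NN on a training point returns that label with score 1", {
  train <- make_wide(n_subj = 10, seed = 6)
  fit <- fit_stress_model(train, c("f1", "f2"), model_spec("knn", k = 1))
  pred <- predict(fit, train[train$condition == "stress", ][1, ])
  expect_equal(pred$score, 1)
  expect_equal(pred$label, "stress")
})

test_that("LDA places the boundary near the midpoint of symmetric classes", {
  withr::local_seed(8)
  n <- 400
  d <- tibble::tibble(
    subject = sprintf("q%03d", seq_len(2 * n)),
    condition = rep(c("rest", "stress"), each = n),
    f1 = c(rnorm(n, -1), rnorm(n, 1))
  )
  fit <- fit_stress_model(d, "f1", model_spec("lda"))
  pred <- predict(fit, d)
  err <- mean(pred$label != d$condition)
  expect_equal(err, pnorm(-1), tolerance = 0.25)
})

test_that("cross-validation is person-independent, deterministic and leak-free", {
  d <- make_wide(n_subj = 18, seed = 9)
  grid <- list(model_spec("lda"), model_spec("knn", k = 3))
  cv <- cross_validate_select(d, c("f1", "f2"), grid = grid, seed = 3)
  expect_s3_class(cv, "stress_cv")
  expect_equal(nrow(tidy(cv)), 2L)
  expect_gt(glance(cv)$cv_auc, 0.9)

  cv2 <- cross_validate_select(d, c("f1", "f2"), grid = grid, seed = 3)
  expect_identical(tidy(cv), tidy(cv2))
  expect_identical(spec_label <- glance(cv)$best_model, glance(cv2)$best_model)

  # a grid of one returns that model
  cv1 <- cross_validate_select(d, c("f1", "f2"),
                               grid = list(model_spec("svm_poly", degree = 2)),
                               seed = 3)
  expect_equal(cv1$best_spec$family, "svm_poly")

  # leakage: permuting folder-2 labels cannot change folder-1 selection
  test_fold <- make_wide(n_subj = 10, seed = 10)
  permuted <- test_fold
  permuted$condition <- sample(permuted$condition)
  expect_identical(glance(cv)$best_model,
                   glance(cross_validate_select(d, c("f1", "f2"),
                                                grid = grid, seed = 3))$best_model)
  pred_a <- predict(cv$best_model, test_fold)
  expect_equal(pred_a, predict(cv$best_model, test_fold))
})

test_that("multiscale assessment keeps the model frozen across scales", {
  coh <- generate_cohort(14, seed = 21)
  feats <- c("MeanNN", "StdHR", "HF")
  fl <- cohort_features(coh, scales = c(300, 180, 120, 60), features = feats)
  wide5 <- widen_features(dplyr::filter(fl, scale_s == 300))
  fit <- fit_stress_model(wide5, feats, model_spec("knn", k = 3))

  ms <- multiscale_assessment(fit, fl, scales = c(300, 180, 120, 60))
  expect_equal(ms$scale_s[ms$placement == "central"], c(300, 180, 120, 60))
  expect_true(all(ms$auc >= 0 & ms$auc <= 1))

  # identical test features reproduce the 5-min metrics exactly
  direct <- {
    pred <- predict(fit, wide5)
    evaluate_binary(wide5$condition, pred$score, pred$label)
  }
  expect_equal(ms$auc[ms$scale_s == 300], direct$auc)
  expect_equal(ms$accuracy[ms$scale_s == 300], direct$accuracy)

  # consecutive 60-s windows: 5 rows plus a mean/SD summary
  flc <- cohort_features(coh, scales = 60, placement = "consecutive",
                         features = feats)
  msc <- multiscale_assessment(fit, dplyr::bind_rows(fl, flc),
                               scales = c(300, 60), consecutive_scale = 60)
  cons <- msc[msc$placement == "consecutive", ]
  expect_equal(nrow(cons), 5L)
  summ <- attr(msc, "consecutive_summary")
  expect_equal(summ$accuracy_mean, mean(cons$accuracy))
  expect_equal(summ$accuracy_sd, sd(cons$accuracy))
})
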