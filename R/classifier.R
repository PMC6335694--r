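# Person-independent stress classification harness: subject-level split,
# relevance/redundancy feature selection on benchmark features, model grid
# with person-independent cross-validation, and the train-on-short /
# test-on-ultra-short assessment.

#' Split subjects into training/validation and test folders
#'
#' Random person-independent split: both conditions of a subject always land
#' in the same folder, so the test folder is fully independent of training.
#'
#' @param subjects Character vector of subject ids (or a data frame with a
#'   `subject` column).
#' @param fraction Fraction of subjects assigned to folder 1 (default 0.6).
#' @param seed Integer seed making the split reproducible.
#' @return Tibble `subject`, `folder` (`"folder1"` / `"folder2"`).
#' @examples
#' split_subjects(sprintf("s%02d", 1:42), seed = 7) |> dplyr::count(folder)
#' @export
split_subjects <- function(subjects, fraction = 0.6, seed = 1) {
  if (is.data.frame(subjects)) subjects <- subjects$subject
  subjects <- unique(as.character(subjects))
  n <- length(subjects)
  if (n < 10L) abort("Need at least 10 subjects to split.")
  n1 <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, n1))
  tibble(
    subject = subjects,
    folder = ifelse(seq_len(n) %in% idx, "folder1", "folder2")
  )
}

#' Relevance/redundancy feature selection on benchmark features
#'
#' Two-stage selection on the training folder's 5-min features: relevance
#' keeps candidates whose paired rest-vs-stress Wilcoxon p-value is below
#' `alpha`; redundancy links features whose pairwise Spearman `|rho|`
#' exceeds `redundancy_rho`, takes connected components of that graph and
#' keeps one representative per component - the most relevant (lowest p),
#' ties broken lexicographically.
#'
#' @param data Wide feature tibble for folder 1 at the benchmark scale
#'   (columns `subject`, `condition` and the candidate features).
#' @param candidates Candidate feature names (typically the surrogate-gate
#'   survivors).
#' @param alpha Relevance significance level.
#' @param redundancy_rho Redundancy correlation threshold.
#' @return Tibble `feature`, `p_value`, `relevant`, `cluster`, `selected`.
#'   Errors if no candidate is relevant.
#' @export
select_features <- function(data, candidates, alpha = 0.05,
                            redundancy_rho = 0.7) {
  assert_cols(data, c("subject", "condition", candidates), "data")
  pvals <- purrr::map_dbl(candidates, function(f) {
    wide <- data |>
      select(all_of(c("subject", "condition", f))) |>
      pivot_wider(names_from = "condition", values_from = all_of(f))
    suppressWarnings(wilcoxon_signed_rank(wide$rest, wide$stress)$p_value)
  })
  relevant <- candidates[is.finite(pvals) & pvals < alpha]
  if (length(relevant) == 0L) {
    abort("No candidate feature is relevant on folder 1 at the given alpha.")
  }
  p_rel <- pvals[match(relevant, candidates)]
  # redundancy graph over relevant features
  k <- length(relevant)
  adj <- diag(TRUE, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        rho <- spearman(data[[relevant[i]]], data[[relevant[j]]])$rho
        if (is.finite(rho) && abs(rho) > redundancy_rho) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  cluster <- connected_components(adj)
  selected <- vapply(unique(cluster), function(cl) {
    members <- which(cluster == cl)
    members[order(p_rel[members], relevant[members])][1L]
  }, integer(1L))
  out <- tibble(
    feature = candidates,
    p_value = pvals,
    relevant = candidates %in% relevant,
    cluster = NA_integer_,
    selected = FALSE
  )
  out$cluster[match(relevant, out$feature)] <- cluster
  out$selected[match(relevant[selected], out$feature)] <- TRUE
  out
}

connected_components <- function(adj) {
  k <- nrow(adj)
  comp <- rep(NA_integer_, k)
  current <- 0L
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    current <- current + 1L
    frontier <- i
    while (length(frontier) > 0L) {
      comp[frontier] <- current
      nbrs <- which(apply(adj[frontier, , drop = FALSE], 2L, any))
      frontier <- setdiff(nbrs, which(!is.na(comp)))
    }
  }
  comp
}

#' Model specification for the stress classifier grid
#'
#' @param family One of `"knn"`, `"lda"`, `"tree"`, `"svm_poly"`, `"mlp"`.
#' @param ... Family hyperparameters: `k` (knn, 1/3/5); `degree`
#'   (svm_poly, 1-5); `pruning_conf` (tree, 0.05-0.5) and `min_leaf`
#'   (tree, 2-20); `learning_rate` (mlp, 0.3-0.9), `momentum` (mlp, 0.2-1)
#'   and optionally `epochs`.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(family = c("knn", "lda", "tree", "svm_poly", "mlp"),
                       ...) {
  family <- match.arg(family)
  pars <- list(...)
  check_range <- function(name, lo, hi) {
    if (!is.null(pars[[name]]) && (pars[[name]] < lo || pars[[name]] > hi)) {
      abort(sprintf("`%s` must lie in [%s, %s].", name, lo, hi))
    }
  }
  switch(family,
    knn = {
      pars$k <- pars$k %||% 3L
      if (!pars$k %in% c(1L, 3L, 5L)) abort("knn `k` must be 1, 3 or 5.")
    },
    svm_poly = {
      pars$degree <- pars$degree %||% 1L
      check_range("degree", 1, 5)
    },
    tree = {
      pars$pruning_conf <- pars$pruning_conf %||% 0.25
      pars$min_leaf <- pars$min_leaf %||% 2L
      check_range("pruning_conf", 0.05, 0.5)
      check_range("min_leaf", 2, 20)
    },
    mlp = {
      pars$learning_rate <- pars$learning_rate %||% 0.3
      pars$momentum <- pars$momentum %||% 0.2
      pars$epochs <- pars$epochs %||% 500L
      check_range("learning_rate", 0.3, 0.9)
      check_range("momentum", 0.2, 1)
    },
    lda = NULL
  )
  structure(list(family = family, pars = pars), class = "model_spec")
}

# Effective-complexity rank used only as the final tie-break (simpler first).
spec_complexity <- function(spec) {
  switch(spec$family,
    lda = 1,
    knn = 2,
    tree = 3,
    svm_poly = 3 + spec$pars$degree / 10,
    mlp = 5
  )
}

spec_label <- function(spec) {
  p <- spec$pars
  extra <- switch(spec$family,
    knn = sprintf("k=%d", p$k),
    svm_poly = sprintf("degree=%d", p$degree),
    tree = sprintf("conf=%.2f,min_leaf=%d", p$pruning_conf, p$min_leaf),
    mlp = sprintf("lr=%.1f,mom=%.1f", p$learning_rate, p$momentum),
    lda = ""
  )
  if (extra == "") spec$family else paste0(spec$family, "(", extra, ")")
}

#' Default hyperparameter grid over the five model families
#'
#' kNN with k in {1, 3, 5}; LDA; polynomial-kernel SVM with degree 1-5;
#' pruned decision trees over a pruning-confidence x minimum-leaf grid; and
#' a single-hidden-layer (3 unit) perceptron over a learning-rate x
#' momentum grid.
#'
#' @return A list of [model_spec()] objects.
#' @export
model_grid <- function() {
  c(
    purrr::map(c(1L, 3L, 5L), \(k) model_spec("knn", k = k)),
    list(model_spec("lda")),
    purrr::map(1:5, \(d) model_spec("svm_poly", degree = d)),
    purrr::map(c(0.05, 0.25, 0.5), \(cf) model_spec("tree", pruning_conf = cf, min_leaf = 2L)),
    purrr::map(c(5L, 10L, 20L), \(ml) model_spec("tree", pruning_conf = 0.25, min_leaf = ml)),
    purrr::pmap(
      expand.grid(lr = c(0.3, 0.6, 0.9), mom = c(0.2, 0.6, 1.0)),
      \(lr, mom) model_spec("mlp", learning_rate = lr, momentum = mom)
    )
  )
}

#' Fit a stress classifier on standardized features
#'
#' Standardizes the features with training-set statistics only (z-scores),
#' then fits the requested family. The positive class is `"stress"`;
#' continuous scores are the stress vote fraction (kNN), posterior
#' probability (LDA), leaf stress proportion (tree), oriented decision
#' value (SVM) or output activation (MLP), with hard labels at 0.5 (0 for
#' the SVM margin).
#'
#' @param data Wide feature tibble with a `condition` column
#'   (`rest`/`stress`) and the feature columns.
#' @param features Feature names used by the model.
#' @param spec [model_spec()].
#' @param seed Seed for stochastic fitters (MLP initialisation).
#' @return A `"stress_model"` object.
#' @export
fit_stress_model <- function(data, features, spec, seed = 1) {
  assert_cols(data, c("condition", features), "data")
  x <- as.matrix(data[, features, drop = FALSE])
  if (any(!is.finite(x))) {
    bad <- which(!stats::complete.cases(x))[1L]
    abort(sprintf("Non-finite feature value in training instance %d.", bad))
  }
  y <- factor(data$condition, levels = c("rest", "stress"))
  centers <- colMeans(x)
  sds <- apply(x, 2L, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  xs <- scale(x, center = centers, scale = sds)
  fit <- switch(spec$family,
    knn = list(x = xs, y = y),
    lda = MASS::lda(xs, grouping = y),
    tree = {
      df <- data.frame(y = y, xs)
      rpart::rpart(
        y ~ ., data = df, method = "class",
        parms = list(split = "information"),
        control = rpart::rpart.control(
          minsplit = 2L * spec$pars$min_leaf,
          minbucket = spec$pars$min_leaf,
          cp = tree_cp(spec$pars$pruning_conf),
          xval = 0L
        )
      )
    },
    svm_poly = e1071::svm(
      xs, y, kernel = "polynomial", degree = spec$pars$degree,
      coef0 = 1, scale = FALSE
    ),
    mlp = with_seed(seed, mlp_train(
      xs, as.numeric(y == "stress"),
      hidden = 3L,
      lr = spec$pars$learning_rate,
      momentum = spec$pars$momentum,
      epochs = spec$pars$epochs
    ))
  )
  structure(
    list(spec = spec, fit = fit, features = features,
         centers = centers, sds = sds),
    class = "stress_model"
  )
}

# Monotone map from C4.5-style pruning confidence (smaller = heavier
# pruning) onto the tree's cost-complexity parameter.
tree_cp <- function(pruning_conf) {
  0.01 + 0.5 * (0.5 - pruning_conf)
}

#' @export
predict.stress_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  if (any(!is.finite(x))) {
    bad <- which(!stats::complete.cases(x))[1L]
    abort(sprintf("Non-finite feature value in test instance %d.", bad))
  }
  xs <- scale(x, center = object$centers, scale = object$sds)
  spec <- object$spec
  score <- switch(spec$family,
    knn = knn_scores(object$fit$x, object$fit$y, xs, k = spec$pars$k),
    lda = unname(predict(object$fit, xs)$posterior[, "stress"]),
    tree = {
      df <- data.frame(xs)
      unname(predict(object$fit, df, type = "prob")[, "stress"])
    },
    svm_poly = {
      dv <- attr(predict(object$fit, xs, decision.values = TRUE),
                 "decision.values")
      v <- as.numeric(dv[, 1L])
      if (grepl("^stress/", colnames(dv)[1L])) v else -v
    },
    mlp = mlp_forward(object$fit, xs)
  )
  threshold <- if (spec$family == "svm_poly") 0 else 0.5
  tibble(
    score = score,
    label = ifelse(score >= threshold, "stress", "rest")
  )
}

# Fraction of stress votes among the k nearest training points
# (Euclidean distance on the standardized features; distance ties broken
# by training order, deterministically).
knn_scores <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1L, function(row) {
    d <- sqrt(colSums((t(train_x) - row)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    mean(train_y[nn] == "stress")
  })
}

# Minimal single-hidden-layer perceptron (logistic activations) trained by
# per-instance stochastic gradient descent with momentum on squared error:
# the classical configuration whose learning-rate/momentum grid the model
# specification exposes.
mlp_train <- function(x, y, hidden = 3L, lr = 0.3, momentum = 0.2,
                      epochs = 500L) {
  n_in <- ncol(x)
  w1 <- matrix(runif((n_in + 1L) * hidden, -0.5, 0.5), n_in + 1L, hidden)
  w2 <- runif(hidden + 1L, -0.5, 0.5)
  v1 <- w1 * 0
  v2 <- w2 * 0
  sigm <- function(z) 1 / (1 + exp(-z))
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    for (i in seq_len(n)) {
      xi <- c(1, x[i, ])
      h <- sigm(drop(xi %*% w1))
      hb <- c(1, h)
      o <- sigm(sum(hb * w2))
      delta_o <- (o - y[i]) * o * (1 - o)
      delta_h <- delta_o * w2[-1L] * h * (1 - h)
      g2 <- delta_o * hb
      g1 <- outer(xi, delta_h)
      v2 <- momentum * v2 - lr * g2
      v1 <- momentum * v1 - lr * g1
      w2 <- w2 + v2
      w1 <- w1 + v1
    }
  }
  list(w1 = w1, w2 = w2)
}

mlp_forward <- function(fit, x) {
  sigm <- function(z) 1 / (1 + exp(-z))
  apply(x, 1L, function(row) {
    h <- sigm(drop(c(1, row) %*% fit$w1))
    sigm(sum(c(1, h) * fit$w2))
  })
}

#' Binary classification metrics with stress as the positive class
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy and AUC.
#' The AUC is the Mann-Whitney rank statistic on the continuous scores
#' (tie-aware), so it is invariant under monotone score transforms.
#'
#' @param truth True conditions (`"rest"`/`"stress"`).
#' @param score Continuous classifier scores (larger = more stress-like).
#' @param label Optional hard labels; defaults to thresholding `score`
#'   at 0.5.
#' @return One-row tibble `sensitivity`, `specificity`, `accuracy`, `auc`,
#'   `n`.
#' @examples
#' evaluate_binary(rep(c("rest", "stress"), each = 3), c(.1, .2, .3, .7, .8, .9))
#' @export
evaluate_binary <- function(truth, score, label = NULL) {
  truth <- as.character(truth)
  if (length(unique(truth)) < 2L) {
    abort("`truth` must contain both classes.")
  }
  label <- label %||% ifelse(score >= 0.5, "stress", "rest")
  pos <- truth == "stress"
  tp <- sum(label == "stress" & pos)
  fn <- sum(label == "rest" & pos)
  tn <- sum(label == "rest" & !pos)
  fp <- sum(label == "stress" & !pos)
  r <- rank(score)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(truth),
    auc = auc,
    n = length(truth)
  )
}

#' Person-independent cross-validated model selection
#'
#' Partitions folder-1 *subjects* (never instances) into `k` folds, fits
#' every specification in the grid on each training fold and scores the
#' held-out fold; the best model maximises mean cross-validated AUC, ties
#' broken by accuracy and then by the simpler family. A degenerate fold
#' whose training part contains a single class triggers one refold with a
#' new seed (logged via a message).
#'
#' @param data Wide folder-1 feature tibble (`subject`, `condition`,
#'   features) at the benchmark scale.
#' @param features Feature names entering the models.
#' @param grid List of [model_spec()]s (default [model_grid()]).
#' @param k Number of folds (default 3).
#' @param seed Seed controlling folds and stochastic fits.
#' @return A `"stress_cv"` object: tibble of per-spec CV results with the
#'   winning spec, and a final model refitted on all of folder 1.
#' @export
cross_validate_select <- function(data, features, grid = model_grid(),
                                  k = 3L, seed = 1) {
  assert_cols(data, c("subject", "condition", features), "data")
  subjects <- unique(data$subject)
  folds <- make_folds(subjects, k, seed)
  for (attempt in 1:5) {
    degenerate <- any(purrr::map_lgl(seq_len(k), function(f) {
      train <- data[data$subject %in% subjects[folds != f], ]
      length(unique(train$condition)) < 2L
    }))
    if (!degenerate) break
    seed <- seed + 1L
    inform(sprintf("Degenerate fold; refolding with seed %d.", seed))
    folds <- make_folds(subjects, k, seed)
  }
  results <- purrr::imap(grid, function(spec, i) {
    fold_metrics <- purrr::map(seq_len(k), function(f) {
      train <- data[data$subject %in% subjects[folds != f], ]
      test <- data[data$subject %in% subjects[folds == f], ]
      fit <- fit_stress_model(train, features, spec, seed = seed + f)
      pred <- predict(fit, test)
      evaluate_binary(test$condition, pred$score, pred$label)
    }) |> list_rbind()
    tibble(
      model = spec_label(spec),
      family = spec$family,
      cv_auc = mean(fold_metrics$auc),
      cv_accuracy = mean(fold_metrics$accuracy),
      complexity = spec_complexity(spec),
      spec_id = i
    )
  }) |> list_rbind()
  best_idx <- results |>
    arrange(desc(.data$cv_auc), desc(.data$cv_accuracy), .data$complexity) |>
    slice(1L) |>
    pull("spec_id")
  best_spec <- grid[[best_idx]]
  final <- fit_stress_model(data, features, best_spec, seed = seed)
  structure(
    list(results = results, best_spec = best_spec, best_model = final,
         features = features, k = k, seed = seed),
    class = "stress_cv"
  )
}

make_folds <- function(subjects, k, seed) {
  n <- length(subjects)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' @exportS3Method generics::tidy
tidy.stress_cv <- function(x, ...) {
  x$results |> arrange(desc(.data$cv_auc), desc(.data$cv_accuracy))
}

#' @exportS3Method generics::glance
glance.stress_cv <- function(x, ...) {
  best <- x$results |>
    filter(.data$model == spec_label(x$best_spec)) |>
    slice(1L)
  tibble(
    best_model = best$model,
    cv_auc = best$cv_auc,
    cv_accuracy = best$cv_accuracy,
    n_specs = nrow(x$results),
    k = x$k,
    features = paste(x$features, collapse = ",")
  )
}

#' Assess a frozen benchmark-trained model across time scales
#'
#' The model is trained once on 5-min features and never refitted; its
#' performance is then measured on the test folder's features at each
#' shorter central-window scale, and (optionally) on every consecutive
#' window at one scale, summarised as mean and SD across windows.
#'
#' @param model `"stress_model"` (or the `best_model` of a `"stress_cv"`).
#' @param features_long Long feature tibble for the *test* folder (central
#'   windows; include consecutive windows for `consecutive_scale`).
#' @param scales Central-window scales to evaluate (default
#'   `c(300, 180, 120, 60)`).
#' @param consecutive_scale Scale (seconds) at which consecutive windows
#'   are evaluated per-window; `NULL` to skip.
#' @return A `"multiscale_eval"` tibble: `placement`, `scale_s`, `window`
#'   and the [evaluate_binary()] metrics; the mean/SD summary over
#'   consecutive windows is kept in `attr(, "consecutive_summary")`.
#'   Scales whose required features are masked are skipped with a warning.
#' @export
multiscale_assessment <- function(model, features_long,
                                  scales = c(300, 180, 120, 60),
                                  consecutive_scale = NULL) {
  if (inherits(model, "stress_cv")) model <- model$best_model
  wide_all <- widen_features(features_long)
  eval_at <- function(df, placement, scale_s, window) {
    pred <- predict(model, df)
    bind_cols(
      tibble(placement = placement, scale_s = scale_s, window = window),
      evaluate_binary(df$condition, pred$score, pred$label)
    )
  }
  has_window <- "window" %in% names(wide_all)
  central <- purrr::map(scales, function(s) {
    df <- wide_all |> filter(.data$scale_s == s)
    if (has_window) df <- df |> filter(.data$window == "central")
    if (nrow(df) == 0L || any(!is.finite(as.matrix(df[, model$features])))) {
      warn(sprintf("Scale %d s skipped: required features unavailable.", s))
      return(NULL)
    }
    eval_at(df, "central", s, "central")
  }) |> list_rbind()
  out <- central
  summary_tbl <- NULL
  if (!is.null(consecutive_scale)) {
    dfc <- wide_all |>
      filter(.data$scale_s == consecutive_scale, .data$window != "central")
    wins <- as.character(sort(unique(as.integer(dfc$window))))
    per_win <- purrr::map(wins, function(w) {
      df <- dfc |> filter(.data$window == w)
      if (nrow(df) == 0L) return(NULL)
      eval_at(df, "consecutive", consecutive_scale, w)
    }) |> list_rbind()
    out <- bind_rows(out, per_win)
    summary_tbl <- per_win |>
      summarise(across(c("sensitivity", "specificity", "accuracy", "auc"),
                       list(mean = mean, sd = sd)))
  }
  structure(out, consecutive_summary = summary_tbl,
            class = c("multiscale_eval", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.multiscale_eval <- function(object, ...) {
  df <- object |>
    filter(.data$placement == "central") |>
    pivot_longer(c("sensitivity", "specificity", "accuracy", "auc"),
                 names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$scale_s, y = .data$value,
                 colour = .data$metric)) +
    geom_line() +
    geom_point() +
    scale_x_reverse(breaks = sort(unique(df$scale_s))) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Excerpt length (s)", y = "Metric",
         title = "Frozen 5-min model assessed on shorter excerpts") +
    theme_minimal()
}
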