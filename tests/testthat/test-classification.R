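test_that("bagged trees separate separable data and are deterministic", {
  df <- separable_dataset(n = 120, pos_frac = 0.3, seed = 2)
  model <- train_dtb(df, n_trees = 25, seed = 1)
  scores <- predict(model, df)
  cm <- evaluate(scores, df$label)
  expect_equal(metrics(cm)[["ACC"]], 1.0)

  m1 <- train_dtb(df, n_trees = 1, seed = 3)
  expect_length(m1$trees, 1L)
  expect_true(all(predict(m1, df) %in% c(0, 1)))

  m_a <- train_dtb(df, n_trees = 10, seed = 5)
  m_b <- train_dtb(df, n_trees = 10, seed = 5)
  expect_identical(predict(m_a, df), predict(m_b, df))

  single <- df[df$label == 0L, ]
  expect_error(train_dtb(single), "single class")
})

test_that("RUSBoost scores rare positives that a majority vote misses", {
  df <- separable_dataset(n = 200, pos_frac = 0.05, seed = 4)
  test_df <- separable_dataset(n = 200, pos_frac = 0.05, seed = 5)
  sn <- vapply(1:5, function(s) {
    model <- train_rusboost(df, n_rounds = 30, seed = s)
    sc <- predict(model, test_df)
    expect_true(all(sc >= 0 & sc <= 1))
    m <- metrics(evaluate(sc, test_df$label))
    m[["SN"]]
  }, 0)
  expect_true(all(sn > 0.8))
  # the majority-vote baseline never predicts a positive
  baseline <- metrics(evaluate(rep(0, nrow(test_df)), test_df$label))
  expect_equal(baseline[["SN"]], 0)
})

test_that("balanced input reduces RUSBoost to plain boosting", {
  df <- separable_dataset(n = 80, pos_frac = 0.5, seed = 6)
  model <- train_rusboost(df, n_rounds = 10, seed = 1)
  expect_s3_class(model, "nettop_model")
  expect_true(all(predict(model, df) >= 0 & predict(model, df) <= 1))
})

test_that("evaluate builds confusion counts at the threshold", {
  lab <- c(1, 1, 0, 0, 1, 0, 0, 0, 1, 0)
  cm <- evaluate(lab, lab)
  expect_equal(cm$FP + cm$FN, 0L)
  cm0 <- evaluate(rep(0, 10), lab)
  expect_equal(cm0$TP + cm0$FP, 0L)
  cm9 <- evaluate(c(lab[1:9], 1 - lab[10]), lab)
  expect_equal(cm9$TP + cm9$TN + cm9$FP + cm9$FN, 10L)
  expect_equal(cm9$FP + cm9$FN, 1L)
  expect_error(evaluate(1:3, 1:2), "same length")
})

test_that("metrics reproduce the hand-derived confusion arithmetic", {
  cm <- structure(list(TP = 9L, FP = 2L, TN = 8L, FN = 1L),
                  class = "nettop_confusion")
  m <- metrics(cm)
  expect_equal(m[["SN"]], 0.9)
  expect_equal(m[["SP"]], 0.8)
  expect_equal(m[["ACC"]], 0.85)
  expect_equal(m[["PPV"]], 9 / 11)
  expect_equal(m[["F"]], 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  expect_equal(m[["Gm"]], sqrt(0.72))

  perfect <- metrics(evaluate(c(1, 1, 0), c(1, 1, 0)))
  expect_true(all(perfect[c("ACC", "PPV", "SN", "SP", "F", "Gm")] == 1))

  none_pred <- metrics(evaluate(rep(0, 4), c(1, 1, 0, 0)))
  expect_equal(none_pred[["PPV"]], 0)
  expect_true("PPV" %in% attr(none_pred, "degenerate"))
})

test_that("ROC curve is monotone and AUC behaves as a rank statistic", {
  lab <- c(1, 1, 0, 0)
  expect_equal(roc_auc(1 - lab, lab)$auc, 0)
  expect_equal(roc_auc(lab, lab)$auc, 1)
  set.seed(8)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.4)
  r1 <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, r1$auc)       # monotone invariance
  expect_equal(r1$auc + roc_auc(-scores, labels)$auc, 1)
  expect_true(all(diff(r1$curve$fpr) >= 0) && all(diff(r1$curve$tpr) >= 0))
  expect_equal(r1$curve[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(r1$curve[nrow(r1$curve), ]), c(fpr = 1, tpr = 1))
  expect_error(roc_auc(scores, rep(1, 50)), "both classes")
  # null distribution: random scores on balanced labels concentrate at 1/2
  set.seed(9)
  auc_null <- roc_auc(runif(2000), rep(c(0, 1), 1000))$auc
  expect_lt(abs(auc_null - 0.5), 0.05)
})

test_that("cross-validation partitions rows, stays fold-honest, and summarizes", {
  study <- generate_study(synthetic_spec(n_vertices = 150, seed = 3,
                                         positive_fraction = 0.1))
  cv <- cross_validate(study$features, study$signature, "dtb",
                       k_folds = 5, use_smote = TRUE, seed = 7, n_trees = 20)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_length(cv$folds, nrow(study$features))
  test_sets <- lapply(cv$fold_detail, `[[`, "test_vertices")
  expect_setequal(unlist(test_sets), study$features$vertex)
  expect_equal(sum(lengths(test_sets)), nrow(study$features))
  # synthetic rows appear in training folds only
  expect_true(all(vapply(cv$fold_detail, `[[`, 0L, "n_synthetic") > 0L))
  expect_false(any(grepl("^syn", unlist(test_sets))))
  # summary arithmetic: mean and 1.96 * (sd / sqrt(k)) over folds
  for (mt in cv$summary$metric) {
    v <- cv$per_fold[[mt]]
    v <- v[!is.na(v)]
    row <- cv$summary[cv$summary$metric == mt, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$half_width, 1.96 * sd(v) / sqrt(length(v)))
  }
})

test_that("SMOTE lifts the median G-mean when the planted signal is weak", {
  # with a strong planted signal the bagged trees saturate with or without
  # balancing; the oversampling benefit shows once label noise is high
  diffs <- vapply(1:5, function(s) {
    study <- generate_study(synthetic_spec(n_vertices = 500, noise_sd = 4,
                                           seed = s))
    gm <- function(use_smote) {
      cv <- cross_validate(study$features, study$signature, "dtb",
                           k_folds = 5, use_smote = use_smote, seed = s,
                           n_trees = 50)
      cv$summary$mean[cv$summary$metric == "Gm"]
    }
    gm(TRUE) - gm(FALSE)
  }, 0)
  expect_gt(median(diffs), 0)
})

test_that("cross-validation guards its preconditions", {
  study <- generate_study(synthetic_spec(n_vertices = 100, seed = 4,
                                         positive_fraction = 0.1))
  expect_error(cross_validate(study$features, study$signature, "rusboost",
                              use_smote = TRUE),
               "conflicts with SMOTE")
  expect_error(cross_validate(study$features, study$signature, "dtb",
                              k_folds = 1), "k_folds")
  expect_error(cross_validate(study$features, study$signature, "dtb",
                              k_folds = 50, use_smote = FALSE),
               "too few positive")
})
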