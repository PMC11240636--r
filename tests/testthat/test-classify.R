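test_that("patient-level split reproduces the canonical 68/197 partition", {
  plan <- plan_cohort(cohort_spec(n_patients = 265, seed = 99))
  sp <- split_patients(plan$manifest, test_fraction = 68 / 265, seed = 4)
  expect_equal(sp$test$patients, 68)
  expect_equal(sp$train$patients, 197)
  expect_length(intersect(sp$train_patients, sp$test_patients), 0)
  # all of a patient's samples follow the patient
  m <- plan$manifest
  expect_setequal(unique(m$patient_id[m$patient_id %in% sp$test_patients]),
                  sp$test_patients)
  # deterministic under a fixed seed
  sp2 <- split_patients(plan$manifest, test_fraction = 68 / 265, seed = 4)
  expect_identical(sp$test_patients, sp2$test_patients)
  # stratification: both classes in both sets
  expect_true(all(sp$test$patients_by_label > 0))
  expect_true(all(sp$train$patients_by_label > 0))
})

test_that("grouped CV folds never let a patient straddle a fold pair", {
  df <- make_feature_table(n_patients = 40, delta = 1, seed = 2)
  folds <- clawxrd:::grouped_folds(df, n_folds = 10, seed = 3)
  per_patient <- tapply(folds, df$patient_id, function(f) length(unique(f)))
  expect_true(all(per_patient == 1))
  expect_equal(sort(unique(folds)), 1:10)
})

test_that("cross-validated grid search behaves at the null and under signal", {
  # permuted labels: chance-level CV AUC
  df <- make_feature_table(n_patients = 60, delta = 0, seed = 5)
  tiny_grid <- default_grid(num_trees = 100, max_depth = 0,
                            mtry_rule = "sqrt")
  clf0 <- fit_classifier(df, grid = tiny_grid, n_folds = 5, seed = 11)
  expect_lt(abs(max(clf0$cv_table$mean_cv_auc) - 0.5), 0.07)
  # strong effect: high CV AUC, and refit hyperparameters are reproducible
  df1 <- make_feature_table(n_patients = 60, delta = 1.5, seed = 6)
  clf1 <- fit_classifier(df1, grid = default_grid(num_trees = c(100, 300),
                                                  max_depth = c(0, 5),
                                                  mtry_rule = "sqrt"),
                         n_folds = 5, seed = 12)
  expect_gt(max(clf1$cv_table$mean_cv_auc), 0.9)
  clf1b <- fit_classifier(df1, grid = default_grid(num_trees = c(100, 300),
                                                   max_depth = c(0, 5),
                                                   mtry_rule = "sqrt"),
                          n_folds = 5, seed = 12)
  expect_identical(clf1$best_params, clf1b$best_params)
  expect_equal(clf1$cv_table$mean_cv_auc, clf1b$cv_table$mean_cv_auc)
})

test_that("sample prediction returns calibrated-range probabilities and flags name mismatches", {
  df <- make_feature_table(n_patients = 40, delta = 1.2, seed = 8)
  sp <- split_patients(df, test_fraction = 0.25, seed = 1)
  tr <- df[df$patient_id %in% sp$train_patients, ]
  te <- df[df$patient_id %in% sp$test_patients, ]
  clf <- fit_classifier(tr, grid = default_grid(100, 0, "sqrt"),
                        n_folds = 5, seed = 2)
  preds <- predict_samples(clf, te)
  expect_true(all(preds$prob >= 0 & preds$prob <= 1))
  expect_gt(roc_auc(preds$label == "cancer", preds$prob), 0.8)
  bad <- te; names(bad)[names(bad) == "f01"] <- "q01"
  expect_error(predict_samples(clf, bad), "feature-name mismatch")
})

test_that("sample-to-patient transfer rules aggregate as specified", {
  sp <- data.frame(sample_id = sprintf("s%d", 1:6),
                   patient_id = c("A", "A", "A", "A", "B", "B"),
                   label = c(rep("cancer", 4), rep("no_cancer", 2)),
                   prob = c(0.2, 0.4, 0.6, 0.8, 0.3, 0.3),
                   stringsAsFactors = FALSE)
  agg <- aggregate_patients(sp, method = "mean_prob")
  expect_equal(agg$prob[agg$patient_id == "A"], 0.5)
  expect_equal(agg$prob[agg$patient_id == "B"], 0.3)
  expect_equal(agg$n_samples, c(4, 2))
  # identical samples collapse to the sample probability
  expect_equal(aggregate_patients(sp[5:6, ], "mean_prob")$prob, 0.3)
  # vote rule: N of 4 at the sample threshold; unequal counts warn
  expect_warning(
    v <- aggregate_patients(sp, method = "vote_n", n_votes = 2,
                            sample_threshold = 0.5),
    "unequal samples")
  expect_equal(v$prob[v$patient_id == "A"], 1)  # 2 of 4 votes
  expect_equal(v$prob[v$patient_id == "B"], 0)
  # mean-features route collapses the table to one row per patient
  mf <- average_features_by_patient(make_feature_table(10, seed = 3))
  expect_equal(nrow(mf), 10)
})

test_that("patient averaging improves on samples when noise is independent", {
  # per-sample scores = patient signal + independent noise; averaging 4
  # samples shrinks the noise, so patient AUC >= sample AUC
  set.seed(42)
  n_pat <- 120
  truth <- rep(c(TRUE, FALSE), each = n_pat / 2)
  signal <- ifelse(truth, 0.6, 0.4)
  sp <- do.call(rbind, lapply(seq_len(n_pat), function(i)
    data.frame(sample_id = sprintf("s%d_%d", i, 1:4),
               patient_id = sprintf("P%d", i),
               label = if (truth[i]) "cancer" else "no_cancer",
               prob = pmin(1, pmax(0, signal[i] + rnorm(4, 0, 0.15))))))
  agg <- aggregate_patients(sp, "mean_prob")
  auc_s <- roc_auc(sp$label == "cancer", sp$prob)
  auc_p <- roc_auc(agg$label == "cancer", agg$prob)
  expect_gt(auc_p, auc_s)
})

test_that("trapezoid AUC equals the Mann-Whitney formulation to 1e-10", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    score <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    expect_equal(roc_auc(truth, score), auc_mann_whitney(truth, score),
                 tolerance = 1e-10)
  }
})

test_that("metrics report: identities, perfect separation, tie convention", {
  # worked examples from the canonical results table
  expect_equal(balanced_accuracy(72.4, 97.4), 84.9)
  expect_equal(round(balanced_accuracy(44.8, 92.3), 1), 68.6)
  # perfect separation
  preds <- data.frame(label = rep(c("cancer", "no_cancer"), each = 5),
                      prob = c(runif(5, 0.8, 1), runif(5, 0, 0.2)))
  mr <- compute_metrics(preds)
  expect_equal(mr$auc, 1)
  expect_equal(mr$best$sensitivity, 1)
  expect_equal(mr$best$specificity, 1)
  # all-equal probabilities: AUC 1/2 by the midrank tie convention
  ties <- data.frame(label = rep(c("cancer", "no_cancer"), 10), prob = 0.5)
  expect_equal(compute_metrics(ties)$auc, 0.5)
  # balanced-accuracy identity at every threshold; ROC monotone
  set.seed(9)
  rnd <- data.frame(label = sample(c("cancer", "no_cancer"), 60, TRUE),
                    prob = runif(60))
  mr2 <- compute_metrics(rnd)
  expect_equal(mr2$threshold_table$balanced_accuracy,
               (mr2$threshold_table$sensitivity +
                mr2$threshold_table$specificity) / 2)
  expect_true(all(diff(mr2$roc$tpr) >= 0))
  expect_true(all(diff(mr2$roc$fpr) >= 0))
  expect_error(compute_metrics(data.frame(label = "cancer", prob = 1)),
               "single-class")
})
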