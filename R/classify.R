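# ---- patient-level splitting ------------------------------------------------

#' Stratified patient-level train/test split
#'
#' Patients (never samples) are assigned to the blind test set, stratified by
#' label, so all of a patient's samples follow the patient and the test set
#' is untouched by training and validation. Sample counts differ slightly
#' from the patient fraction because patients contribute different numbers of
#' samples.
#'
#' @param manifest Data frame with \code{sample_id, patient_id, label}.
#' @param test_fraction Fraction of patients held out (default 68/265, the
#'   canonical blind-set share).
#' @param seed RNG seed for the draw.
#' @return A \code{"split_plan"}: \code{train_patients},
#'   \code{test_patients}, and per-set patient/sample counts by label.
#' @export
split_patients <- function(manifest, test_fraction = 68 / 265, seed = 1) {
  stopifnot(all(c("patient_id", "label") %in% names(manifest)),
            test_fraction > 0, test_fraction < 1)
  pat <- unique(manifest[, c("patient_id", "label")])
  if (anyDuplicated(pat$patient_id))
    stop("inconsistent labels within a patient: labels attach to patients, not samples")
  tab <- table(pat$label)
  if (any(tab < 2)) stop("need at least 2 patients per class to split")
  test_ids <- with_local_seed(seed, {
    unlist(lapply(names(tab), function(lb) {
      ids <- pat$patient_id[pat$label == lb]
      sample(ids, round(length(ids) * test_fraction))
    }))
  })
  train_ids <- setdiff(pat$patient_id, test_ids)
  count <- function(ids) {
    p <- pat[pat$patient_id %in% ids, ]
    s <- manifest[manifest$patient_id %in% ids, ]
    list(patients = nrow(p), samples = nrow(s),
         patients_by_label = table(p$label), samples_by_label = table(s$label))
  }
  structure(list(train_patients = sort(train_ids),
                 test_patients = sort(test_ids),
                 train = count(train_ids), test = count(test_ids),
                 test_fraction = test_fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d patients / %d samples, test %d patients / %d samples\n",
              x$train$patients, x$train$samples, x$test$patients, x$test$samples))
  invisible(x)
}

# stratified patient-grouped fold assignment: every sample of a patient lands
# in the same fold, folds balanced in patients per class
grouped_folds <- function(manifest, n_folds, seed) {
  pat <- unique(manifest[, c("patient_id", "label")])
  fold_of <- with_local_seed(seed, {
    f <- integer(nrow(pat)); names(f) <- pat$patient_id
    for (lb in unique(pat$label)) {
      ids <- sample(pat$patient_id[pat$label == lb])
      f[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
    f
  })
  unname(fold_of[manifest$patient_id])
}

# ---- random forest with grid search -----------------------------------------

#' Default hyperparameter grid for the random forest
#'
#' Modest, fully documented grid: number of trees, maximal tree depth
#' (0 = unlimited), and the features-per-split rule (\code{"sqrt"} or
#' \code{"log2"} of the feature count). Class weights are balanced
#' throughout.
#'
#' @param num_trees,max_depth,mtry_rule Vectors of grid levels.
#' @return Data frame, one row per grid point.
#' @export
default_grid <- function(num_trees = c(100, 300, 500),
                         max_depth = c(0, 5, 10),
                         mtry_rule = c("sqrt", "log2")) {
  expand.grid(num_trees = num_trees, max_depth = max_depth,
              mtry_rule = mtry_rule, stringsAsFactors = FALSE)
}

feature_cols <- function(df) {
  setdiff(names(df), c("sample_id", "patient_id", "label", "batch_id", "path"))
}

fit_ranger <- function(df, params, seed, class_weights = TRUE) {
  cols <- feature_cols(df)
  y <- factor(df$label, levels = c("no_cancer", "cancer"))
  mtry <- switch(params$mtry_rule,
                 sqrt = max(1L, floor(sqrt(length(cols)))),
                 log2 = max(1L, floor(log2(length(cols)))))
  cw <- if (class_weights) {
    tb <- table(y); as.numeric(sum(tb) / (length(tb) * tb))
  } else NULL
  ranger::ranger(x = df[, cols, drop = FALSE], y = y,
                 num.trees = params$num_trees,
                 max.depth = if (params$max_depth == 0) NULL else params$max_depth,
                 mtry = mtry, probability = TRUE,
                 class.weights = cw, seed = seed,
                 num.threads = 1)
}

#' Fit the cross-validated random-forest classifier
#'
#' Grid search over \code{\link{default_grid}} scored by mean ROC-AUC under
#' 10-fold cross-validation. Folds are grouped by patient — no patient's
#' samples ever straddle a train/validation fold pair — and stratified by
#' label. The best grid point is refit on the full training table. Ties in
#' mean CV AUC resolve to the earliest grid row.
#'
#' @param train_df Feature table (as from \code{\link{extract_features}})
#'   for training patients only.
#' @param grid Hyperparameter grid data frame.
#' @param n_folds Number of CV folds.
#' @param seed Seed controlling fold assignment and forest randomness.
#' @return A \code{"claw_classifier"}: \code{model} (ranger fit),
#'   \code{best_params}, \code{cv_table} (mean and per-fold AUC per grid
#'   row), \code{feature_names}.
#' @export
fit_classifier <- function(train_df, grid = default_grid(), n_folds = 10,
                           seed = 1) {
  stopifnot(length(unique(train_df$label)) == 2)
  folds <- grouped_folds(train_df, n_folds, seed)
  # guard against degenerate folds (a single class): re-stratify is built in,
  # so a degenerate fold indicates too few patients per class
  for (f in seq_len(n_folds)) {
    if (length(unique(train_df$label[folds == f])) < 2)
      stop("degenerate CV fold ", f, ": one class only; use fewer folds or more patients")
  }
  cv_scores <- matrix(NA_real_, nrow(grid), n_folds)
  for (gi in seq_len(nrow(grid))) {
    for (f in seq_len(n_folds)) {
      tr <- train_df[folds != f, , drop = FALSE]
      va <- train_df[folds == f, , drop = FALSE]
      fit <- fit_ranger(tr, grid[gi, ], seed = seed + 1000L * f)
      p <- predict_prob(fit, va)
      cv_scores[gi, f] <- roc_auc(va$label == "cancer", p)
    }
  }
  mean_auc <- rowMeans(cv_scores)
  best <- which.max(mean_auc)
  model <- fit_ranger(train_df, grid[best, ], seed = seed)
  structure(list(model = model,
                 best_params = grid[best, , drop = FALSE],
                 cv_table = cbind(grid, mean_cv_auc = mean_auc),
                 cv_scores = cv_scores,
                 folds = folds,
                 feature_names = feature_cols(train_df),
                 seed = seed),
            class = "claw_classifier")
}

#' @export
print.claw_classifier <- function(x, ...) {
  bp <- x$best_params
  cat(sprintf("<claw_classifier> random forest: %d trees, depth %s, mtry %s; mean CV AUC %.3f\n",
              bp$num_trees, if (bp$max_depth == 0) "unlimited" else bp$max_depth,
              bp$mtry_rule, max(x$cv_table$mean_cv_auc)))
  invisible(x)
}

predict_prob <- function(model, df) {
  fit <- if (inherits(model, "claw_classifier")) model$model else model
  cols <- fit$forest$independent.variable.names
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("feature-name mismatch: missing ", paste(miss, collapse = ", "))
  as.numeric(stats::predict(fit, data = df[, cols, drop = FALSE],
                            num.threads = 1)$predictions[, "cancer"])
}

#' Per-sample cancer probabilities on a blind set
#'
#' @param classifier A \code{\link{fit_classifier}} result.
#' @param test_df Feature table of blind samples.
#' @return Data frame \code{sample_id, patient_id, label, prob}.
#' @export
predict_samples <- function(classifier, test_df) {
  p <- predict_prob(classifier, test_df)
  stopifnot(all(p >= 0 & p <= 1))
  data.frame(sample_id = test_df$sample_id, patient_id = test_df$patient_id,
             label = test_df$label, prob = p, stringsAsFactors = FALSE)
}

# ---- sample-to-patient transfer ---------------------------------------------

#' Aggregate per-sample predictions into per-patient diagnoses
#'
#' Three transfer rules:
#' \describe{
#'   \item{\code{mean_prob}}{the patient's score is the arithmetic mean of
#'     its samples' cancer probabilities (the most reliable rule; unequal
#'     sample counts are no problem).}
#'   \item{\code{vote_n}}{samples are first classified at
#'     \code{sample_threshold}; a patient is called cancerous when at least
#'     \code{n_votes} samples vote cancer. With unequal samples per patient
#'     this rule is ill-posed, so a proportional fallback
#'     (\code{votes / n_samples >= n_votes / modal_n}) is applied with a
#'     warning.}
#'   \item{\code{mean_features}}{handled upstream: average feature vectors
#'     per patient with \code{\link{average_features_by_patient}} before
#'     training, then each patient is a single row (known to be unstable —
#'     it discards within-patient information).}
#' }
#'
#' @param sample_preds Data frame from \code{\link{predict_samples}}.
#' @param method Transfer rule.
#' @param n_votes Vote count for \code{vote_n} (1..modal samples).
#' @param sample_threshold Per-sample decision threshold for \code{vote_n}.
#' @return Data frame \code{patient_id, label, n_samples, prob} where
#'   \code{prob} is the mean probability (\code{mean_prob}) or the vote
#'   fraction scaled decision score (\code{vote_n}).
#' @export
aggregate_patients <- function(sample_preds,
                               method = c("mean_prob", "vote_n"),
                               n_votes = 2, sample_threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(all(c("patient_id", "label", "prob") %in% names(sample_preds)))
  sp <- split(sample_preds, sample_preds$patient_id)
  rows <- lapply(sp, function(d) {
    lab <- unique(d$label)
    stopifnot(length(lab) == 1)
    data.frame(patient_id = d$patient_id[1], label = lab,
               n_samples = nrow(d), prob = mean(d$prob),
               votes = sum(d$prob >= sample_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (method == "vote_n") {
    tb <- table(out$n_samples)
    modal_n <- max(as.integer(names(tb))[tb == max(tb)])
    if (length(unique(out$n_samples)) > 1) {
      warning("vote_n with unequal samples per patient; using proportional rule votes/n >= ",
              n_votes, "/", modal_n)
    }
    out$prob <- as.numeric(out$votes / out$n_samples >= n_votes / modal_n)
  }
  out$votes <- NULL
  out
}

#' Average feature vectors per patient
#'
#' Upstream step of the \code{mean_features} transfer rule: collapses a
#' sample-level feature table to one mean row per patient.
#'
#' @param df Feature table.
#' @return Patient-level feature table (\code{sample_id} becomes the
#'   patient id).
#' @export
average_features_by_patient <- function(df) {
  cols <- feature_cols(df)
  sp <- split(df, df$patient_id)
  rows <- lapply(sp, function(d) {
    cbind(data.frame(sample_id = d$patient_id[1], patient_id = d$patient_id[1],
                     label = d$label[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(d[, cols, drop = FALSE])),
                        check.names = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
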