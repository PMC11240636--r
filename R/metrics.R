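# ---- ROC --------------------------------------------------------------------

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the sorted unique scores and returns
#' the (FPR, TPR) staircase, anchored at (0,0) and (1,1). Ties in score move
#' the operating point diagonally, which is the midrank convention: the
#' trapezoid area under this curve equals the Mann-Whitney U statistic with
#' tied pairs counted 1/2.
#'
#' @param truth Logical (or 0/1): positive class indicator.
#' @param score Numeric classifier score, higher = more positive.
#' @return \code{data.frame(threshold, fpr, tpr)}.
#' @export
roc_curve <- function(truth, score) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(score), all(is.finite(score)))
  if (!any(truth) || all(truth))
    stop("ROC undefined: need both classes present")
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- truth[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tie group
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / sum(!truth)),
             tpr = c(0, tp[last] / sum(truth)))
}

#' Area under the ROC curve (trapezoid)
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1]; ties handled by the midrank convention.
#' @export
roc_auc <- function(truth, score) {
  rc <- roc_curve(truth, score)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Balanced accuracy
#'
#' \code{(sensitivity + specificity) / 2}, on whatever scale its arguments
#' use (fractions or percent).
#'
#' @param sensitivity,specificity Numeric.
#' @return Balanced accuracy.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

# ---- threshold sweep --------------------------------------------------------

#' Classification metrics over a threshold grid
#'
#' For each threshold t the decision is \code{prob >= t}; sensitivity
#' (cancer recall), specificity (non-cancer recall) and balanced accuracy
#' are tabulated, the ROC curve and its trapezoid AUC are computed from the
#' full probability ranking, and the operating point maximizing balanced
#' accuracy subject to a specificity floor (default 90\%, the screening
#' objective) is reported. Works identically for sample-level and
#' patient-level predictions.
#'
#' @param preds Data frame with \code{label} (\code{"cancer"} /
#'   \code{"no_cancer"}) and \code{prob}.
#' @param thresholds Threshold grid (default 0 to 1 by 0.01).
#' @param spec_floor Specificity constraint for the reported best operating
#'   point, as a fraction.
#' @return A \code{"metrics_report"}: \code{auc}, \code{roc},
#'   \code{threshold_table}, \code{best} (constrained argmax row),
#'   \code{best_unconstrained}, \code{n} by class.
#' @export
compute_metrics <- function(preds, thresholds = seq(0, 1, by = 0.01),
                            spec_floor = 0.9) {
  stopifnot(all(c("label", "prob") %in% names(preds)))
  truth <- preds$label == "cancer"
  if (!any(truth) || all(truth)) stop("metrics undefined: single-class input")
  pos <- sum(truth); neg <- sum(!truth)
  tab <- do.call(rbind, lapply(thresholds, function(t) {
    dec <- preds$prob >= t
    sens <- sum(dec & truth) / pos
    spec <- sum(!dec & !truth) / neg
    data.frame(threshold = t, sensitivity = sens, specificity = spec,
               balanced_accuracy = balanced_accuracy(sens, spec))
  }))
  rc <- roc_curve(truth, preds$prob)
  auc <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  ok <- tab$specificity > spec_floor
  best <- if (any(ok)) tab[ok, ][which.max(tab$balanced_accuracy[ok]), ]
          else tab[which.max(tab$balanced_accuracy), ]
  structure(list(auc = auc, roc = rc, threshold_table = tab,
                 best = best,
                 best_unconstrained = tab[which.max(tab$balanced_accuracy), ],
                 spec_floor = spec_floor,
                 n = c(cancer = pos, no_cancer = neg)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> AUC %.3f over %d cancer / %d no-cancer\n",
              x$auc, x$n["cancer"], x$n["no_cancer"]))
  b <- x$best
  cat(sprintf("  best (spec > %.0f%%): threshold %.2f, spec %.1f%%, sens %.1f%%, bal.acc %.1f%%\n",
              100 * x$spec_floor, b$threshold, 100 * b$specificity,
              100 * b$sensitivity, 100 * b$balanced_accuracy))
  invisible(x)
}
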