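# Diagnostic-test statistics, ROC machinery and leave-one-patient-out
# cross-validation.

ci_prop <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n)$conf.int)
}

#' Diagnostic metrics from binary predictions
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' accuracy from a 2x2 contingency table, each with an exact
#' (Clopper-Pearson) 95% confidence interval. A metric with a zero
#' denominator is returned as `NA` with `NA` CI.
#'
#' @param pred,truth Logical vectors of equal length; `truth` must contain
#'   both classes.
#' @return List of class `diagnostic_metrics` with elements `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (each `c(estimate, lower,
#'   upper)`), plus the table counts `tp`, `fp`, `tn`, `fn`, `n_pos`,
#'   `n_neg`.
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  if (length(unique(truth)) < 2)
    stop("truth must contain both positive and negative cases")
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  met <- function(x, n) {
    if (n == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    ci <- ci_prop(x, n)
    c(estimate = x / n, lower = ci[1], upper = ci[2])
  }
  structure(list(
    sensitivity = met(tp, tp + fn),
    specificity = met(tn, tn + fp),
    ppv = met(tp, tp + fp),
    npv = met(tn, tn + fn),
    accuracy = met(tp + tn, length(pred)),
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_pos = tp + fn, n_neg = tn + fp
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %5.1f%% (95%% CI %.1f-%.1f)\n", m,
                100 * v["estimate"], 100 * v["lower"], 100 * v["upper"]))
  }
  invisible(x)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney pair statistic (the probability a random
#' positive outscores a random negative, ties counting one half), with the
#' DeLong variance estimator for the confidence interval.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Logical truth; both classes must be present.
#' @return Named numeric `c(auc, lower, upper)`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2)
    stop("truth must contain both positive and negative cases")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  c(auc = ci[2], lower = ci[1], upper = ci[3])
}

#' Compare candidate model AUCs against a gold-standard model
#'
#' Paired DeLong tests of AUC equality of each candidate against the gold
#' model on the same samples, with Bonferroni adjustment over the number of
#' candidates.
#'
#' @param gold_scores Scores of the gold-standard model.
#' @param other_scores_list Named list of candidate score vectors, paired
#'   with `gold_scores` sample-for-sample.
#' @param truth Logical truth vector.
#' @return Data frame: model, auc, gold_auc, raw p, Bonferroni-adjusted p.
#' @export
compare_auc_to_gold <- function(gold_scores, other_scores_list, truth) {
  truth <- as.logical(truth)
  stopifnot(is.list(other_scores_list), length(other_scores_list) >= 1)
  if (any(vapply(other_scores_list, length, 1L) != length(gold_scores)))
    stop("all score vectors must be paired (equal length) with gold_scores")
  m <- length(other_scores_list)
  rg <- pROC::roc(truth, as.numeric(gold_scores), levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  rows <- lapply(seq_len(m), function(k) {
    sc <- as.numeric(other_scores_list[[k]])
    if (isTRUE(all.equal(sc, as.numeric(gold_scores)))) {
      p <- 1
      auc_k <- as.numeric(pROC::auc(rg))
    } else {
      rk <- pROC::roc(truth, sc, levels = c(FALSE, TRUE), direction = "<",
                      quiet = TRUE)
      p <- pROC::roc.test(rg, rk, method = "delong", paired = TRUE)$p.value
      auc_k <- as.numeric(pROC::auc(rk))
    }
    data.frame(model = names(other_scores_list)[k] %||% paste0("model", k),
               auc = auc_k, gold_auc = as.numeric(pROC::auc(rg)),
               p_raw = p, p_adjusted = min(1, m * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-patient-out cross-validation
#'
#' Folds are defined by patient: all samples of one patient are held out
#' together, a model is trained on the remaining patients and predicts the
#' held-out samples, and the per-fold predictions are pooled so each sample
#' is predicted exactly once.
#'
#' @param table Sample table with feature columns.
#' @param config A [model_config()]; each fold trains with a seed derived
#'   deterministically from `config$seed` and the fold number.
#' @return `table`'s id columns plus `score_1..score_6`, `pred_label`, and
#'   `fold` (the held-out patient).
#' @export
leave_one_patient_out <- function(table, config = model_config()) {
  patients <- sort(unique(table$patient_id))
  if (length(patients) < 3) stop("leave-one-patient-out needs at least 3 patients")
  out <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    p <- patients[k]
    test_rows <- table$patient_id == p
    train <- table[!test_rows, , drop = FALSE]
    if (length(unique(train$label)) < 2)
      stop("removing patient ", p, " leaves a single-class training set")
    fold_config <- config
    fold_config$seed <- (config$seed * 1000L + k) %% .Machine$integer.max
    model <- train_classifier(train, fold_config)
    pred <- predict(model, table[test_rows, , drop = FALSE])
    out[[k]] <- cbind(table[test_rows, sample_table_base_cols], pred,
                      fold = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-vs-rest clinical metrics at sample and ROI level
#'
#' For each clinical class (healthy, PE, pneumonia), positives are the
#' samples (or ROIs) truly of that class and negatives are those of the
#' other clinical classes; extra categories are excluded. Sample-level AUC
#' uses the class's sigmoid score; binary sample calls use the argmax label.
#'
#' @param predictions Prediction table (from [leave_one_patient_out()] or
#'   `predict` + id columns) with `label`, `pred_label` and `score_*`.
#' @param level `"sample"` or `"roi"` (majority-vote aggregation first).
#' @return Named list per clinical class: `auc` (with CI; sample level
#'   only), `metrics` (a [confusion_metrics()] object), `n_pos`, `n_neg`.
#' @export
clinical_metrics <- function(predictions, level = c("sample", "roi")) {
  level <- match.arg(level)
  if (level == "roi") {
    roi <- aggregate_predictions(predictions)
    keep <- roi$label %in% CLINICAL_CLASSES
    roi <- roi[keep, , drop = FALSE]
    out <- lapply(CLINICAL_CLASSES, function(cl) {
      truth <- roi$label == cl
      pred <- roi$modal_class == cl
      list(metrics = confusion_metrics(pred, truth),
           n_pos = sum(truth), n_neg = sum(!truth))
    })
    return(out)
  }
  keep <- predictions$label %in% CLINICAL_CLASSES
  df <- predictions[keep, , drop = FALSE]
  out <- lapply(CLINICAL_CLASSES, function(cl) {
    truth <- df$label == cl
    pred <- df$pred_label == cl
    list(auc = roc_auc(df[[paste0("score_", cl)]], truth),
         metrics = confusion_metrics(pred, truth),
         n_pos = sum(truth), n_neg = sum(!truth))
  })
  out
}
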