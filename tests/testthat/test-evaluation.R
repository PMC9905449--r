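test_that("confusion metrics reproduce hand-computed contingency values", {
  # TP=3 FN=1 TN=5 FP=1
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5))
  m <- confusion_metrics(pred, truth)
  expect_equal(unname(m$sensitivity["estimate"]), 0.75)
  expect_equal(unname(m$specificity["estimate"]), 5 / 6)
  expect_equal(unname(m$ppv["estimate"]), 0.75)
  expect_equal(unname(m$npv["estimate"]), 5 / 6)
  expect_equal(unname(m$accuracy["estimate"]), 0.8)
  # Clopper-Pearson interval agrees with the exact binomial test
  expect_equal(unname(m$sensitivity[c("lower", "upper")]),
               as.numeric(binom.test(3, 4)$conf.int))
})

test_that("a perfect classifier reaches 100% with CIs capped at 1", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  m <- confusion_metrics(truth, truth)
  for (met in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(unname(m[[met]]["estimate"]), 1)
    expect_equal(unname(m[[met]]["upper"]), 1)
  }
  expect_error(confusion_metrics(truth, rep(TRUE, 20)), "both")
})

test_that("metrics match independent tabulation on random draws", {
  set.seed(23)
  pred <- runif(1000) > 0.4
  truth <- runif(1000) > 0.55
  m <- confusion_metrics(pred, truth)
  tab <- table(pred = factor(pred, c(TRUE, FALSE)),
               truth = factor(truth, c(TRUE, FALSE)))
  expect_equal(unname(m$sensitivity["estimate"]), tab[1, 1] / sum(tab[, 1]))
  expect_equal(unname(m$specificity["estimate"]), tab[2, 2] / sum(tab[, 2]))
  expect_equal(unname(m$ppv["estimate"]), tab[1, 1] / sum(tab[1, ]))
  expect_equal(unname(m$npv["estimate"]), tab[2, 2] / sum(tab[2, ]))
  # order permutation changes nothing
  p <- sample(1000)
  m2 <- confusion_metrics(pred[p], truth[p])
  expect_equal(m2$sensitivity, m$sensitivity)
})

test_that("AUC equals exhaustive pair counting, with sane endpoints", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  sep <- c(rnorm(10, 10), rnorm(10, -10))
  expect_equal(unname(roc_auc(sep, truth)["auc"]), 1)
  expect_equal(unname(roc_auc(rep(1, 20), truth)["auc"]), 0.5)
  set.seed(27)
  for (i in 1:8) {
    n <- sample(10:100, 1)
    truth <- runif(n) > 0.5
    if (length(unique(truth)) < 2) next
    scores <- sample(seq_len(20), n, replace = TRUE)  # many ties
    got <- roc_auc(scores, truth)
    expect_equal(unname(got["auc"]), oracle_auc(scores, truth),
                 tolerance = 1e-12)
    expect_true(got["lower"] <= got["auc"] && got["auc"] <= got["upper"])
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both")
})

test_that("gold-standard AUC comparison applies Bonferroni correctly", {
  set.seed(31)
  truth <- rep(c(TRUE, FALSE), each = 100)
  gold <- rnorm(200) + truth * 3
  worse <- rnorm(200) + truth * 0.5
  worse2 <- rnorm(200) + truth * 0.3
  res <- compare_auc_to_gold(gold, list(gold = gold, a = worse, b = worse2), truth)
  expect_equal(res$p_raw[res$model == "gold"], 1)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  expect_error(compare_auc_to_gold(gold, list(a = worse[-1]), truth), "paired")
})

test_that("clearly different AUCs are detected after adjustment", {
  set.seed(33)
  hits <- 0
  for (r in 1:20) {
    truth <- rep(c(TRUE, FALSE), each = 250)
    gold <- rnorm(500) + truth * qnorm(0.95) * sqrt(2)   # AUC ~ 0.95
    weak <- rnorm(500) + truth * qnorm(0.70) * sqrt(2)   # AUC ~ 0.70
    res <- compare_auc_to_gold(gold, list(w = weak, x = weak, y = weak), truth)
    if (all(res$p_adjusted < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("leave-one-patient-out holds out whole patients exactly once", {
  tab <- separable_table(n_per_class = 80)  # 4 patients, 3 classes
  cfg <- model_config(seed = 17, max_epochs = 40, patience = 10, batch_size = 32L)
  pooled <- leave_one_patient_out(tab, cfg)
  expect_equal(nrow(pooled), nrow(tab))
  expect_equal(sort(unique(pooled$fold)), sort(unique(tab$patient_id)))
  # every sample predicted exactly once, within its own patient's fold
  expect_equal(pooled$fold, pooled$patient_id)
  expect_equal(as.vector(table(pooled$patient_id)),
               as.vector(table(tab$patient_id)))
  expect_error(leave_one_patient_out(tab[tab$patient_id %in% c("P1", "P2"), ], cfg),
               "at least 3")
  # separable data: pooled accuracy is high
  expect_gte(mean(pooled$pred_label == pooled$label), 0.9)
})

test_that("clinical metrics report one-vs-rest panels at both levels", {
  set.seed(35)
  n <- 90
  preds <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 30),
    roi_id = rep(rep(1:3, each = 10), 3),
    slice = 1L, row = 1:90, col = 1L, window_side = 3L,
    label = rep(rep(c(1L, 2L, 3L), each = 10), 3)
  )
  # strong scores for the true class
  for (k in 1:6) preds[[paste0("score_", k)]] <- runif(n, 0, 0.2)
  for (k in 1:3) {
    idx <- preds$label == k
    preds[[paste0("score_", k)]][idx] <- runif(sum(idx), 0.7, 1)
  }
  preds$pred_label <- apply(as.matrix(preds[paste0("score_", 1:6)]), 1, which.max)
  cm <- clinical_metrics(preds, "sample")
  expect_named(cm, c("HEALTHY", "PE", "PNEUMONIA"))
  for (cl in names(cm)) expect_gte(unname(cm[[cl]]$auc["auc"]), 0.99)
  roi <- clinical_metrics(preds, "roi")
  expect_equal(unname(roi$PE$metrics$sensitivity["estimate"]), 1)
})
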