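# End-to-end orchestration of the four-model experiment: preprocess a
# cohort, build matched sample tables, leave-one-patient-out model
# selection on the training group, final fits, held-out test evaluation at
# sample and ROI level, and AUC comparison against the gold model.

#' Preprocess one patient: fuse SPECT onto the CT grid and normalize
#'
#' Resizes the SPECT volume to the CT grid, segments lungs in both
#' modalities, registers the SPECT lung mask onto the CT lung mask with an
#' MSE affine, resamples the SPECT intensities through the transform, and
#' produces both normalizations.
#'
#' @param ct CT [volume3d()].
#' @param spect SPECT [volume3d()] (any grid).
#' @param labels Label volume path or array (see [read_roi_labels()]).
#' @param patient_id Patient identifier.
#' @param closing_radius CT lung-mask closing radius, default 5.
#' @param spect_threshold SPECT lung threshold in counts, default 20,
#'   applied after resizing.
#' @return List: `ct`, `spect_reg` (registered counts), `spect_norm` (list
#'   `MAX` / `PERCENTILE99`), `transform`, masks, and `rois`.
#' @export
preprocess_patient <- function(ct, spect, labels, patient_id = "P0",
                               closing_radius = 5L, spect_threshold = 20) {
  spect_rs <- resize_spect_to_ct(spect, ct)
  ct_mask <- segment_lungs_ct(ct, closing_radius = closing_radius)
  # closing also fills perfusion-defect holes in the SPECT mask, so the two
  # thresholded masks present comparable shapes to the MSE registration
  sp_mask <- morphological_closing(segment_lungs_spect(spect_rs, threshold = spect_threshold),
                                   closing_radius)
  transform <- register_masks_affine(sp_mask, ct_mask)
  spect_reg <- apply_transform(spect_rs, transform, ct)
  rois <- read_roi_labels(labels, patient_id = patient_id)
  list(ct = ct, spect_reg = spect_reg,
       spect_norm = list(MAX = normalize_spect(spect_reg, "MAX"),
                         PERCENTILE99 = normalize_spect(spect_reg, "PERCENTILE99")),
       transform = transform, ct_mask = ct_mask, spect_mask = sp_mask,
       rois = rois)
}

#' Select the 3x3 samples whose centers carry a valid 5x5 window
#'
#' Window containment is monotone in window size, so the 5x5 sample centers
#' of an ROI are a subset of its 3x3 centers. Keeping exactly those rows
#' matches the per-stratum counts of the 5x5 table *and* pairs the two
#' window sizes sample-for-sample, which the paired AUC comparisons
#' require. This is the deterministic count-matching used by
#' [run_experiment()]; [match_sample_counts()] is the general seeded
#' alternative.
#'
#' @param table3,table5 Sample tables for window sides 3 and 5.
#' @return The rows of `table3` whose `(patient, roi, slice, row, col)`
#'   occur in `table5`.
#' @export
match_samples_by_center <- function(table3, table5) {
  key <- function(df) paste(df$patient_id, df$roi_id, df$slice, df$row, df$col)
  out <- table3[key(table3) %in% key(table5), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# samples + features for one patient and all four (window, normalization)
# arms; CT features depend only on the window size, so they are computed
# once per size and shared between the two SPECT normalizations.
patient_sample_tables <- function(prep, config = radiomics_config()) {
  out <- list()
  for (side in c(3L, 5L)) {
    samples <- do.call(rbind, lapply(prep$rois, enumerate_window_samples,
                                     window_side = side))
    ct_feat <- modality_features_for_samples(samples, prep$ct, "CT", config)
    for (norm in c("MAX", "PERCENTILE99")) {
      sp_feat <- modality_features_for_samples(samples, prep$spect_norm[[norm]],
                                               "SPECT", config)
      out[[paste0("w", side, "_", norm)]] <- cbind(samples, ct_feat, sp_feat)
    }
  }
  out
}

#' The four standard model configurations
#'
#' 3x3 / 5x5 windows crossed with maximum / 99th-percentile SPECT
#' normalization: `ModelPrct3`, `ModelPrct5`, `ModelMx3`, `ModelMx5`.
#'
#' @param seed Base training seed; each configuration derives its own.
#' @param ... Passed to [model_config()] (hyperparameters).
#' @return Named list of four [model_config()] objects.
#' @export
standard_configs <- function(seed = 1L, ...) {
  arms <- list(list(3L, "PERCENTILE99"), list(5L, "PERCENTILE99"),
               list(3L, "MAX"), list(5L, "MAX"))
  cfgs <- lapply(seq_along(arms), function(i) {
    model_config(window_side = arms[[i]][[1]], normalization = arms[[i]][[2]],
                 seed = (as.integer(seed) * 17L + i) %% 2147483647L, ...)
  })
  stats::setNames(cfgs, vapply(cfgs, `[[`, "", "label"))
}

table_key <- function(config) {
  paste0("w", config$window_side, "_", config$normalization)
}

# Per-class AUC table (rows = models) from a list of prediction tables.
auc_table <- function(pred_list) {
  rows <- lapply(names(pred_list), function(lbl) {
    cm <- clinical_metrics(pred_list[[lbl]], "sample")
    row <- data.frame(model = lbl, stringsAsFactors = FALSE)
    for (cl in names(cm)) {
      a <- cm[[cl]]$auc
      row[[paste0("auc_", cl)]] <- a[["auc"]]
      row[[paste0("ci_", cl)]] <- sprintf("%.3f-%.3f", a[["lower"]], a[["upper"]])
    }
    row$mean_auc <- mean(unlist(row[paste0("auc_", names(cm))]))
    row
  })
  do.call(rbind, rows)
}

# Paired DeLong comparisons of every model against the gold model, one
# panel per clinical class; the gold model's own cell is flagged.
gold_comparisons <- function(pred_list, gold_label) {
  keep <- pred_list[[gold_label]]$label %in% CLINICAL_CLASSES
  rows <- list()
  for (cl in names(CLINICAL_CLASSES)) {
    code <- CLINICAL_CLASSES[[cl]]
    truth <- pred_list[[gold_label]]$label[keep] == code
    gold_scores <- pred_list[[gold_label]][[paste0("score_", code)]][keep]
    others <- lapply(pred_list, function(df) df[[paste0("score_", code)]][keep])
    cmp <- compare_auc_to_gold(gold_scores, others, truth)
    cmp$class <- cl
    cmp$is_gold <- cmp$model == gold_label
    cmp$p_raw[cmp$is_gold] <- NA_real_
    cmp$p_adjusted[cmp$is_gold] <- NA_real_
    rows[[cl]] <- cmp
  }
  do.call(rbind, rows)
}

metrics_rows <- function(cm_list, model, level) {
  rows <- lapply(names(cm_list), function(cl) {
    m <- cm_list[[cl]]$metrics
    df <- data.frame(model = model, level = level, class = cl,
                     stringsAsFactors = FALSE)
    if (!is.null(cm_list[[cl]]$auc)) {
      df$auc <- cm_list[[cl]]$auc[["auc"]]
      df$auc_ci <- sprintf("%.3f-%.3f", cm_list[[cl]]$auc[["lower"]],
                           cm_list[[cl]]$auc[["upper"]])
    } else {
      df$auc <- NA_real_
      df$auc_ci <- NA_character_
    }
    for (met in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
      v <- m[[met]]
      df[[met]] <- v[["estimate"]]
      df[[paste0(met, "_ci")]] <- sprintf("%.3f-%.3f", v[["lower"]], v[["upper"]])
    }
    df$n_pos <- cm_list[[cl]]$n_pos
    df$n_neg <- cm_list[[cl]]$n_neg
    df
  })
  do.call(rbind, rows)
}

#' Run the four-model experiment end to end
#'
#' Preprocesses every cohort patient, builds count-matched sample tables
#' for both window sizes and normalizations, performs leave-one-patient-out
#' validation of all four models on the training group, selects the gold
#' model (highest mean clinical-class AUC), refits every model on the full
#' training group, evaluates on the held-out test patients at sample and
#' ROI level, and compares every model's AUC against the gold model with
#' Bonferroni-adjusted paired DeLong tests. All randomness derives from
#' `seed`; identical seeds reproduce an identical report bundle.
#'
#' @param cohort_dir Cohort directory from [generate_cohort()] (or the same
#'   layout for real data).
#' @param out_dir Output directory for the report bundle (TSV tables,
#'   `summary.json`, matched sample tables). `NULL` skips writing.
#' @param seed Integer master seed.
#' @param configs Named list of four [model_config()]s, default
#'   [standard_configs()].
#' @param radiomics A [radiomics_config()].
#' @param verbose Print per-stage progress.
#' @return List: `samples` (matched tables per arm), `loso`
#'   (per-model LOSO predictions, AUC table, comparisons), `gold_label`,
#'   `test` (per-model predictions, AUC and metrics tables at both levels,
#'   comparisons), `manifest`.
#' @export
run_experiment <- function(cohort_dir, out_dir = NULL, seed = 1L,
                           configs = standard_configs(seed),
                           radiomics = radiomics_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  manifest <- read_cohort_manifest(cohort_dir)
  train_ids <- manifest$patient_id[manifest$group == "train"]
  test_ids <- manifest$patient_id[manifest$group == "test"]
  stopifnot(length(train_ids) >= 3, length(intersect(train_ids, test_ids)) == 0)

  arms <- c("w3_MAX", "w3_PERCENTILE99", "w5_MAX", "w5_PERCENTILE99")
  tables <- stats::setNames(vector("list", 4), arms)
  for (pid in sort(manifest$patient_id)) {
    pdir <- file.path(cohort_dir, pid)
    prep <- preprocess_patient(
      read_volume(file.path(pdir, "ct.nii.gz"), "CT"),
      read_volume(file.path(pdir, "spect.nii.gz"), "SPECT"),
      file.path(pdir, "labels.nii.gz"), patient_id = pid)
    pt <- patient_sample_tables(prep, radiomics)
    for (a in arms) tables[[a]] <- rbind(tables[[a]], pt[[a]])
    say("preprocessed %s (%d/%d): %d + %d samples", pid,
        match(pid, sort(manifest$patient_id)), nrow(manifest),
        nrow(pt$w3_MAX), nrow(pt$w5_MAX))
  }
  # count-match the 3x3 tables to the 5x5 tables (paired by center)
  for (norm in c("MAX", "PERCENTILE99")) {
    tables[[paste0("w3_", norm)]] <- match_samples_by_center(
      tables[[paste0("w3_", norm)]], tables[[paste0("w5_", norm)]])
  }
  say("matched tables: %s samples per arm",
      paste(vapply(tables, nrow, 1L), collapse = "/"))

  split_tab <- function(tab, ids) tab[tab$patient_id %in% ids, , drop = FALSE]

  say("leave-one-patient-out on %d training patients...", length(train_ids))
  loso_pred <- lapply(configs, function(cfg) {
    leave_one_patient_out(split_tab(tables[[table_key(cfg)]], train_ids), cfg)
  })
  loso_auc <- auc_table(loso_pred)
  gold_label <- loso_auc$model[which.max(loso_auc$mean_auc)]
  loso_cmp <- gold_comparisons(loso_pred, gold_label)
  say("gold model by LOSO mean AUC: %s", gold_label)

  say("final fits + test evaluation...")
  models <- lapply(configs, function(cfg)
    train_classifier(split_tab(tables[[table_key(cfg)]], train_ids), cfg))
  test_pred <- lapply(names(configs), function(lbl) {
    tab <- split_tab(tables[[table_key(configs[[lbl]])]], test_ids)
    cbind(tab[sample_table_base_cols], predict(models[[lbl]], tab))
  })
  names(test_pred) <- names(configs)
  test_auc <- auc_table(test_pred)
  test_cmp <- gold_comparisons(test_pred, gold_label)
  test_metrics <- do.call(rbind, c(
    lapply(names(test_pred), function(lbl)
      metrics_rows(clinical_metrics(test_pred[[lbl]], "sample"), lbl, "sample")),
    lapply(names(test_pred), function(lbl)
      metrics_rows(clinical_metrics(test_pred[[lbl]], "roi"), lbl, "roi"))))
  loso_metrics <- metrics_rows(clinical_metrics(loso_pred[[gold_label]], "sample"),
                               gold_label, "sample")

  res <- list(samples = tables, models = models,
              loso = list(predictions = loso_pred,
                                            auc = loso_auc, comparisons = loso_cmp,
                                            gold_metrics = loso_metrics),
              gold_label = gold_label,
              test = list(predictions = test_pred, auc = test_auc,
                          comparisons = test_cmp, metrics = test_metrics),
              manifest = manifest,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(loso_auc, "loso_auc.tsv")
    wt(loso_cmp, "loso_auc_comparisons.tsv")
    wt(loso_metrics, "loso_gold_metrics.tsv")
    wt(test_auc, "test_auc.tsv")
    wt(test_cmp, "test_auc_comparisons.tsv")
    wt(test_metrics, "test_metrics.tsv")
    for (a in arms)
      write_sample_table(tables[[a]], file.path(out_dir, paste0("samples_", a, ".tsv")))
    for (lbl in names(test_pred))
      wt(test_pred[[lbl]], paste0("test_predictions_", lbl, ".tsv"))
    jsonlite::write_json(
      list(seed = seed, gold_label = gold_label,
           n_train = length(train_ids), n_test = length(test_ids),
           samples_per_arm = lapply(tables, nrow),
           loso_mean_auc = stats::setNames(as.list(loso_auc$mean_auc), loso_auc$model)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
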