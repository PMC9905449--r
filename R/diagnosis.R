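# Lesion-level diagnosis: aggregate per-sample predictions within each ROI
# by majority vote over the predicted tissue patterns.

# Tie-break priority: clinical severity first, so ties never hide the most
# dangerous pattern.
aggregation_priority <- c(
  TISSUE_CLASSES[["PE"]], TISSUE_CLASSES[["PNEUMONIA"]],
  TISSUE_CLASSES[["ABNORMAL_CT_LOW_PERF"]], TISSUE_CLASSES[["HEALTHY"]],
  TISSUE_CLASSES[["BODY_TISSUE"]], TISSUE_CLASSES[["BACKGROUND"]]
)

#' Aggregate sample predictions into one ROI diagnosis
#'
#' The ROI's diagnosis is the most frequent predicted image pattern among
#' its samples; count ties are broken by clinical severity (PE > pneumonia >
#' abnormal-CT/low-perfusion > healthy > body tissue > background). The
#' three binary diagnostic calls (PE/noPE, pneumonia/no pneumonia,
#' healthy/not healthy) are positive iff the modal class equals the target,
#' so at most one call is positive; extra-category votes are kept and can
#' win the vote, yielding an all-negative ROI.
#'
#' @param predicted_labels Integer vector of predicted tissue class codes
#'   (1-6) for all samples of one ROI.
#' @return List of class `roi_diagnosis`: `modal_class`, `class_counts`
#'   (length 6), `n_samples` and logical `binary_calls` (`PE`, `PNEUMONIA`,
#'   `HEALTHY`).
#' @export
aggregate_roi <- function(predicted_labels) {
  predicted_labels <- as.integer(predicted_labels)
  if (length(predicted_labels) == 0) stop("cannot aggregate an empty ROI")
  stopifnot(all(predicted_labels %in% TISSUE_CLASSES))
  counts <- tabulate(predicted_labels, nbins = 6L)
  top <- aggregation_priority[counts[aggregation_priority] == max(counts)][1]
  structure(list(
    modal_class = as.integer(top),
    class_counts = stats::setNames(counts, names(TISSUE_CLASSES)),
    n_samples = length(predicted_labels),
    binary_calls = c(PE = top == TISSUE_CLASSES[["PE"]],
                     PNEUMONIA = top == TISSUE_CLASSES[["PNEUMONIA"]],
                     HEALTHY = top == TISSUE_CLASSES[["HEALTHY"]])
  ), class = "roi_diagnosis")
}

#' Aggregate a prediction table into per-ROI diagnoses
#'
#' @param predictions Data frame with `patient_id`, `roi_id`, `label` (true
#'   class of the ROI) and `pred_label` columns (one row per sample).
#' @return Data frame with one row per (patient, ROI): true label, modal
#'   predicted class, sample count, and the three binary calls.
#' @export
aggregate_predictions <- function(predictions) {
  stopifnot(all(c("patient_id", "roi_id", "label", "pred_label") %in%
                  names(predictions)))
  key <- interaction(predictions$patient_id, predictions$roi_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(predictions)), key), function(idx) {
    d <- aggregate_roi(predictions$pred_label[idx])
    data.frame(patient_id = predictions$patient_id[idx[1]],
               roi_id = predictions$roi_id[idx[1]],
               label = predictions$label[idx[1]],
               modal_class = d$modal_class,
               n_samples = d$n_samples,
               call_PE = d$binary_calls[["PE"]],
               call_PNEUMONIA = d$binary_calls[["PNEUMONIA"]],
               call_HEALTHY = d$binary_calls[["HEALTHY"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
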