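#' qspect: local radiomic analysis of perfusion SPECT/CT
#'
#' Tools to register and normalize paired CT / perfusion-SPECT volumes,
#' extract windowed 2D radiomic features pixel-wise inside annotated regions
#' of interest, classify window samples into six tissue-pattern classes with
#' a class-weighted fully connected network, and aggregate sample predictions
#' into lesion-level diagnoses (pulmonary embolism / pneumonia / healthy),
#' together with leave-one-patient-out evaluation, ROC comparison machinery
#' and a synthetic phantom cohort generator.
#'
#' @keywords internal
"_PACKAGE"

#' Six tissue-pattern classes
#'
#' Integer codes of the six image-pattern classes. Codes 1-3 are the clinical
#' targets (healthy lung, pulmonary embolism, pneumonia); codes 4-6 are extra
#' categories added so the classifier also learns what the targets are *not*:
#' abnormal CT with low perfusion, black background (no tracer uptake) and
#' extrapulmonary body tissue.
#'
#' @format Named integer vector of length 6.
#' @export
TISSUE_CLASSES <- c(
  HEALTHY = 1L,
  PE = 2L,
  PNEUMONIA = 3L,
  ABNORMAL_CT_LOW_PERF = 4L,
  BACKGROUND = 5L,
  BODY_TISSUE = 6L
)

#' Clinical target classes (subset of [TISSUE_CLASSES])
#' @export
CLINICAL_CLASSES <- TISSUE_CLASSES[c("HEALTHY", "PE", "PNEUMONIA")]

tissue_class_name <- function(code) {
  stopifnot(all(code %in% TISSUE_CLASSES))
  names(TISSUE_CLASSES)[match(code, TISSUE_CLASSES)]
}
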