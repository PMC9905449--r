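#' Construct a 3D scalar volume
#'
#' A `volume3d` wraps a 3D array of scalar values (rows x cols x slices)
#' together with its voxel spacing in mm and its modality. CT values are in
#' Hounsfield units; SPECT values are tracer counts or, after
#' [normalize_spect()], unitless normalized intensities.
#'
#' @param values 3D numeric array, indexed `[row, col, slice]`.
#' @param spacing Numeric length-3 voxel size in mm, `(dx, dy, dz)` where
#'   `dx`/`dy` are in-plane and `dz` is the slice spacing.
#' @param modality `"CT"` or `"SPECT"`.
#' @param units `"HU"`, `"counts"` or `"normalized"`. Defaults to the
#'   conventional unit of the modality.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing, modality = c("CT", "SPECT"),
                     units = NULL) {
  modality <- match.arg(modality)
  if (is.null(units)) units <- if (modality == "CT") "HU" else "counts"
  units <- match.arg(units, c("HU", "counts", "normalized"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive voxel sizes (dx, dy, dz) in mm")
  if (modality == "CT" && units == "HU" && min(values) < -1100)
    stop("implausible CT: values below -1100 HU")
  if (modality == "SPECT" && units == "counts" && min(values) < 0)
    stop("SPECT counts must be non-negative")
  structure(
    list(values = values, spacing = spacing, modality = modality,
         units = units),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %s [%s]  %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$modality, x$units, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' Voxel volume of a `volume3d` in cubic millimetres
#' @param volume A [volume3d()].
#' @return Scalar, `dx * dy * dz`.
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

#' Construct a 2D region-of-interest annotation
#'
#' One expert-annotated 2D pixel region on a single slice, carrying one of
#' the six tissue-pattern classes.
#'
#' @param patient_id Character patient identifier.
#' @param roi_id Integer identifier, unique within a patient.
#' @param slice_index 1-based slice index.
#' @param pixels Two-column integer matrix of 1-based `(row, col)` pixel
#'   coordinates on that slice.
#' @param label Tissue class code (1-6) or name (see [TISSUE_CLASSES]).
#' @return An object of class `roi_annotation`.
#' @export
roi_annotation <- function(patient_id, roi_id, slice_index, pixels, label) {
  if (is.character(label)) label <- TISSUE_CLASSES[[label]]
  label <- as.integer(label)
  if (!label %in% TISSUE_CLASSES) stop("label must be a tissue class code 1-6")
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("ROI must contain at least one pixel")
  if (ncol(pixels) != 2L) stop("'pixels' must be an n x 2 (row, col) matrix")
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("row", "col")
  if (anyDuplicated(pixels)) pixels <- unique(pixels)
  structure(
    list(patient_id = as.character(patient_id), roi_id = as.integer(roi_id),
         slice_index = as.integer(slice_index), pixels = pixels,
         label = label),
    class = "roi_annotation"
  )
}

#' @export
print.roi_annotation <- function(x, ...) {
  cat(sprintf("<roi_annotation> patient %s, roi %d, slice %d: %d px, class %s\n",
              x$patient_id, x$roi_id, x$slice_index, nrow(x$pixels),
              tissue_class_name(x$label)))
  invisible(x)
}
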