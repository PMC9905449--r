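# Volume, annotation and sample-table I/O. NIfTI-1 via RNifti; DICOM series
# via the minimal reader in dicom_read.R; sample tables as TSV.

#' Read a CT or SPECT volume
#'
#' Reads either a single NIfTI-1 file or a directory containing an
#' uncompressed DICOM series. DICOM rescale slope/intercept are applied, so
#' CT values come back in Hounsfield units; slices are sorted by their z
#' position. Voxel spacing is taken from the headers.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a DICOM series directory.
#' @param modality `"CT"` or `"SPECT"`.
#' @param units Value units; defaults to `"HU"` for CT, `"counts"` for SPECT.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, modality = c("CT", "SPECT"), units = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    vol <- read_dicom_series(path, modality)
    if (!is.null(units)) vol$units <- match.arg(units, c("HU", "counts", "normalized"))
    return(vol)
  }
  im <- RNifti::readNifti(path)
  vals <- array(as.numeric(im), dim = dim(im))
  if (length(dim(vals)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  volume3d(vals, spacing = RNifti::pixdim(im)[1:3], modality = modality,
           units = units)
}

#' Write a volume to NIfTI-1
#'
#' @param volume A [volume3d()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI storage type, default `"double"` for lossless
#'   round-trips (use `"int16"` for label volumes).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "volume3d"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  im <- RNifti::asNifti(volume$values)
  RNifti::pixdim(im) <- volume$spacing
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' Write an integer label volume to NIfTI-1
#' @param labels 3D integer array (0 = unlabeled, 1-6 tissue class codes).
#' @param spacing Voxel spacing in mm, `(dx, dy, dz)`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(labels, spacing, path) {
  im <- RNifti::asNifti(array(as.numeric(labels), dim = dim(labels)))
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path, datatype = "int16")
  invisible(path)
}

#' Extract 2D ROI annotations from a label volume
#'
#' The annotation convention is an integer label volume on the CT grid with
#' 0 for unlabeled voxels and tissue class codes 1-6 elsewhere. Because the
#' expert annotations are 2D regions, each connected 2D component
#' (8-connectivity) of equal label within a slice becomes one ROI;
#' same-label regions on different slices are distinct ROIs.
#'
#' @param path NIfTI label volume path, or a 3D integer array.
#' @param patient_id Patient identifier attached to the returned ROIs.
#' @return List of [roi_annotation()], `roi_id` unique within the patient.
#' @export
read_roi_labels <- function(path, patient_id = "P0") {
  if (is.character(path)) {
    im <- RNifti::readNifti(path)
    labels <- array(as.integer(round(as.numeric(im))), dim = dim(im))
  } else {
    labels <- array(as.integer(path), dim = dim(path))
  }
  bad <- setdiff(unique(as.vector(labels)), 0:6)
  if (length(bad) > 0)
    stop("label volume contains codes outside 0-6: ", paste(bad, collapse = ", "))
  rois <- list()
  roi_id <- 0L
  for (s in seq_len(dim(labels)[3])) {
    sl <- labels[, , s]
    for (code in sort(setdiff(unique(as.vector(sl)), 0L))) {
      comp <- label_components(sl == code)
      for (k in seq_len(max(comp))) {
        idx <- which(comp == k, arr.ind = TRUE)
        roi_id <- roi_id + 1L
        rois[[roi_id]] <- roi_annotation(patient_id, roi_id, s, idx, code)
      }
    }
  }
  rois
}

sample_table_base_cols <- c("patient_id", "roi_id", "slice", "row", "col",
                           "window_side", "label")

#' Write a window-sample table
#'
#' One row per window sample: patient, ROI, window center `(slice, row,
#' col)`, window side, tissue class code, then the feature columns in their
#' fixed documented order (see [feature_names()]). Written as TSV with full
#' precision so that read/write round-trips are lossless.
#'
#' @param samples Data frame as produced by [enumerate_window_samples()] /
#'   [extract_features_for_samples()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_sample_table <- function(samples, path) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(sample_table_base_cols, names(samples))
  if (length(missing_cols) > 0)
    stop("sample table missing columns: ", paste(missing_cols, collapse = ", "))
  feat <- setdiff(names(samples), sample_table_base_cols)
  if (length(feat) > 0 && !all(vapply(samples[feat], is.numeric, logical(1))))
    stop("feature columns must be numeric")
  df <- samples[c(sample_table_base_cols, feat)]
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window-sample table written by [write_sample_table()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("roi_id", "slice", "row", "col", "window_side", "label"))
    df[[col]] <- as.integer(df[[col]])
  df$patient_id <- as.character(df$patient_id)
  df
}
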