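# Shared fixtures. Heavy objects are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

small_phantom <- function(seed = 11) {
  cached(paste0("phantom_", seed),
         generate_phantom_patient(phantom_spec(), seed = seed, patient_id = "PX"))
}

# Write a tiny synthetic DICOM CT series with python/pydicom (an independent
# writer, so the package's reader is not checked against itself). Returns
# the series directory, or NULL if python/pydicom is unavailable.
write_dicom_fixture <- function(dir, n_slices = 4, rows = 8, cols = 8,
                                slope = 1, intercept = -1024) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  script <- sprintf('
import numpy as np, pydicom, os, sys
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
outdir = sys.argv[1]
truth = outdir + "_truth"
os.makedirs(truth, exist_ok=True)
rows, cols, n = %d, %d, %d
rng = np.random.default_rng(7)
series_uid = generate_uid()
order = [2, 0, 3, 1]  # shuffled on disk; reader must sort by position
for k in range(n):
    px = (rng.integers(0, 3000, size=(rows, cols))).astype(np.int16)
    ds = Dataset()
    meta = FileMetaDataset()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    ds.file_meta = meta
    ds.SOPClassUID = meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = series_uid
    ds.Modality = "CT"
    ds.Rows, ds.Columns = rows, cols
    ds.BitsAllocated, ds.BitsStored, ds.HighBit = 16, 16, 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope, ds.RescaleIntercept = %g, %g
    ds.PixelSpacing = [0.7, 1.25]
    ds.SliceThickness = 3.0
    ds.ImagePositionPatient = [0.0, 0.0, 3.0 * k]
    ds.InstanceNumber = k + 1
    ds.PixelData = px.tobytes()
    np.save(os.path.join(truth, "slice%%d.npy" %% k), px)
    pydicom.dcmwrite(os.path.join(outdir, "ct%%03d.dcm" %% order[k]), ds,
                     enforce_file_format=True)
', rows, cols, n_slices, slope, intercept)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- suppressWarnings(system2("python", c(sf, shQuote(dir)),
                                     stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L)) return(NULL)
  dir
}

# reference pixel arrays saved by the fixture writer (row-major int16)
read_dicom_fixture_truth <- function(dir, n_slices = 4, rows = 8, cols = 8) {
  lapply(seq_len(n_slices) - 1, function(k) {
    con <- file.path(paste0(dir, "_truth"), sprintf("slice%d.npy", k))
    raw <- readBin(con, "raw", n = file.size(con))
    # .npy v1 header: magic(6) + version(2) + header_len(2) + header
    hlen <- as.integer(raw[9]) + 256L * as.integer(raw[10])
    px <- readBin(raw[(10 + hlen + 1):length(raw)], "integer", n = rows * cols,
                  size = 2, signed = TRUE, endian = "little")
    matrix(px, rows, cols, byrow = TRUE)
  })
}

# small deterministic sample table with fake features
toy_sample_table <- function(n = 12, n_features = 28, seed = 5) {
  set.seed(seed)
  tab <- data.frame(
    patient_id = rep(c("A", "B"), length.out = n),
    roi_id = rep(1:2, each = ceiling(n / 2))[1:n],
    slice = 1L, row = seq_len(n) + 2L, col = 5L,
    window_side = 3L,
    label = rep(c(1L, 2L, 3L), length.out = n),
    stringsAsFactors = FALSE
  )
  feats <- matrix(rnorm(n * n_features), n, n_features,
                  dimnames = list(NULL, feature_names("both")[seq_len(n_features)]))
  cbind(tab, as.data.frame(feats))
}

# linearly separable blobs table for classifier tests: class k centered at
# distance `sep` along feature k
separable_table <- function(n_per_class = 100, classes = 1:3, sep = 6, seed = 9) {
  set.seed(seed)
  rows <- lapply(classes, function(k) {
    X <- matrix(rnorm(n_per_class * 28), n_per_class, 28)
    X[, k] <- X[, k] + sep
    df <- data.frame(patient_id = paste0("P", rep(1:4, length.out = n_per_class)),
                     roi_id = k, slice = 1L, row = 1L, col = 1L,
                     window_side = 3L, label = k, stringsAsFactors = FALSE)
    cbind(df, stats::setNames(as.data.frame(X), feature_names("both")))
  })
  do.call(rbind, rows)
}
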