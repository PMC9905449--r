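# Minimal DICOM series reader: uncompressed single-frame little-endian
# images (explicit or implicit VR), which covers CT and reconstructed SPECT
# exports. Only the tags needed to assemble a volume are parsed.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

DCM_TAGS <- list(
  rows            = dcm_tag(0x0028, 0x0010),
  cols            = dcm_tag(0x0028, 0x0011),
  bits_alloc      = dcm_tag(0x0028, 0x0100),
  pixel_rep       = dcm_tag(0x0028, 0x0103),
  pixel_spacing   = dcm_tag(0x0028, 0x0030),
  slice_thickness = dcm_tag(0x0018, 0x0050),
  ipp             = dcm_tag(0x0020, 0x0032),
  rescale_int     = dcm_tag(0x0028, 0x1052),
  rescale_slope   = dcm_tag(0x0028, 0x1053),
  instance_number = dcm_tag(0x0020, 0x0013),
  transfer_syntax = dcm_tag(0x0002, 0x0010),
  pixel_data      = dcm_tag(0x7FE0, 0x0010)
)

read_uint <- function(raw, signed = FALSE) {
  n <- length(raw)
  v <- sum(as.integer(raw) * 2^(8 * (seq_len(n) - 1)))
  if (signed && v >= 2^(8 * n - 1)) v <- v - 2^(8 * n)
  v
}

# Parse one DICOM file into a list of raw element values keyed "GGGG,EEEE".
parse_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = file.size(path))
  if (length(bytes) < 132 + 8) stop("not a DICOM file (too short): ", path)
  explicit <- TRUE
  pos <- 1L
  if (rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  }
  elements <- list()
  n <- length(bytes)
  while (pos + 8 <= n + 1) {
    group <- read_uint(bytes[pos:(pos + 1)])
    element <- read_uint(bytes[(pos + 2):(pos + 3)])
    key <- dcm_tag(group, element)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
          len <- read_uint(bytes[(pos + 8):(pos + 11)])
          hdr <- 12L
        } else {
          len <- read_uint(bytes[(pos + 6):(pos + 7)])
          hdr <- 8L
        }
      } else {
        # file without preamble written implicit VR
        explicit <- FALSE
        len <- read_uint(bytes[(pos + 4):(pos + 7)])
        hdr <- 8L
      }
    } else {
      len <- read_uint(bytes[(pos + 4):(pos + 7)])
      hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length element (compressed/sequence) unsupported: ", key)
    val_start <- pos + hdr
    if (val_start + len - 1 > n) stop("truncated DICOM element ", key, " in ", path)
    if (len > 0) elements[[key]] <- bytes[val_start:(val_start + len - 1)]
    pos <- val_start + len
  }
  elements
}

dcm_string <- function(elements, key, default = NULL) {
  raw <- elements[[key]]
  if (is.null(raw)) return(default)
  trimws(rawToChar(raw[raw != as.raw(0)]))
}

dcm_numeric <- function(elements, key, default = NULL) {
  s <- dcm_string(elements, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(elements, key) {
  raw <- elements[[key]]
  if (is.null(raw)) return(NULL)
  read_uint(raw[1:2])
}

# Read an uncompressed single-frame DICOM series directory into a volume3d.
read_dicom_series <- function(path, modality) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM series directory: ", path)
  slices <- lapply(files, parse_dicom_file)
  ts <- dcm_string(slices[[1]], DCM_TAGS$transfer_syntax)
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported transfer syntax (compressed?): ", ts)
  nr <- dcm_us(slices[[1]], DCM_TAGS$rows)
  nc <- dcm_us(slices[[1]], DCM_TAGS$cols)
  bits <- dcm_us(slices[[1]], DCM_TAGS$bits_alloc)
  if (is.null(nr) || is.null(nc)) stop("DICOM missing Rows/Columns")
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit pixel data supported")
  signed <- identical(dcm_us(slices[[1]], DCM_TAGS$pixel_rep), 1)
  # slice order: z of ImagePositionPatient, falling back to InstanceNumber
  zpos <- vapply(slices, function(el) {
    ipp <- dcm_numeric(el, DCM_TAGS$ipp)
    if (!is.null(ipp) && length(ipp) == 3) ipp[3] else NA_real_
  }, numeric(1))
  if (anyNA(zpos)) {
    inst <- vapply(slices, function(el)
      dcm_numeric(el, DCM_TAGS$instance_number, NA_real_)[1], numeric(1))
    if (anyNA(inst)) stop("cannot sort series: no ImagePositionPatient or InstanceNumber")
    ord <- order(inst)
    dz <- dcm_numeric(slices[[1]], DCM_TAGS$slice_thickness, 1)[1]
  } else {
    ord <- order(zpos)
    if (length(zpos) > 1L) {
      gaps <- diff(sort(zpos))
      dz <- stats::median(gaps)
      if (any(abs(gaps - dz) > 0.01 * dz + 1e-6))
        stop(sprintf("non-uniform slice spacing: gaps range %.4g-%.4g mm", min(gaps), max(gaps)))
      if (dz <= 0) stop("duplicate slice positions in series")
    } else {
      dz <- dcm_numeric(slices[[1]], DCM_TAGS$slice_thickness, 1)[1]
    }
  }
  slices <- slices[ord]
  ps <- dcm_numeric(slices[[1]], DCM_TAGS$pixel_spacing, c(1, 1))
  vals <- array(0, dim = c(nr, nc, length(slices)))
  for (k in seq_along(slices)) {
    el <- slices[[k]]
    pd <- el[[DCM_TAGS$pixel_data]]
    if (is.null(pd)) stop("slice without PixelData in series")
    if (bits == 16L) {
      px <- readBin(pd, "integer", n = nr * nc, size = 2L,
                    signed = signed, endian = "little")
    } else {
      px <- as.integer(pd[seq_len(nr * nc)])
    }
    slope <- dcm_numeric(el, DCM_TAGS$rescale_slope, 1)[1]
    inter <- dcm_numeric(el, DCM_TAGS$rescale_int, 0)[1]
    # DICOM stores pixels row by row; R fills arrays column-major
    vals[, , k] <- matrix(px * slope + inter, nrow = nr, ncol = nc, byrow = TRUE)
  }
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  volume3d(vals, spacing = c(ps[2], ps[1], dz), modality = modality)
}
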