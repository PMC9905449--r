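# Windowed 2D radiomic features: gray-level discretization, GLCM / GLDM /
# GLRLM texture matrices and the reproducibility-selected 14-feature subset,
# computed per modality and concatenated CT-then-SPECT.

#' Radiomics configuration
#'
#' Fixed global gray-level bin edges per modality (shared by every window of
#' a modality so features are comparable across samples), the GLDM
#' similarity tolerance and the voxel volume used by TotalEnergy.
#'
#' @param ct_lo,ct_hi,ct_width CT binning: bin width in HU over
#'   `[ct_lo, ct_hi]`; defaults 25 HU over \[-1050, 400\].
#' @param spect_lo,spect_hi,spect_width Normalized-SPECT binning; defaults
#'   width 0.05 over \[0, 1.5\].
#' @param alpha GLDM gray-level similarity tolerance, default 0.
#' @param voxel_volume Voxel volume in mm^3 for TotalEnergy, default 1
#'   (unitless); set from the CT header for physical units.
#' @return List of class `radiomics_config`.
#' @export
radiomics_config <- function(ct_lo = -1050, ct_hi = 400, ct_width = 25,
                             spect_lo = 0, spect_hi = 1.5, spect_width = 0.05,
                             alpha = 0L, voxel_volume = 1) {
  structure(list(
    CT = list(lo = ct_lo, hi = ct_hi, width = ct_width,
              n_levels = as.integer(round((ct_hi - ct_lo) / ct_width))),
    SPECT = list(lo = spect_lo, hi = spect_hi, width = spect_width,
                 n_levels = as.integer(round((spect_hi - spect_lo) / spect_width))),
    alpha = as.integer(alpha), voxel_volume = voxel_volume
  ), class = "radiomics_config")
}

#' Names of the 14 radiomic features, in their fixed order
#'
#' Three first-order features, four from the gray-level co-occurrence matrix
#' (GLCM), three from the gray-level dependence matrix (GLDM) and four from
#' the gray-level run-length matrix (GLRLM).
#'
#' @param modality Optional `"CT"`/`"SPECT"` prefix; `NULL` returns the bare
#'   names.
#' @return Character vector (length 14, or 28 for `modality = "both"`).
#' @export
feature_names <- function(modality = NULL) {
  base <- c("Entropy", "TotalEnergy", "Uniformity",
            "Id", "Idm", "JointEnergy", "MaximumProbability",
            "DependenceNonUniformityNormalized", "DependenceVariance",
            "LargeDependenceEmphasis",
            "GrayLevelNonUniformityNormalized",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "ShortRunEmphasis")
  if (is.null(modality)) return(base)
  if (identical(modality, "both"))
    return(c(paste0("CT_", base), paste0("SPECT_", base)))
  paste0(modality, "_", base)
}

#' Discretize a window into gray levels
#'
#' Values are binned with the fixed global edges of the modality
#' (`level = floor((x - lo) / width) + 1`); values outside the global range
#' are clamped into the end bins. Level indices start at 1.
#'
#' @param window 2D numeric matrix of raw values.
#' @param modality `"CT"` or `"SPECT"`.
#' @param config A [radiomics_config()].
#' @param quiet Suppress the clamping warning.
#' @return List of class `discretized_window`: `levels` (integer matrix),
#'   `n_levels`, `bin_edges`; attribute `n_clamped`.
#' @export
discretize <- function(window, modality = c("CT", "SPECT"),
                       config = radiomics_config(), quiet = FALSE) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(window), all(is.finite(window)))
  b <- config[[modality]]
  lev <- floor((window - b$lo) / b$width) + 1
  n_clamped <- sum(lev < 1 | lev > b$n_levels)
  if (n_clamped > 0 && !quiet)
    warning(sprintf("%d value(s) outside the global %s range clamped to end bins",
                    n_clamped, modality))
  lev <- pmin(pmax(lev, 1), b$n_levels)
  storage.mode(lev) <- "integer"
  structure(
    list(levels = lev, n_levels = b$n_levels,
         bin_edges = seq(b$lo, b$hi, by = b$width)),
    class = "discretized_window", n_clamped = n_clamped
  )
}

# Compact a discretized window: remap occupied levels to 1..L, keeping the
# original level indices for distance-dependent features.
compact_levels <- function(dw) {
  vals <- sort(unique(as.vector(dw$levels)))
  lev <- matrix(match(dw$levels, vals), nrow(dw$levels), ncol(dw$levels))
  list(lev = lev, values = vals)
}

glcm_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Gray-level co-occurrence matrix of a discretized window
#'
#' Co-occurrences at distance 1 in the four 2D directions (0, 45, 90 and
#' 135 degrees), symmetrized, pooled across directions and normalized to
#' sum 1. Rows/columns are the occupied gray levels (original level indices
#' in `dimnames`).
#'
#' @param dw A [discretize()]d window.
#' @return Normalized symmetric matrix `P(i, j)`.
#' @export
glcm_matrix <- function(dw) {
  cl <- compact_levels(dw)
  lev <- cl$lev
  L <- length(cl$values)
  n <- nrow(lev); m <- ncol(lev)
  if (n * m < 2) stop("GLCM needs a window of at least 2 pixels")
  counts <- matrix(0, L, L)
  for (off in glcm_offsets) {
    rr <- seq_len(n); cc <- seq_len(m)
    r1 <- rr[rr + off[1] >= 1 & rr + off[1] <= n]
    c1 <- cc[cc + off[2] >= 1 & cc + off[2] <= m]
    if (length(r1) == 0 || length(c1) == 0) next
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
    key <- (a - 1L) * L + b
    tab <- tabulate(key, nbins = L * L)
    inc <- matrix(tab, L, L, byrow = TRUE)
    counts <- counts + inc + t(inc)
  }
  P <- counts / sum(counts)
  dimnames(P) <- list(cl$values, cl$values)
  P
}

#' GLCM features: JointEnergy, MaximumProbability, Id, Idm
#'
#' `JointEnergy = sum p^2`; `MaximumProbability = max p`;
#' `Id = sum p / (1 + |i - j|)` (inverse difference);
#' `Idm = sum p / (1 + (i - j)^2)` (inverse difference moment), with `i, j`
#' the gray-level indices.
#'
#' @param P Normalized GLCM from [glcm_matrix()].
#' @return Named numeric vector of the four features.
#' @export
glcm_features <- function(P) {
  lv <- as.numeric(rownames(P))
  if (is.null(lv) || anyNA(lv)) lv <- seq_len(nrow(P))
  dif <- abs(outer(lv, lv, "-"))
  c(Id = sum(P / (1 + dif)),
    Idm = sum(P / (1 + dif^2)),
    JointEnergy = sum(P^2),
    MaximumProbability = max(P))
}

#' First-order features: Entropy, TotalEnergy, Uniformity
#'
#' Computed on the discretized gray-level histogram (`p` the level
#' frequencies over occupied levels): `Entropy = -sum p log2(p + eps)` with
#' `eps = 2.2e-16`, `Uniformity = sum p^2`. `TotalEnergy = voxel_volume *
#' sum x^2` over the raw window values.
#'
#' @param window Raw 2D numeric matrix.
#' @param dw The corresponding [discretize()]d window.
#' @param voxel_volume Voxel volume in mm^3 (1 for unitless features).
#' @return Named numeric vector of the three features.
#' @export
first_order_features <- function(window, dw, voxel_volume = 1) {
  eps <- 2.2e-16
  counts <- tabulate(as.vector(dw$levels), nbins = dw$n_levels)
  p <- counts[counts > 0] / sum(counts)
  c(Entropy = -sum(p * log2(p + eps)),
    TotalEnergy = voxel_volume * sum(window^2),
    Uniformity = sum(p^2))
}

# Dependence size of every pixel: 1 + number of 8-neighbors (inside the
# window) whose gray level differs by at most alpha.
dependence_sizes <- function(lev, alpha = 0L) {
  n <- nrow(lev); m <- ncol(lev)
  cnt <- matrix(0L, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- seq_len(n); r1 <- r1[r1 + dr >= 1 & r1 + dr <= n]
    c1 <- seq_len(m); c1 <- c1[c1 + dc >= 1 & c1 + dc <= m]
    if (length(r1) == 0 || length(c1) == 0) next
    sim <- abs(lev[r1, c1, drop = FALSE] - lev[r1 + dr, c1 + dc, drop = FALSE]) <= alpha
    cnt[r1, c1] <- cnt[r1, c1] + sim
  }
  cnt + 1L
}

#' GLDM features: DependenceNonUniformityNormalized, DependenceVariance,
#' LargeDependenceEmphasis
#'
#' The dependence size of a pixel is one plus the number of its 8-neighbors
#' inside the window whose level differs by at most `alpha`. With `P(i, j)`
#' counting pixels of level `i` and dependence `j` and `Nz = sum P`:
#' `LDE = sum j^2 P / Nz`, `DNN = sum_j (sum_i P)^2 / Nz^2`,
#' `DV = sum (j - mu)^2 P / Nz`.
#'
#' @param dw A [discretize()]d window.
#' @param alpha Similarity tolerance, default 0 (exact level match).
#' @return Named numeric vector of the three features.
#' @export
gldm_features <- function(dw, alpha = 0L) {
  j <- as.numeric(dependence_sizes(dw$levels, alpha))
  nj <- tabulate(j, nbins = max(j))
  nz <- length(j)
  mu <- mean(j)
  c(DependenceNonUniformityNormalized = sum(nj^2) / nz^2,
    DependenceVariance = mean((j - mu)^2),
    LargeDependenceEmphasis = mean(j^2))
}

# Maximal same-level runs along one direction; returns a two-column matrix
# (level, length), one row per run.
runs_in_direction <- function(lev, direction) {
  n <- nrow(lev); m <- ncol(lev)
  lines <- switch(direction,
    horizontal = split(lev, row(lev)),
    vertical   = split(lev, col(lev)),
    diagonal   = split(lev, row(lev) - col(lev)),   # parallel to (1, 1)
    antidiag   = split(lev, row(lev) + col(lev))    # parallel to (-1, 1)
  )
  out <- lapply(lines, function(v) {
    r <- rle(as.vector(v))
    cbind(level = r$values, length = r$lengths)
  })
  do.call(rbind, out)
}

glrlm_directions <- c("horizontal", "antidiag", "vertical", "diagonal")

#' GLRLM features: GrayLevelNonUniformityNormalized,
#' RunLengthNonUniformityNormalized, RunPercentage, ShortRunEmphasis
#'
#' Maximal runs of equal level are counted in the four 2D directions; each
#' feature is computed per direction from the run-length matrix `P(i, j)`
#' (level `i`, length `j`; `Nr` runs, `Np` pixels) and averaged over
#' directions: `SRE = (sum P / j^2) / Nr`, `RP = Nr / Np`,
#' `RLNN = sum_j (sum_i P)^2 / Nr^2`, `GLNN = sum_i (sum_j P)^2 / Nr^2`.
#'
#' @param dw A [discretize()]d window.
#' @param directions Subset of the four directions (for tests).
#' @return Named numeric vector of the four features.
#' @export
glrlm_features <- function(dw, directions = glrlm_directions) {
  np <- length(dw$levels)
  if (np < 2) stop("GLRLM needs a window of at least 2 pixels")
  per_dir <- vapply(directions, function(d) {
    runs <- runs_in_direction(dw$levels, d)
    nr <- nrow(runs)
    len <- runs[, "length"]; levv <- runs[, "level"]
    c(GLNN = sum(tabulate(match(levv, unique(levv)))^2) / nr^2,
      RLNN = sum(tabulate(len, nbins = max(len))^2) / nr^2,
      RP = nr / np,
      SRE = sum(1 / len^2) / nr)
  }, numeric(4))
  avg <- rowMeans(per_dir)
  c(GrayLevelNonUniformityNormalized = avg[["GLNN"]],
    RunLengthNonUniformityNormalized = avg[["RLNN"]],
    RunPercentage = avg[["RP"]],
    ShortRunEmphasis = avg[["SRE"]])
}

#' Extract the full 28-value feature vector for one sample
#'
#' Computes the 14 features on the CT window and on the (normalized) SPECT
#' window and concatenates CT-then-SPECT in the fixed order of
#' [feature_names()].
#'
#' @param ct_window,spect_window 2D numeric matrices of equal side.
#' @param config A [radiomics_config()].
#' @return Named numeric vector of length 28, all finite.
#' @export
extract_feature_vector <- function(ct_window, spect_window,
                                   config = radiomics_config()) {
  stopifnot(all(dim(ct_window) == dim(spect_window)))
  fv <- c(
    modality_features(ct_window, "CT", config),
    modality_features(spect_window, "SPECT", config)
  )
  names(fv) <- feature_names("both")
  stopifnot(all(is.finite(fv)))
  fv
}

modality_features <- function(window, modality, config) {
  dw <- discretize(window, modality, config, quiet = TRUE)
  c(first_order_features(window, dw, config$voxel_volume),
    glcm_features(glcm_matrix(dw)),
    gldm_features(dw, config$alpha),
    glrlm_features(dw))
}

# 14 features of one modality for every row of a sample table, as a
# data frame of prefixed columns.
modality_features_for_samples <- function(samples, volume, modality, config) {
  feats <- matrix(NA_real_, nrow(samples), 14,
                  dimnames = list(NULL, feature_names(modality)))
  for (k in seq_len(nrow(samples))) {
    h <- (samples$window_side[k] - 1L) %/% 2L
    rr <- (samples$row[k] - h):(samples$row[k] + h)
    cc <- (samples$col[k] - h):(samples$col[k] + h)
    feats[k, ] <- modality_features(volume$values[rr, cc, samples$slice[k]],
                                    modality, config)
  }
  as.data.frame(feats)
}

#' Extract features for every sample of a sample table
#'
#' Discretizes the CT and normalized SPECT volumes once with the global bin
#' edges, then computes the 28-value feature vector of each sample's window.
#'
#' @param samples Sample table from [enumerate_window_samples()].
#' @param ct CT [volume3d()] (registered grid).
#' @param spect_norm Normalized SPECT [volume3d()] on the same grid.
#' @param config A [radiomics_config()]; its `voxel_volume` is used unless
#'   `use_ct_spacing` is TRUE, in which case it is taken from the CT header.
#' @param use_ct_spacing Take TotalEnergy's voxel volume from the CT.
#' @return `samples` with 28 feature columns appended.
#' @export
extract_features_for_samples <- function(samples, ct, spect_norm,
                                         config = radiomics_config(),
                                         use_ct_spacing = FALSE) {
  stopifnot(inherits(ct, "volume3d"), inherits(spect_norm, "volume3d"),
            all(dim(ct$values) == dim(spect_norm$values)))
  if (use_ct_spacing) config$voxel_volume <- voxel_volume(ct)
  if (nrow(samples) == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, 28,
                                  dimnames = list(NULL, feature_names("both"))))
    return(cbind(samples, empty))
  }
  feats <- matrix(NA_real_, nrow(samples), 28,
                  dimnames = list(NULL, feature_names("both")))
  for (k in seq_len(nrow(samples))) {
    h <- (samples$window_side[k] - 1L) %/% 2L
    rr <- (samples$row[k] - h):(samples$row[k] + h)
    cc <- (samples$col[k] - h):(samples$col[k] + h)
    s <- samples$slice[k]
    feats[k, ] <- extract_feature_vector(ct$values[rr, cc, s],
                                         spect_norm$values[rr, cc, s], config)
  }
  cbind(samples, as.data.frame(feats))
}
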