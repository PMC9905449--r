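# Lung segmentation, SPECT resizing/registration onto the CT grid, and
# SPECT intensity normalization.

#' Construct a binary mask on a reference grid
#' @param values Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Object of class `binary_mask3d`.
#' @export
binary_mask3d <- function(values, spacing = c(1, 1, 1)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.logical(values)) values <- array(values != 0, dim = dim(values))
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "binary_mask3d")
}

#' @export
print.binary_mask3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask3d> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' Construct a 3D affine transform
#'
#' The transform maps reference (fixed) voxel coordinates `x = (row, col,
#' slice)` to source (moving) voxel coordinates `y = A x + t`; resampling
#' with [apply_transform()] pulls source values back onto the reference
#' grid. Units are voxels of the respective grids.
#'
#' @param linear 3 x 3 matrix `A`, must be invertible.
#' @param translation Length-3 vector `t`.
#' @return Object of class `affine_transform3d`.
#' @export
affine_transform3d <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (abs(det(linear)) < 1e-12) stop("affine linear part is singular")
  structure(list(linear = linear, translation = translation),
            class = "affine_transform3d")
}

#' @export
print.affine_transform3d <- function(x, ...) {
  cat("<affine_transform3d> y = A x + t (voxel units)\nA =\n")
  print(round(x$linear, 6))
  cat("t =", round(x$translation, 6), "\n")
  invisible(x)
}

#' Serialize / deserialize an affine transform as JSON
#' @param transform An [affine_transform3d()].
#' @param path File path.
#' @return `read_transform` returns the transform; `write_transform` returns
#'   `path` invisibly.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(linear = as.vector(t(transform$linear)),  # row-major
         translation = transform$translation, units = "voxel"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform3d(matrix(j$linear, 3, 3, byrow = TRUE), j$translation)
}

#' Segment the lungs on a CT volume
#'
#' Voxels with intensity in the closed interval \[-950, -300\] HU are
#' thresholded (aerated parenchyma; denser than -300 is soft tissue, below
#' -950 is outside air), the largest 3D connected component (26-connectivity)
#' is kept, and the mask is smoothed by morphological closing with a ball of
#' the given radius to fill vessels and concave boundary notches.
#'
#' @param ct CT [volume3d()] in HU.
#' @param hu_range Closed HU interval, default `c(-950, -300)`.
#' @param closing_radius Ball radius in voxels for the closing, default 5.
#' @return A [binary_mask3d()] on the CT grid.
#' @export
segment_lungs_ct <- function(ct, hu_range = c(-950, -300), closing_radius = 5L) {
  stopifnot(inherits(ct, "volume3d"), ct$modality == "CT")
  v <- ct$values
  thr <- v >= hu_range[1] & v <= hu_range[2]
  if (!any(thr))
    stop(sprintf("empty segmentation: no voxel in [%g, %g] HU", hu_range[1], hu_range[2]))
  mask <- largest_component(thr)
  mask <- morphological_closing(binary_mask3d(mask, ct$spacing), closing_radius)
  mask
}

#' Morphological closing of a binary mask with a ball structuring element
#'
#' Dilation by a discrete ball of the given voxel radius followed by erosion
#' by the same ball; fills interior holes and concave notches smaller than
#' the ball. The mask is padded so the operation behaves as on an infinite
#' background (closing is extensive and idempotent).
#'
#' @param mask A [binary_mask3d()] or logical 3D array.
#' @param radius Ball radius in voxels (>= 1).
#' @return A [binary_mask3d()].
#' @export
morphological_closing <- function(mask, radius = 5L) {
  spacing <- c(1, 1, 1)
  if (inherits(mask, "binary_mask3d")) { spacing <- mask$spacing; mask <- mask$values }
  stopifnot(radius >= 1)
  if (!any(mask)) return(binary_mask3d(array(FALSE, dim(mask)), spacing))
  r <- as.integer(radius)
  ball <- ball_element(r)
  d <- dim(mask)
  padded <- array(0, dim = d + 2L * r)
  padded[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <- mask
  # counts are integers, so rounding makes the FFT result exact
  dil <- round(fft_convolve3d(padded, ball)) > 0
  ero <- round(fft_convolve3d(dil + 0, ball)) == sum(ball)
  binary_mask3d(ero[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])],
                spacing)
}

#' Segment the lungs on a perfusion SPECT volume
#'
#' Background voxels have essentially no tracer, so a simple count threshold
#' separates perfused lung: voxels with intensity strictly greater than the
#' threshold are lung.
#'
#' @param spect SPECT [volume3d()] in counts.
#' @param threshold Count threshold, default 20.
#' @return A [binary_mask3d()] on the SPECT grid.
#' @export
segment_lungs_spect <- function(spect, threshold = 20) {
  stopifnot(inherits(spect, "volume3d"), spect$modality == "SPECT")
  binary_mask3d(spect$values > threshold, spect$spacing)
}

#' Resize a SPECT volume onto the CT grid shape
#'
#' Trilinear interpolation with corner-aligned coordinate mapping along all
#' three axes, so the first and last voxels of each axis coincide. The
#' result carries the CT's shape and spacing.
#'
#' @param spect SPECT [volume3d()].
#' @param ct CT [volume3d()] defining the target shape and spacing.
#' @return A SPECT [volume3d()] on the CT grid.
#' @export
resize_spect_to_ct <- function(spect, ct) {
  stopifnot(inherits(spect, "volume3d"), inherits(ct, "volume3d"))
  ds <- dim(spect$values); dc <- dim(ct$values)
  if (any(ds < 2) || any(dc < 2))
    stop("resize requires at least 2 voxels along every axis")
  if (all(ds == dc)) {
    out <- spect; out$spacing <- ct$spacing
    return(out)
  }
  ax <- function(n_dst, n_src) 1 + (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1)
  coords <- as.matrix(expand.grid(r = ax(dc[1], ds[1]), c = ax(dc[2], ds[2]),
                                  s = ax(dc[3], ds[3])))
  vals <- array(interp3(spect$values, coords), dim = dc)
  volume3d(vals, ct$spacing, "SPECT", spect$units)
}

#' Resample a volume through an affine transform onto a reference grid
#'
#' For every reference voxel `x`, the output value is the trilinear sample
#' of `volume` at `A x + t`; voxels mapping outside the source grid are 0.
#'
#' @param volume Source [volume3d()].
#' @param transform An [affine_transform3d()] mapping reference voxel
#'   coordinates to source voxel coordinates.
#' @param reference [volume3d()] (or its dim/spacing) defining the output grid.
#' @return A [volume3d()] on the reference grid.
#' @export
apply_transform <- function(volume, transform, reference) {
  stopifnot(inherits(volume, "volume3d"), inherits(transform, "affine_transform3d"))
  dref <- dim(reference$values)
  grid <- as.matrix(expand.grid(r = seq_len(dref[1]), c = seq_len(dref[2]),
                                s = seq_len(dref[3])))
  src <- grid %*% t(transform$linear) +
    matrix(transform$translation, nrow(grid), 3, byrow = TRUE)
  vals <- array(interp3(volume$values, src), dim = dref)
  volume3d(vals, reference$spacing, volume$modality, volume$units)
}

# Mean-squared-error cost and analytic gradient for affine mask registration
# at one pyramid level. Parameters p = (vec(A) by column, tau) act about the
# fixed-mask centroid in finest-level voxel coordinates.
register_level_cost <- function(p, xs, fvals, mov, grad_arrs, cf, f) {
  A <- matrix(p[1:9], 3, 3)
  tau <- p[10:12]
  y_fine <- sweep(xs, 2, cf) %*% t(A) +
    matrix(cf + tau, nrow(xs), 3, byrow = TRUE)
  y_coarse <- (y_fine + (f - 1) / 2) / f
  m <- interp3(mov, y_coarse)
  r <- m - fvals
  cost <- mean(r^2)
  G <- cbind(interp3(grad_arrs[[1]], y_coarse),
             interp3(grad_arrs[[2]], y_coarse),
             interp3(grad_arrs[[3]], y_coarse)) / f
  gr <- G * (2 * r / length(r))
  gA <- t(gr) %*% sweep(xs, 2, cf)
  list(cost = cost, grad = c(as.vector(gA), colSums(gr)))
}

central_gradient3d <- function(x) {
  d <- dim(x)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (x[3:d[1], , ] - x[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (x[, 3:d[2], ] - x[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (x[, , 3:d[3]] - x[, , 1:(d[3] - 2)]) / 2
  list(gx, gy, gz)
}

#' Affine registration of two binary masks by mean squared error
#'
#' Estimates the affine transform mapping fixed-grid voxel coordinates onto
#' the moving grid so that the transformed moving mask matches the fixed
#' mask. Both masks are smoothed with a small Gaussian so the MSE cost is
#' differentiable, and the cost is minimized by BFGS with analytic gradients
#' over a 3-level multi-resolution pyramid, initialized at center-of-mass
#' alignment. Registering masks rather than intensities sidesteps the
#' multimodal intensity relationship between CT and SPECT.
#'
#' @param moving,fixed [binary_mask3d()] objects on the same grid shape.
#' @param sigma Gaussian smoothing in voxels, default 2.
#' @param levels Integer downsampling factors of the pyramid (coarse to
#'   fine), default `c(4, 2, 1)`.
#' @param maxit Maximum BFGS iterations per level (recycled along
#'   `levels`), default `c(150, 80, 40)`.
#' @param reltol Relative cost-change stopping tolerance, default 1e-8.
#' @return An [affine_transform3d()]; attribute `converged` is FALSE (with a
#'   warning) if any level hit the iteration cap.
#' @export
register_masks_affine <- function(moving, fixed, sigma = 2, levels = c(4L, 2L, 1L),
                                  maxit = c(150L, 80L, 40L), reltol = 1e-8) {
  stopifnot(inherits(moving, "binary_mask3d"), inherits(fixed, "binary_mask3d"))
  if (!any(moving$values) || !any(fixed$values))
    stop("cannot register empty masks")
  if (!all(dim(moving$values) == dim(fixed$values)))
    stop("masks must share a grid shape (resize first)")
  mov_s <- gaussian_smooth3d(moving$values + 0, sigma)
  fix_s <- gaussian_smooth3d(fixed$values + 0, sigma)
  com <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    colMeans(idx)
  }
  cf <- com(fixed$values)
  p <- c(as.vector(diag(3)), com(moving$values) - cf)
  converged <- TRUE
  maxit <- rep_len(maxit, length(levels))
  for (li in seq_along(levels)) {
    f <- levels[li]
    if (f > 1) {
      mov_l <- block_downsample(mov_s, f)
      fix_l <- block_downsample(fix_s, f)
    } else {
      mov_l <- mov_s; fix_l <- fix_s
    }
    ga <- central_gradient3d(mov_l)
    # sample where either smoothed mask has support; at full resolution a
    # stride-2 in-plane subsample retains sub-voxel accuracy at 4x speed
    keep <- which(fix_l > 1e-4 | mov_l > 1e-4)
    if (f == 1) {
      dl1 <- dim(fix_l)
      i0k <- keep - 1L
      rk <- i0k %% dl1[1] + 1L
      ck <- (i0k %/% dl1[1]) %% dl1[2] + 1L
      keep <- keep[rk %% 2L == 1L & ck %% 2L == 1L]
    }
    dl <- dim(fix_l)
    i0 <- keep - 1L
    xc <- cbind(i0 %% dl[1] + 1L, (i0 %/% dl[1]) %% dl[2] + 1L,
                i0 %/% (dl[1] * dl[2]) + 1L)
    xs <- (xc - 1) * f + (f + 1) / 2   # fine-level coords of block centers
    fvals <- fix_l[keep]
    env <- new.env()
    fn <- function(p) {
      res <- register_level_cost(p, xs, fvals, mov_l, ga, cf, f)
      env$grad <- res$grad
      res$cost
    }
    gr <- function(p) { fn(p); env$grad }
    opt <- stats::optim(p, fn, gr, method = "BFGS",
                        control = list(maxit = maxit[li], reltol = reltol))
    p <- opt$par
    if (opt$convergence != 0 && f == 1) converged <- FALSE
  }
  A <- matrix(p[1:9], 3, 3)
  tau <- p[10:12]
  tr <- affine_transform3d(A, as.vector(cf + tau - A %*% cf))
  if (!converged)
    warning("mask registration hit the iteration cap; returning best transform found")
  attr(tr, "converged") <- converged
  tr
}

#' Normalize SPECT intensities
#'
#' Compensates between-scan differences in tracer concentration. In `MAX`
#' mode the scan is mapped to `[0, 1]` with `(x - min) / (max - min)`. In
#' `PERCENTILE99` mode the denominator is the 99th percentile minus the
#' minimum, so the 99th-percentile intensity maps to exactly 1 and focal
#' hotspot artifacts above it exceed 1 instead of compressing the rest of
#' the scan; values are not clipped. Statistics are computed over the full
#' volume; percentiles use linear interpolation between order statistics.
#'
#' @param spect SPECT [volume3d()].
#' @param mode `"MAX"` or `"PERCENTILE99"`.
#' @return A [volume3d()] with `units = "normalized"`.
#' @export
normalize_spect <- function(spect, mode = c("MAX", "PERCENTILE99")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spect, "volume3d"))
  v <- spect$values
  lo <- min(v)
  hi <- if (mode == "MAX") max(v) else
    stats::quantile(v, 0.99, names = FALSE, type = 7)
  if (hi - lo <= 0)
    stop("cannot normalize: zero denominator (constant volume",
         if (mode != "MAX") " up to the 99th percentile", ")")
  volume3d((v - lo) / (hi - lo), spect$spacing, "SPECT", "normalized")
}
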