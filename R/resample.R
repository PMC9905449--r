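# Trilinear interpolation and FFT-based 3D convolution: shared numerical
# primitives for resizing, affine resampling, smoothing and morphology.

#' Trilinear interpolation of a 3D array at continuous voxel coordinates
#'
#' Coordinates are 1-based voxel indices `(row, col, slice)`; points outside
#' the grid return `fill`.
#'
#' @param arr 3D numeric array.
#' @param coords N x 3 matrix of `(row, col, slice)` coordinates.
#' @param fill Value for out-of-grid points.
#' @return Numeric vector of length N.
#' @export
interp3 <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  r <- coords[, 1]; c <- coords[, 2]; s <- coords[, 3]
  inside <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2] & s >= 1 & s <= d[3]
  out <- rep(fill, nrow(coords))
  if (!any(inside)) return(out)
  r <- r[inside]; c <- c[inside]; s <- s[inside]
  r0 <- pmin(floor(r), d[1] - 1L); r0 <- pmax(r0, 1)
  c0 <- pmin(floor(c), d[2] - 1L); c0 <- pmax(c0, 1)
  s0 <- pmin(floor(s), d[3] - 1L); s0 <- pmax(s0, 1)
  fr <- r - r0; fc <- c - c0; fs <- s - s0
  n12 <- d[1] * d[2]
  base <- (r0 - 1) + (c0 - 1) * d[1] + (s0 - 1) * n12 + 1
  v000 <- arr[base];                  v100 <- arr[base + 1]
  v010 <- arr[base + d[1]];           v110 <- arr[base + d[1] + 1]
  v001 <- arr[base + n12];            v101 <- arr[base + n12 + 1]
  v011 <- arr[base + n12 + d[1]];     v111 <- arr[base + n12 + d[1] + 1]
  out[inside] <-
    v000 * (1 - fr) * (1 - fc) * (1 - fs) + v100 * fr * (1 - fc) * (1 - fs) +
    v010 * (1 - fr) * fc * (1 - fs)       + v110 * fr * fc * (1 - fs) +
    v001 * (1 - fr) * (1 - fc) * fs       + v101 * fr * (1 - fc) * fs +
    v011 * (1 - fr) * fc * fs             + v111 * fr * fc * fs
  out
}

# Zero-padded "same" convolution of a 3D array with a centered 3D kernel.
fft_convolve3d <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  stopifnot(all(dk %% 2 == 1))
  dp <- dx + dk - 1
  xp <- array(0, dim = dp); xp[1:dx[1], 1:dx[2], 1:dx[3]] <- x
  kp <- array(0, dim = dp); kp[1:dk[1], 1:dk[2], 1:dk[3]] <- kernel
  conv <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(dp)
  half <- (dk - 1) / 2
  conv[(half[1] + 1):(half[1] + dx[1]),
       (half[2] + 1):(half[2] + dx[2]),
       (half[3] + 1):(half[3] + dx[3])]
}

# Discrete ball structuring element of given voxel radius.
ball_element <- function(radius) {
  stopifnot(radius >= 1)
  g <- seq(-radius, radius)
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  array(as.numeric(d2 <= radius^2), dim = rep(2 * radius + 1, 3))
}

# Isotropic Gaussian smoothing via FFT convolution (kernel truncated at 3
# sigma, normalized to unit sum).
gaussian_smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(outer(g, g), g)
  fft_convolve3d(x, k / sum(k))
}

# Block-mean downsampling by an integer factor per axis (trailing partial
# blocks dropped). Used for the registration pyramid.
block_downsample <- function(x, f) {
  d <- dim(x)
  nd <- d %/% f
  stopifnot(all(nd >= 2))
  x <- x[1:(nd[1] * f), 1:(nd[2] * f), 1:(nd[3] * f)]
  dim(x) <- c(f, nd[1], f, nd[2], f, nd[3])
  apply(x, c(2, 4, 6), mean)
}
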