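make_lung_ct <- function(dm = c(32, 32, 16)) {
  ct <- array(-1024, dim = dm)
  body <- qspect:::ellipsoid_mask(dm, (dm + 1) / 2, dm / 2 - 1)
  ct[body] <- 40
  ell <- qspect:::ellipsoid_mask(dm, (dm + 1) / 2, c(9, 7, 5))
  ct[ell] <- -800
  list(ct = volume3d(ct, c(1, 1, 1), "CT"), lung = ell)
}

test_that("CT lung segmentation recovers a lung-density ellipsoid", {
  fx <- make_lung_ct()
  mask <- segment_lungs_ct(fx$ct)
  # brute-force oracle: threshold + keep biggest labeled blob, no closing
  thr <- fx$ct$values >= -950 & fx$ct$values <= -300
  expect_equal(thr, fx$lung)   # clean phantom: threshold is exact here
  expect_gte(dice_coef(mask$values, fx$lung), 0.99)
})

test_that("segmentation with nothing in the HU range errors", {
  vol <- volume3d(array(-1000, dim = c(4, 4, 4)), c(1, 1, 1), "CT")
  expect_error(segment_lungs_ct(vol), "empty segmentation")
})

test_that("only the largest connected component survives thresholding", {
  ct <- array(0, dim = c(40, 20, 10))
  ct[2:11, 2:11, 2:6] <- -800    # 500 voxels
  ct[25:34, 5:14, 3:4] <- -800   # 200 voxels
  vol <- volume3d(ct, c(1, 1, 1), "CT")
  thr <- vol$values >= -950 & vol$values <= -300
  biggest <- largest_component(thr)
  expect_equal(sum(biggest), 500)
  expect_true(all(which(biggest) %in% which(ct == -800)))
  expect_false(any(biggest[25:34, 5:14, 3:4]))
})

test_that("closing fills interior holes and matches the brute-force oracle", {
  mask <- array(FALSE, dim = c(26, 26, 26))
  mask[4:23, 4:23, 4:23] <- TRUE
  mask[12:14, 12:14, 12:14] <- FALSE   # interior hole
  closed <- morphological_closing(binary_mask3d(mask), radius = 5)
  expect_true(all(closed$values[12:14, 12:14, 12:14]))
  expect_equal(closed$values, oracle_closing(mask, 5))
})

test_that("closing is extensive, idempotent, and maps empty to empty", {
  empty <- binary_mask3d(array(FALSE, dim = c(8, 8, 8)))
  expect_false(any(morphological_closing(empty, 3)$values))
  set.seed(42)
  for (i in 1:5) {
    m <- array(FALSE, dim = c(14, 14, 14))
    seeds <- cbind(sample(4:11, 3), sample(4:11, 3), sample(4:11, 3))
    for (k in 1:3) m[seeds[k, 1] + (-2:2), seeds[k, 2] + (-2:2), seeds[k, 3] + (-1:1)] <- TRUE
    once <- morphological_closing(binary_mask3d(m), radius = 2)
    twice <- morphological_closing(once, radius = 2)
    expect_true(all(once$values[m]))              # extensive
    expect_equal(twice$values, once$values)       # idempotent
    expect_equal(once$values, oracle_closing(m, 2))
  }
})

test_that("SPECT lung mask is a strict count threshold", {
  v <- volume3d(array(c(0, 20, 20.5, 21, 300, 5), dim = c(2, 3, 1)),
                c(1, 1, 1), "SPECT")
  mask <- segment_lungs_spect(v)
  expect_equal(mask$values, array(v$values > 20, dim = dim(v$values)))
  low <- volume3d(array(20, dim = c(3, 3, 2)), c(1, 1, 1), "SPECT")
  expect_false(any(segment_lungs_spect(low)$values))
  one <- volume3d(array(c(rep(0, 7), 21), dim = c(2, 2, 2)), c(1, 1, 1), "SPECT")
  expect_equal(which(segment_lungs_spect(one)$values), 8L)
  set.seed(3)
  rnd <- volume3d(array(runif(60, 0, 40), dim = c(5, 4, 3)), c(1, 1, 1), "SPECT")
  expect_equal(segment_lungs_spect(rnd)$values, rnd$values > 20)
})

test_that("SPECT resize to the CT grid interpolates linearly", {
  ct <- volume3d(array(0, dim = c(4, 4, 4)), c(1, 1, 1), "CT")
  ct$values[] <- -500
  # already on grid: unchanged
  sp_same <- volume3d(array(runif(64, 0, 100), dim = c(4, 4, 4)), c(2, 2, 2), "SPECT")
  rs <- resize_spect_to_ct(sp_same, ct)
  expect_equal(rs$values, sp_same$values, tolerance = 1e-12)
  expect_equal(rs$spacing, ct$spacing)
  # constant stays constant
  const <- volume3d(array(7, dim = c(2, 3, 2)), c(2, 2, 2), "SPECT")
  expect_true(all(abs(resize_spect_to_ct(const, ct)$values - 7) < 1e-12))
  # 2-slice ramp upsampled to 4 slices: corner-aligned thirds
  ramp <- volume3d(array(rep(c(0, 30), each = 4), dim = c(2, 2, 2)), c(1, 1, 2), "SPECT")
  up <- resize_spect_to_ct(ramp, ct)
  expect_equal(up$values[1, 1, ], c(0, 10, 20, 30), tolerance = 1e-12)
  # degenerate single-slice input refuses
  flat <- volume3d(array(1, dim = c(4, 4, 1)), c(1, 1, 1), "SPECT")
  expect_error(resize_spect_to_ct(flat, ct), "at least 2")
})

test_that("affine resampling honors identity, integer shifts and 0 fill", {
  set.seed(8)
  vol <- volume3d(array(runif(4 * 5 * 6, 0, 50), dim = c(4, 5, 6)), c(1, 1, 1), "SPECT")
  idt <- apply_transform(vol, affine_transform3d(), vol)
  expect_equal(idt$values, vol$values, tolerance = 1e-12)
  # a delta spike moves exactly opposite to the pull-back translation
  spike <- volume3d(array(0, dim = c(7, 7, 7)), c(1, 1, 1), "SPECT")
  spike$values[4, 4, 4] <- 9
  tr <- affine_transform3d(diag(3), c(1, 2, 0))  # out(x) = in(x + t)
  moved <- apply_transform(spike, tr, spike)
  expect_equal(moved$values[3, 2, 4], 9)
  expect_equal(sum(moved$values), 9)
  # voxels mapping outside the grid become 0
  far <- apply_transform(vol, affine_transform3d(diag(3), c(100, 0, 0)), vol)
  expect_true(all(far$values == 0))
  expect_error(affine_transform3d(matrix(0, 3, 3)), "singular")
})

test_that("mask registration recovers identity, translation and scale", {
  pat <- small_phantom()
  mask <- binary_mask3d(pat$lung_mask)
  idt <- register_masks_affine(mask, mask)
  expect_lt(norm(idt$linear - diag(3), "F") + sum(abs(idt$translation)), 0.01)

  dm <- dim(mask$values)
  shift <- c(5, 3, 0)
  shifted <- array(FALSE, dm)
  shifted[(1 + shift[1]):dm[1], (1 + shift[2]):dm[2], ] <-
    mask$values[1:(dm[1] - shift[1]), 1:(dm[2] - shift[2]), ]
  tr <- register_masks_affine(binary_mask3d(shifted), mask)
  total <- tr$linear %*% ((dm + 1) / 2) + tr$translation - (dm + 1) / 2
  expect_lt(max(abs(total - shift)), 0.5)

  vol <- volume3d(mask$values + 0, c(1, 1, 1), "SPECT")
  grow <- apply_transform(vol, affine_transform3d(diag(3) / 1.1,
                                                  (1 - 1 / 1.1) * (dm + 1) / 2), vol)
  tr2 <- suppressWarnings(register_masks_affine(binary_mask3d(grow$values > 0.5),
                                                mask))
  expect_lt(max(abs(diag(tr2$linear) - 1.1)), 0.02)
})

test_that("SPECT normalization follows the two printed conventions", {
  v3 <- volume3d(array(c(0, 10, 20, 0, 10, 20, 0, 20), dim = c(2, 2, 2)),
                 c(1, 1, 1), "SPECT")
  mx <- normalize_spect(v3, "MAX")
  expect_equal(sort(unique(as.vector(mx$values))), c(0, 0.5, 1))
  expect_equal(mx$units, "normalized")
  const <- volume3d(array(5, dim = c(2, 2, 2)), c(1, 1, 1), "SPECT")
  expect_error(normalize_spect(const, "MAX"), "constant")
  expect_error(normalize_spect(const, "PERCENTILE99"), "denominator")

  set.seed(10)
  vals <- array(sample(0:999), dim = c(10, 10, 10))
  vol <- volume3d(vals, c(1, 1, 1), "SPECT")
  pr <- normalize_spect(vol, "PERCENTILE99")
  q99 <- quantile(vals, 0.99, names = FALSE, type = 7)
  # the 99th-percentile intensity maps to exactly 1; the max exceeds 1
  expect_equal((q99 - min(vals)) / (q99 - min(vals)), 1)
  expect_equal(max(pr$values), (max(vals) - min(vals)) / (q99 - min(vals)))
  expect_gt(max(pr$values), 1)
  interp <- approx(as.vector(vals), as.vector(pr$values), xout = q99)$y
  expect_equal(interp, 1, tolerance = 1e-9)
})

test_that("normalization is shift-invariant and MAX stays within [0, 1]", {
  set.seed(11)
  for (i in 1:20) {
    vals <- array(rpois(120, lambda = runif(1, 5, 80)), dim = c(6, 5, 4))
    if (diff(range(vals)) == 0) next
    vol <- volume3d(vals, c(1, 1, 1), "SPECT")
    mx <- normalize_spect(vol, "MAX")
    expect_true(all(mx$values >= 0 & mx$values <= 1))
    shifted <- volume3d(vals + 17, c(1, 1, 1), "SPECT")
    expect_equal(normalize_spect(shifted, "MAX")$values, mx$values,
                 tolerance = 1e-12)
    pr <- normalize_spect(vol, "PERCENTILE99")
    expect_equal(normalize_spect(shifted, "PERCENTILE99")$values, pr$values,
                 tolerance = 1e-12)
  }
})

test_that("a focal hotspot barely moves percentile-normalized lung values", {
  pat <- small_phantom()
  spect <- pat$spect_aligned$values
  lung <- pat$lung_mask
  clean <- spect
  clean[clean > 30 * mean(clean[lung])] <- mean(clean[lung])  # strip hotspots
  spot <- clean
  spot[which(lung)[1]] <- 50 * mean(clean[lung])
  nm <- function(v, mode) normalize_spect(volume3d(v, c(1, 1, 1), "SPECT"), mode)$values
  d_max <- abs(mean(nm(spot, "MAX")[lung]) - mean(nm(clean, "MAX")[lung]))
  d_prc <- abs(mean(nm(spot, "PERCENTILE99")[lung]) - mean(nm(clean, "PERCENTILE99")[lung]))
  expect_gt(d_max, 10 * d_prc)
})
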