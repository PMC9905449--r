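test_that("identical seeds reproduce bit-identical phantoms", {
  a <- generate_phantom_patient(seed = 101)
  b <- generate_phantom_patient(seed = 101)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$spect$values, b$spect$values)
  expect_identical(a$labels, b$labels)
  c2 <- generate_phantom_patient(seed = 102)
  expect_false(identical(a$spect$values, c2$spect$values))
})

test_that("PE regions keep lung CT statistics but lose perfusion", {
  pat <- small_phantom()
  pe_mask <- Reduce(`|`, lapply(Filter(function(l) l$class == "PE", pat$lesions),
                                `[[`, "mask"))
  lesions_all <- Reduce(`|`, lapply(pat$lesions, `[[`, "mask"))
  healthy <- pat$lung_mask & !lesions_all
  spect <- pat$spect_aligned$values
  hot <- spect > 30 * mean(spect[pat$lung_mask])
  expect_lt(mean(spect[pe_mask & !hot]), 0.3 * mean(spect[healthy & !hot]))
  # CT in PE regions is indistinguishable from healthy lung
  set.seed(1)
  ct <- pat$ct$values
  tt <- t.test(sample(ct[pe_mask], 500), sample(ct[healthy], 500))
  expect_gt(tt$p.value, 0.01)
  # while pneumonia CT is far denser
  pn_mask <- Reduce(`|`, lapply(Filter(function(l) l$class == "PNEUMONIA",
                                       pat$lesions), `[[`, "mask"))
  expect_gt(mean(ct[pn_mask]) - mean(ct[healthy]), 300)
})

test_that("phantom ROIs cover all six classes and sit on pure patterns", {
  pat <- small_phantom()
  labs <- vapply(pat$rois, `[[`, 1L, "label")
  expect_setequal(unique(labs), 1:6)
  # every PE ROI pixel lies inside a true PE lesion
  pe_mask <- Reduce(`|`, lapply(Filter(function(l) l$class == "PE", pat$lesions),
                                `[[`, "mask"))
  for (roi in pat$rois[labs == TISSUE_CLASSES[["PE"]]]) {
    idx <- cbind(roi$pixels, roi$slice_index)
    expect_true(all(pe_mask[idx]))
  }
  # healthy ROI pixels avoid every lesion
  lesions_all <- Reduce(`|`, lapply(pat$lesions, `[[`, "mask"))
  for (roi in pat$rois[labs == TISSUE_CLASSES[["HEALTHY"]]]) {
    idx <- cbind(roi$pixels, roi$slice_index)
    expect_true(all(pat$lung_mask[idx] & !lesions_all[idx]))
  }
})

test_that("the emitted SPECT grid is coarser and its misalignment is known", {
  pat <- small_phantom()
  expect_true(all(dim(pat$spect$values) < dim(pat$ct$values)))
  # resampling the aligned SPECT through the stored affine reproduces the
  # emitted coarse volume
  grid <- as.matrix(expand.grid(r = seq_len(dim(pat$spect$values)[1]),
                                c = seq_len(dim(pat$spect$values)[2]),
                                s = seq_len(dim(pat$spect$values)[3])))
  src <- grid %*% t(pat$gen_transform$linear) +
    matrix(pat$gen_transform$translation, nrow(grid), 3, byrow = TRUE)
  again <- array(interp3(pat$spect_aligned$values, src),
                 dim = dim(pat$spect$values))
  expect_equal(again, pat$spect$values, tolerance = 1e-12)
})

test_that("cohort generation writes volumes and a consistent manifest", {
  dir <- file.path(tempdir(), "cohort_t")
  unlink(dir, recursive = TRUE)
  mf <- generate_cohort(dir, n_train = 2, n_test = 1, seed = 5)
  expect_equal(nrow(mf), 3L)
  expect_equal(mf$group, c("train", "train", "test"))
  expect_identical(read_cohort_manifest(dir)$patient_id, mf$patient_id)
  for (pid in mf$patient_id)
    expect_true(all(file.exists(file.path(dir, pid,
                                          c("ct.nii.gz", "spect.nii.gz", "labels.nii.gz")))))
  # manifest sample counts equal a fresh enumeration of the written labels
  p1 <- mf$patient_id[1]
  rois <- read_roi_labels(file.path(dir, p1, "labels.nii.gz"), p1)
  s3 <- sum(vapply(rois, function(r) nrow(enumerate_window_samples(r, 3L)), 1L))
  expect_equal(s3, mf$samples_w3[1])
  # distinct patients are distinct volumes
  v1 <- read_volume(file.path(dir, mf$patient_id[1], "ct.nii.gz"), "CT")
  v2 <- read_volume(file.path(dir, mf$patient_id[2], "ct.nii.gz"), "CT")
  expect_false(identical(v1$values, v2$values))
})

test_that("stored misalignment transforms round-trip through JSON", {
  pat <- small_phantom()
  f <- file.path(tempdir(), "tr.json")
  write_transform(pat$gen_transform, f)
  back <- read_transform(f)
  expect_equal(back$linear, pat$gen_transform$linear, tolerance = 1e-12)
  expect_equal(back$translation, pat$gen_transform$translation, tolerance = 1e-12)
})
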