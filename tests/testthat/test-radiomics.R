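test_that("discretization uses fixed global edges and clamps outliers", {
  cfg <- radiomics_config()
  const <- discretize(matrix(-500, 3, 3), "CT", cfg)
  expect_equal(length(unique(as.vector(const$levels))), 1L)
  two <- discretize(matrix(c(-500, -400, -500, -400), 2, 2), "CT", cfg)
  expect_equal(length(unique(as.vector(two$levels))), 2L)
  # shifting by one bin width shifts every level index by one
  set.seed(2)
  w <- matrix(runif(25, -900, 300), 5, 5)
  l0 <- discretize(w, "CT", cfg)$levels
  l1 <- discretize(w + cfg$CT$width, "CT", cfg)$levels
  expect_equal(l1, l0 + 1L)
  # clamping warns and lands in the end bins
  expect_warning(hi <- discretize(matrix(c(1e5, -1e5, 0, 0), 2, 2), "CT", cfg),
                 "clamped")
  expect_equal(range(hi$levels), c(1L, cfg$CT$n_levels))
  expect_silent(discretize(matrix(1e5, 2, 2), "CT", cfg, quiet = TRUE))
})

test_that("GLCM is symmetric, normalized, and matches pair enumeration", {
  checker <- structure(list(levels = matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L), 3, 3),
                            n_levels = 2L, bin_edges = 1:3),
                       class = "discretized_window")
  P <- glcm_matrix(checker)
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  expect_equal(unname(P), unname(oracle_glcm(checker$levels)))
  const <- structure(list(levels = matrix(3L, 3, 3), n_levels = 5L, bin_edges = 1:6),
                     class = "discretized_window")
  expect_equal(unname(glcm_matrix(const)), matrix(1, 1, 1))
})

test_that("constant and closed-form windows give the stated feature values", {
  cfg <- radiomics_config(voxel_volume = 1)
  # constant window of raw value 2 discretizes to one level
  win <- matrix(2, 3, 3)
  dw <- discretize(win, "SPECT", radiomics_config(spect_hi = 3), quiet = TRUE)
  fo <- first_order_features(win, dw, voxel_volume = 1)
  expect_equal(fo[["Entropy"]], 0, tolerance = 1e-12)
  expect_equal(fo[["Uniformity"]], 1)
  expect_equal(fo[["TotalEnergy"]], 36)
  g <- glcm_features(glcm_matrix(dw))
  expect_equal(unname(g), c(1, 1, 1, 1))
  # half level-A half level-B: one bit of entropy
  w2 <- matrix(rep(c(-800, -400), each = 8), 4, 4)
  dw2 <- discretize(w2, "CT", cfg, quiet = TRUE)
  fo2 <- first_order_features(w2, dw2)
  expect_equal(fo2[["Entropy"]], 1, tolerance = 1e-9)
  expect_equal(fo2[["Uniformity"]], 0.5)
  # uniform GLCM over 2x2 levels
  P <- matrix(0.25, 2, 2, dimnames = list(1:2, 1:2))
  gu <- glcm_features(P)
  expect_equal(gu[["JointEnergy"]], 0.25)
  expect_equal(gu[["MaximumProbability"]], 0.25)
})

test_that("all-distinct and constant windows pin GLDM/GLRLM features", {
  distinct <- structure(list(levels = matrix(1:9, 3, 3), n_levels = 9L,
                             bin_edges = 1:10),
                        class = "discretized_window")
  gd <- gldm_features(distinct)
  expect_equal(gd[["LargeDependenceEmphasis"]], 1)
  expect_equal(gd[["DependenceVariance"]], 0)
  gr <- glrlm_features(distinct)
  expect_equal(gr[["ShortRunEmphasis"]], 1)
  expect_equal(gr[["RunPercentage"]], 1)

  const <- structure(list(levels = matrix(7L, 3, 3), n_levels = 9L,
                          bin_edges = 1:10),
                     class = "discretized_window")
  # 3x3 constant window, horizontal runs only: 3 runs of length 3
  gh <- glrlm_features(const, directions = "horizontal")
  expect_equal(gh[["ShortRunEmphasis"]], 1 / 9)
  expect_equal(gh[["RunPercentage"]], 1 / 3)
  expect_equal(gh[["GrayLevelNonUniformityNormalized"]], 1)
  expect_equal(gh[["RunLengthNonUniformityNormalized"]], 1)
  # constant window dependence sizes: 4 corners dep 4, 4 edges dep 6, 1
  # center dep 9
  gdc <- gldm_features(const)
  js <- c(rep(4, 4), rep(6, 4), 9)
  expect_equal(gdc[["LargeDependenceEmphasis"]], mean(js^2))
  expect_equal(gdc[["DependenceVariance"]], mean((js - mean(js))^2))
})

test_that("every feature matches its brute-force oracle on random windows", {
  set.seed(77)
  for (i in 1:60) {
    side <- sample(c(3L, 5L), 1)
    nlev <- sample(2:8, 1)
    rw <- random_window(side, nlev)
    got <- package_all_features(rw$raw, rw$lev)
    want <- oracle_all_features(rw$raw, rw$lev)
    expect_equal(unname(got), unname(want), tolerance = 1e-10,
                 info = sprintf("window %d side %d levels %d", i, side, nlev))
    # Id >= Idm always (1 + d >= 1 + d^2 only for d <= 1, but summed with
    # the same weights Id's denominators are never larger)
    expect_gte(got[["Id"]] + 1e-12, got[["Idm"]])
  }
})

test_that("features invariant to monotone relabeling keep their values", {
  set.seed(13)
  invariant <- c("JointEnergy", "MaximumProbability", "Uniformity", "Entropy",
                 "RunPercentage", "ShortRunEmphasis")
  for (i in 1:10) {
    rw <- random_window(5L, 5L)
    relab <- sort(sample(1:40, 5))  # strictly increasing map 1..5 -> new codes
    lev2 <- matrix(relab[rw$lev], 5, 5)
    f1 <- package_all_features(rw$raw, rw$lev)
    f2 <- package_all_features(rw$raw, lev2)
    expect_equal(f1[invariant], f2[invariant], tolerance = 1e-12)
  }
})

test_that("feature vectors concatenate CT then SPECT in fixed order", {
  set.seed(4)
  ctw <- matrix(rnorm(9, -700, 80), 3, 3)
  spw <- matrix(runif(9, 0, 1.2), 3, 3)
  fv <- extract_feature_vector(ctw, spw)
  expect_length(fv, 28L)
  expect_equal(names(fv), feature_names("both"))
  expect_true(all(is.finite(fv)))
  # first-order features ignore pixel order
  perm <- sample(9)
  fv2 <- extract_feature_vector(matrix(ctw[perm], 3, 3), matrix(spw[perm], 3, 3))
  fo <- c("CT_Entropy", "CT_TotalEnergy", "CT_Uniformity",
          "SPECT_Entropy", "SPECT_TotalEnergy", "SPECT_Uniformity")
  expect_equal(fv[fo], fv2[fo], tolerance = 1e-12)
  # constant windows produce the deterministic degenerate vector; runs per
  # direction on a constant 3x3 are 3+3+5+5 over 4 x 9 pixels
  fvc <- extract_feature_vector(matrix(-800, 3, 3), matrix(0.5, 3, 3))
  expect_equal(unname(fvc["CT_Uniformity"]), 1)
  expect_equal(unname(fvc["CT_JointEnergy"]), 1)
  expect_equal(unname(fvc["SPECT_RunPercentage"]), 4 / 9)
})

test_that("batch extraction reproduces single-window extraction", {
  pat <- small_phantom()
  prep_spect <- normalize_spect(pat$spect_aligned, "PERCENTILE99")
  rois <- pat$rois[vapply(pat$rois, function(r) nrow(r$pixels) > 30, TRUE)]
  samples <- enumerate_window_samples(rois[[1]], 3L)[1:4, ]
  tab <- extract_features_for_samples(samples, pat$ct, prep_spect)
  for (k in seq_len(nrow(tab))) {
    rr <- (tab$row[k] - 1):(tab$row[k] + 1)
    cc <- (tab$col[k] - 1):(tab$col[k] + 1)
    fv <- extract_feature_vector(pat$ct$values[rr, cc, tab$slice[k]],
                                 prep_spect$values[rr, cc, tab$slice[k]])
    expect_equal(unlist(tab[k, feature_names("both")]), fv, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
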