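# Synthetic paired CT / perfusion-SPECT phantom patients with labeled 2D
# ROIs of all six tissue-pattern classes, so every pipeline stage can be
# exercised without clinical data.

#' Phantom generation parameters
#'
#' Defaults describe a small thorax-like scene: two ellipsoidal lungs of
#' aerated-parenchyma CT texture inside a soft-tissue body on an air
#' background; a smooth perfusion field with Poisson count noise on SPECT;
#' pleural-based wedge perfusion defects with untouched CT (the PE
#' signature); consolidation blobs with raised CT and preserved perfusion
#' (pneumonia); blobs with both abnormalities (extra category 4); and a few
#' focal hotspot voxels far above lung counts, the artifact that motivates
#' percentile rather than maximum normalization. The SPECT volume is
#' emitted on a coarser grid misaligned by a known random affine so that
#' resizing and registration are exercised.
#'
#' @param dim CT grid size `(rows, cols, slices)`, default `c(64, 64, 20)`.
#' @param spacing CT voxel spacing mm, default `c(1.25, 1.25, 3)`.
#' @param ct_background,ct_body_mean,ct_body_sd,ct_lung_mean,ct_lung_sd,ct_pneumonia_mean,ct_pneumonia_sd
#'   CT intensity models (HU). Pneumonia mean must be at least 300 HU above
#'   the lung mean; PE regions keep the healthy lung CT model.
#' @param spect_base Baseline lung perfusion in counts, default 100.
#' @param spect_modulation Relative amplitude of the smooth perfusion
#'   inhomogeneity, default 0.25.
#' @param pe_multiplier SPECT multiplier inside PE defects, default 0.15
#'   (must be <= 0.3).
#' @param abnormal_multiplier SPECT multiplier in abnormal-CT/low-perfusion
#'   regions, default 0.2.
#' @param body_lambda,background_lambda Poisson rates outside the lungs.
#' @param hotspot_count,hotspot_amplitude Number of hotspot voxels and their
#'   amplitude as a multiple of the mean lung count, defaults 3 and 50.
#' @param spect_factor Integer coarsening factor of the emitted SPECT grid,
#'   default 2.
#' @param misalign_translation Max misalignment translation (CT voxels),
#'   default 3.
#' @param misalign_scale Misalignment scale range, default `c(0.98, 1.02)`.
#' @param n_rois Named integer vector: number of lesions/regions per class.
#' @param roi_radius In-plane disc radius range (pixels) for healthy /
#'   background / body ROIs.
#' @param max_attempts Placement retries before failing, default 50.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(72L, 72L, 20L), spacing = c(1.25, 1.25, 3),
                         ct_background = -1024, ct_body_mean = 40, ct_body_sd = 20,
                         ct_lung_mean = -800, ct_lung_sd = 60,
                         ct_pneumonia_mean = -400, ct_pneumonia_sd = 100,
                         spect_base = 100, spect_modulation = 0.25,
                         pe_multiplier = 0.15, abnormal_multiplier = 0.2,
                         body_lambda = 2, background_lambda = 0.2,
                         hotspot_count = 3L, hotspot_amplitude = 50,
                         spect_factor = 2L, misalign_translation = 3,
                         misalign_scale = c(0.98, 1.02),
                         n_rois = c(HEALTHY = 2L, PE = 2L, PNEUMONIA = 2L,
                                    ABNORMAL_CT_LOW_PERF = 1L, BACKGROUND = 1L,
                                    BODY_TISSUE = 1L),
                         roi_radius = c(4, 5), max_attempts = 150L) {
  stopifnot(ct_pneumonia_mean - ct_lung_mean >= 300,
            pe_multiplier <= 0.3, spect_factor >= 1)
  structure(as.list(environment()), class = "phantom_spec")
}

ellipsoid_mask <- function(dm, center, semi) {
  r <- (seq_len(dm[1]) - center[1]) / semi[1]
  c <- (seq_len(dm[2]) - center[2]) / semi[2]
  s <- (seq_len(dm[3]) - center[3]) / semi[3]
  outer(outer(r^2, c^2, "+"), s^2, "+") <= 1
}

disc_pixels <- function(center, radius, dm) {
  rr <- max(1, floor(center[1] - radius)):min(dm[1], ceiling(center[1] + radius))
  cc <- max(1, floor(center[2] - radius)):min(dm[2], ceiling(center[2] + radius))
  g <- expand.grid(row = rr, col = cc)
  g <- g[(g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2, ]
  as.matrix(g)
}

shift2d <- function(m, dr, dc, fill = FALSE) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- seq_len(n); cs <- seq_len(p)
  rd <- rs + dr; cd <- cs + dc
  okr <- rd >= 1 & rd <= n; okc <- cd >= 1 & cd <= p
  out[rd[okr], cd[okc]] <- m[rs[okr], cs[okc]]
  out
}

erode2d <- function(m, n = 1L) {
  for (i in seq_len(n)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc & shift2d(m, dr, dc, fill = FALSE)
    }
    m <- acc
  }
  m
}

dilate2d <- function(m, n = 1L) {
  for (i in seq_len(n)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- acc | shift2d(m, dr, dc, fill = FALSE)
    }
    m <- acc
  }
  m
}

#' Generate one phantom patient
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; identical seeds give bit-identical patients.
#' @param patient_id Identifier stored in the ROIs.
#' @return List: `ct` ([volume3d()]), `spect` (coarse, misaligned grid),
#'   `spect_aligned` (same grid as CT, for validation), `labels` (3D
#'   integer array on the CT grid), `rois` (list of [roi_annotation()]),
#'   `gen_transform` (the known coarse-to-CT-grid misalignment affine),
#'   `lung_mask` (true lung voxels) and `patient_id`.
#' @export
generate_phantom_patient <- function(spec = phantom_spec(), seed = 1L,
                                     patient_id = "P01") {
  stopifnot(inherits(spec, "phantom_spec"))
  restore <- local_rng(seed)
  on.exit(restore())
  dm <- as.integer(spec$dim)
  mid <- (dm + 1) / 2

  body <- ellipsoid_mask(dm, c(mid[1], mid[2], mid[3]), c(0.88, 0.82, 0.95) * dm / 2)
  lungs <- vector("list", 2)
  lung_centers <- list(c(mid[1] - 2, mid[2] - 14, mid[3]),
                       c(mid[1] - 2, mid[2] + 14, mid[3]))
  lung_semi <- c(17, 11, 7) + stats::runif(3, -0.5, 0.5)
  for (k in 1:2) {
    ctr <- lung_centers[[k]] + stats::runif(3, -1, 1)
    lungs[[k]] <- list(mask = ellipsoid_mask(dm, ctr, lung_semi),
                       center = ctr, semi = lung_semi)
  }
  # airway-like bridge so the lungs form one connected component, as the
  # real airway tree does on CT
  bridge <- array(FALSE, dim = dm)
  c1 <- lungs[[1]]$center; c2 <- lungs[[2]]$center
  bc <- round(seq(c1[2], c2[2]))
  br <- round(seq(c1[1], c2[1], length.out = length(bc))) - 4L
  bs <- round(seq(c1[3], c2[3], length.out = length(bc)))
  for (i in seq_along(bc)) {
    rr <- max(1, br[i] - 2L):min(dm[1], br[i] + 2L)
    ss <- max(1, bs[i] - 1L):min(dm[3], bs[i] + 1L)
    bridge[rr, bc[i], ss] <- TRUE
  }
  lung_mask <- lungs[[1]]$mask | lungs[[2]]$mask | bridge

  ct <- array(spec$ct_background, dim = dm)
  nb <- sum(body); ct[body] <- stats::rnorm(nb, spec$ct_body_mean, spec$ct_body_sd)
  nl <- sum(lung_mask); ct[lung_mask] <- stats::rnorm(nl, spec$ct_lung_mean, spec$ct_lung_sd)
  ct[ct < -1024] <- -1024

  # --- lesion placement -----------------------------------------------------
  lesion_masks <- list()  # per lesion: list(mask3d, class)
  occupied <- array(FALSE, dim = dm)
  place_wedge <- function(lung_index) {
    for (att in seq_len(spec$max_attempts)) {
      lg <- lungs[[lung_index]]
      theta0 <- stats::runif(1, -pi, pi)
      s0 <- round(lg$center[3] + stats::runif(1, -2, 2))
      zr <- max(2, s0 - 2):min(dm[3] - 1, s0 + 2)
      idx <- which(lg$mask, arr.ind = TRUE)
      idx <- idx[idx[, 3] %in% zr, , drop = FALSE]
      ang <- atan2(idx[, 1] - lg$center[1], idx[, 2] - lg$center[2])
      dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
      radf <- sqrt(((idx[, 1] - lg$center[1]) / lg$semi[1])^2 +
                     ((idx[, 2] - lg$center[2]) / lg$semi[2])^2)
      sel <- dang <= pi / 3 & radf >= 0.25
      if (sum(sel) < 140) next
      m <- array(FALSE, dim = dm)
      m[idx[sel, , drop = FALSE]] <- TRUE
      if (any(m & occupied)) next
      return(m)
    }
    stop("could not place a PE wedge without overlap after ",
         spec$max_attempts, " attempts")
  }
  lung_interior <- lapply(lungs, function(lg) {
    m <- lg$mask
    for (z in seq_len(dm[3])) m[, , z] <- erode2d(m[, , z], 4L)
    m[, , c(1:3, (dm[3] - 2):dm[3])] <- FALSE
    m
  })
  place_blob <- function() {
    for (att in seq_len(spec$max_attempts)) {
      free_n <- vapply(1:2, function(k) sum(lung_interior[[k]] & !occupied), 1L)
      if (sum(free_n) == 0) next
      k <- sample(1:2, 1, prob = free_n + 1e-9)
      lg <- lungs[[k]]
      cand <- which(lung_interior[[k]] & !occupied, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      ctr0 <- cand[sample(nrow(cand), 1), ]
      semi <- c(stats::runif(2, 4.5, 6.5), stats::runif(1, 2, 3))
      m <- ellipsoid_mask(dm, ctr0, semi) & lg$mask
      if (sum(m) < 100) next
      if (any(m & occupied)) next
      return(m)
    }
    stop("could not place a lesion blob without overlap after ",
         spec$max_attempts, " attempts")
  }
  lesion_plan <- c(rep("PE", spec$n_rois[["PE"]]),
                   rep("PNEUMONIA", spec$n_rois[["PNEUMONIA"]]),
                   rep("ABNORMAL_CT_LOW_PERF", spec$n_rois[["ABNORMAL_CT_LOW_PERF"]]))
  n_pe <- 0L
  for (cls in lesion_plan) {
    if (cls == "PE") {
      n_pe <- n_pe + 1L
      m <- place_wedge((n_pe - 1L) %% 2L + 1L)  # alternate lungs
    } else {
      m <- place_blob()
    }
    lesion_masks[[length(lesion_masks) + 1]] <- list(mask = m, class = cls)
    occupied <- occupied | dilate3d_inplane(m, 2L)
  }

  # CT changes: pneumonia and abnormal regions are consolidated
  for (les in lesion_masks) {
    if (les$class %in% c("PNEUMONIA", "ABNORMAL_CT_LOW_PERF")) {
      nn <- sum(les$mask)
      ct[les$mask] <- stats::rnorm(nn, spec$ct_pneumonia_mean, spec$ct_pneumonia_sd)
    }
  }

  # --- SPECT on the CT grid -------------------------------------------------
  rr <- seq_len(dm[1]); cc <- seq_len(dm[2]); ss <- seq_len(dm[3])
  modu <- 1 + spec$spect_modulation *
    outer(outer(sin(2 * pi * rr / dm[1]), cos(2 * pi * cc / dm[2])), ss * 0 + 1)
  lambda <- array(spec$background_lambda, dim = dm)
  lambda[body] <- spec$body_lambda
  lambda[lung_mask] <- (spec$spect_base * modu)[lung_mask]
  for (les in lesion_masks) {
    mult <- switch(les$class, PE = spec$pe_multiplier,
                   ABNORMAL_CT_LOW_PERF = spec$abnormal_multiplier, 1)
    if (mult < 1) lambda[les$mask] <- lambda[les$mask] * mult
  }
  spect_fine <- array(stats::rpois(prod(dm), lambda), dim = dm)
  if (spec$hotspot_count > 0) {
    healthy_lung <- lung_mask & !Reduce(`|`, lapply(lesion_masks, `[[`, "mask"),
                                        array(FALSE, dim = dm))
    hot <- sample(which(healthy_lung), spec$hotspot_count)
    spect_fine[hot] <- spec$hotspot_amplitude * mean(spect_fine[lung_mask])
  }

  # --- coarse misaligned SPECT grid ----------------------------------------
  f <- spec$spect_factor
  dm_c <- pmax(dm %/% f, 2L)
  sc <- stats::runif(3, spec$misalign_scale[1], spec$misalign_scale[2])
  tr <- stats::runif(3, -spec$misalign_translation, spec$misalign_translation)
  # coarse voxel x maps to fine coords: corner-aligned base mapping plus a
  # scale about the volume center and a translation
  ax <- function(n_c, n_f) (n_f - 1) / (n_c - 1)
  base_lin <- diag(ax(dm_c, dm))
  base_off <- 1 - diag(base_lin)
  A <- base_lin %*% diag(sc)
  ctr_f <- (dm + 1) / 2
  t_full <- base_off + as.vector(base_lin %*% ((1 - sc) * ctr_f)) + tr
  gen_transform <- affine_transform3d(A, t_full)
  grid_c <- as.matrix(expand.grid(r = seq_len(dm_c[1]), c = seq_len(dm_c[2]),
                                  s = seq_len(dm_c[3])))
  src <- grid_c %*% t(A) + matrix(t_full, nrow(grid_c), 3, byrow = TRUE)
  spect_coarse <- array(interp3(spect_fine, src), dim = dm_c)

  # --- labels / ROIs --------------------------------------------------------
  labels <- array(0L, dim = dm)
  add_lesion_rois <- function(les) {
    code <- TISSUE_CLASSES[[les$class]]
    zs <- sort(unique(which(les$mask, arr.ind = TRUE)[, 3]))
    areas <- vapply(zs, function(s) sum(les$mask[, , s]), 1L)
    zs <- zs[order(areas, decreasing = TRUE)]
    taken <- 0L
    for (s in zs) {
      if (taken >= 2L) break
      sect <- erode2d(les$mask[, , s], 1L)
      if (sum(sect) < 28) next
      sl <- labels[, , s]
      if (any(sl[sect] != 0)) next
      sl[sect] <- code
      labels[, , s] <<- sl
      taken <- taken + 1L
    }
    if (taken == 0L)
      stop("lesion of class ", les$class, " produced no usable ROI slice")
  }
  for (les in lesion_masks) add_lesion_rois(les)

  place_disc <- function(code, allowed3d) {
    for (att in seq_len(spec$max_attempts)) {
      radius <- stats::runif(1, spec$roi_radius[1], spec$roi_radius[2])
      s <- sample(3:(dm[3] - 2), 1)
      allowed <- erode2d(allowed3d[, , s], ceiling(radius)) &
        labels[, , s] == 0
      cand <- which(allowed, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      ctr <- cand[sample(nrow(cand), 1), ]
      px <- disc_pixels(ctr, radius, dm)
      sl <- labels[, , s]
      if (any(sl[px] != 0)) next
      sl[px] <- code
      labels[, , s] <<- sl
      return(invisible(TRUE))
    }
    stop("could not place a disc ROI of class ", tissue_class_name(code),
         " after ", spec$max_attempts, " attempts")
  }
  healthy_allowed <- lung_mask & !occupied
  for (i in seq_len(spec$n_rois[["HEALTHY"]]))
    place_disc(TISSUE_CLASSES[["HEALTHY"]], healthy_allowed)
  background_allowed <- !dilate3d_inplane(body, 3L)
  for (i in seq_len(spec$n_rois[["BACKGROUND"]]))
    place_disc(TISSUE_CLASSES[["BACKGROUND"]], background_allowed)
  body_allowed <- body & !dilate3d_inplane(lung_mask, 3L)
  for (i in seq_len(spec$n_rois[["BODY_TISSUE"]]))
    place_disc(TISSUE_CLASSES[["BODY_TISSUE"]], body_allowed)

  rois <- read_roi_labels(labels, patient_id = patient_id)
  list(
    ct = volume3d(ct, spec$spacing, "CT"),
    spect = volume3d(spect_coarse, spec$spacing * dm / dm_c, "SPECT"),
    spect_aligned = volume3d(spect_fine, spec$spacing, "SPECT"),
    labels = labels, rois = rois, gen_transform = gen_transform,
    lung_mask = lung_mask, lesions = lesion_masks, patient_id = patient_id
  )
}

dilate3d_inplane <- function(m, n = 1L) {
  for (s in seq_len(dim(m)[3])) m[, , s] <- dilate2d(m[, , s], n)
  m
}

#' Generate a phantom cohort on disk
#'
#' Writes one directory per patient (`ct.nii.gz`, `spect.nii.gz`,
#' `labels.nii.gz`) plus a `manifest.json` listing per-patient seeds, group
#' assignment and per-class ROI and window-sample counts.
#'
#' @param dir Output directory (created if needed).
#' @param n_train,n_test Patients per group.
#' @param spec A [phantom_spec()].
#' @param seed Integer master seed; per-patient seeds are derived from it.
#' @return Invisibly, the manifest as a data frame.
#' @export
generate_cohort <- function(dir, n_train = 20L, n_test = 20L,
                            spec = phantom_spec(), seed = 1L) {
  stopifnot(n_train + n_test >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%02d", i)
    pseed <- (as.integer(seed) * 131L + i * 7919L) %% 2147483647L
    # region placement is rejection sampling and can exhaust its attempts
    # for an unlucky seed; retry with a deterministically perturbed seed
    pat <- NULL
    for (retry in 0:9) {
      pat <- tryCatch(
        generate_phantom_patient(spec, seed = (pseed + retry * 500009L) %% 2147483647L,
                                 patient_id = pid),
        error = function(e) NULL)
      if (!is.null(pat)) break
    }
    if (is.null(pat))
      stop("could not generate phantom patient ", pid, " after 10 seed retries")
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    write_volume(pat$ct, file.path(pdir, "ct.nii.gz"))
    write_volume(pat$spect, file.path(pdir, "spect.nii.gz"))
    write_label_volume(pat$labels, spec$spacing, file.path(pdir, "labels.nii.gz"))
    write_transform(pat$gen_transform, file.path(pdir, "gen_transform.json"))
    roi_tab <- table(factor(vapply(pat$rois, `[[`, 1L, "label"), levels = 1:6))
    s3 <- sum(vapply(pat$rois, function(r) nrow(enumerate_window_samples(r, 3L)), 1L))
    s5 <- sum(vapply(pat$rois, function(r) nrow(enumerate_window_samples(r, 5L)), 1L))
    rows[[i]] <- data.frame(
      patient_id = pid, seed = pseed,
      group = if (i <= n_train) "train" else "test",
      n_rois = length(pat$rois),
      t(as.integer(roi_tab)) |> as.data.frame() |>
        stats::setNames(paste0("rois_", names(TISSUE_CLASSES))),
      samples_w3 = s3, samples_w5 = s5,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort manifest written by [generate_cohort()]
#' @param dir Cohort directory.
#' @return Data frame manifest.
#' @export
read_cohort_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
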