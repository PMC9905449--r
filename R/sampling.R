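# Enumeration of valid window-centered samples inside ROIs, and sample-count
# matching across window sizes.

#' Enumerate window-centered samples inside an ROI
#'
#' A pixel of the ROI is a valid sample center if and only if every pixel of
#' the `window_side` x `window_side` square centered on it also belongs to
#' the ROI, so features computed on the window never see unlabeled tissue.
#' Samples are returned in deterministic raster (row-major within column,
#' column-major overall following the pixel sort) order.
#'
#' @param roi A [roi_annotation()].
#' @param window_side Odd window side in pixels, 3 or 5 by default
#'   configurations.
#' @return Data frame with one row per valid center: `patient_id`, `roi_id`,
#'   `slice`, `row`, `col`, `window_side`, `label`. Zero rows if no window
#'   fits.
#' @export
enumerate_window_samples <- function(roi, window_side = 3L) {
  stopifnot(inherits(roi, "roi_annotation"))
  window_side <- as.integer(window_side)
  if (window_side < 3L || window_side %% 2L == 0L)
    stop("window_side must be odd and >= 3, got ", window_side)
  h <- (window_side - 1L) %/% 2L
  px <- roi$pixels
  key <- paste(px[, 1], px[, 2])
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  ok <- rep(TRUE, nrow(px))
  for (k in seq_len(nrow(offs))) {
    if (offs$dr[k] == 0L && offs$dc[k] == 0L) next
    ok <- ok & (paste(px[, 1] + offs$dr[k], px[, 2] + offs$dc[k]) %in% key)
  }
  centers <- px[ok, , drop = FALSE]
  ord <- order(centers[, 1], centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  data.frame(
    patient_id = rep(roi$patient_id, nrow(centers)),
    roi_id = rep(roi$roi_id, nrow(centers)),
    slice = rep(roi$slice_index, nrow(centers)),
    row = as.integer(centers[, 1]), col = as.integer(centers[, 2]),
    window_side = rep(window_side, nrow(centers)),
    label = rep(roi$label, nrow(centers)),
    stringsAsFactors = FALSE
  )
}

#' Match the sample counts of one table to another
#'
#' Larger windows fit in fewer ROI positions, so the two window sizes yield
#' different sample counts. For comparable statistics, the larger table is
#' subsampled uniformly without replacement to the smaller table's counts,
#' stratified by patient and tissue class so class balance per patient is
#' preserved. Reproducible given the seed.
#'
#' @param table_a Sample table to subsample (must have at least as many rows
#'   per patient-class stratum as `table_b`).
#' @param table_b Sample table defining the target stratum counts.
#' @param seed Integer RNG seed.
#' @param by Stratification columns, default `c("patient_id", "label")`.
#' @return Subsample of `table_a` (original row order preserved).
#' @export
match_sample_counts <- function(table_a, table_b, seed,
                                by = c("patient_id", "label")) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b))
  key_a <- interaction(table_a[by], drop = FALSE, sep = "|")
  key_b <- interaction(table_b[by], drop = FALSE, sep = "|")
  want <- table(as.character(key_b))
  have <- table(as.character(key_a))
  missing_strata <- setdiff(names(want), names(have))
  if (length(missing_strata) > 0)
    stop("strata absent from table_a: ", paste(missing_strata, collapse = ", "))
  short <- names(want)[want > have[names(want)]]
  if (length(short) > 0)
    stop("table_a has fewer rows than table_b in strata: ",
         paste(short, collapse = ", "))
  keep <- logical(nrow(table_a))
  rng <- local_rng(seed)
  on.exit(rng())
  for (strat in sort(names(want))) {
    rows <- which(as.character(key_a) == strat)
    n <- as.integer(want[[strat]])
    keep[if (length(rows) == n) rows else sample(rows, n)] <- TRUE
  }
  table_a[keep, , drop = FALSE]
}

# Set the RNG state for a scoped operation; returns a restorer function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
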