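# Connected-component labeling on logical arrays.
#
# 2D regions use 8-connectivity (annotated blobs are contiguous brush
# strokes); 3D lung masks use 26-connectivity. Both are the same BFS over a
# precomputed neighbor-offset stencil, vectorized over the current frontier.

neighbor_offsets <- function(ndim) {
  if (ndim == 2L) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
  } else {
    g <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  }
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  as.matrix(g)
}

#' Label connected components of a logical array
#'
#' 8-connectivity for 2D inputs, 26-connectivity for 3D inputs.
#'
#' @param mask Logical 2D or 3D array.
#' @return Integer array of the same shape: 0 for background, components
#'   numbered 1..k in decreasing voxel-count order (component 1 is largest).
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  ndim <- length(dm)
  stopifnot(ndim %in% c(2L, 3L), is.logical(mask))
  lab <- array(0L, dim = dm)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  offs <- neighbor_offsets(ndim)
  # linear-index displacement of each stencil neighbor
  if (ndim == 2L) {
    doff <- offs[, 1] + offs[, 2] * dm[1]
    coord <- cbind((idx - 1L) %% dm[1] + 1L, (idx - 1L) %/% dm[1] + 1L)
  } else {
    doff <- offs[, 1] + offs[, 2] * dm[1] + offs[, 3] * dm[1] * dm[2]
    i0 <- idx - 1L
    coord <- cbind(i0 %% dm[1] + 1L,
                   (i0 %/% dm[1]) %% dm[2] + 1L,
                   i0 %/% (dm[1] * dm[2]) + 1L)
  }
  rownames(coord) <- NULL
  inmask <- array(FALSE, dim = dm)
  inmask[idx] <- TRUE
  visited <- array(FALSE, dim = dm)
  comp <- 0L
  sizes <- integer(0)
  for (seed in idx) {
    if (visited[seed]) next
    comp <- comp + 1L
    frontier <- seed
    visited[seed] <- TRUE
    n <- 0L
    while (length(frontier) > 0L) {
      lab[frontier] <- comp
      n <- n + length(frontier)
      # expand frontier by every stencil offset, discarding wrap-arounds
      cand <- rep(frontier, each = length(doff)) + rep(doff, length(frontier))
      src <- rep(frontier, each = length(doff))
      ok <- cand >= 1L & cand <= prod(dm)
      cand <- cand[ok]; src <- src[ok]
      # reject neighbors that wrapped across an array edge
      if (ndim == 2L) {
        keep <- abs(((cand - 1L) %% dm[1]) - ((src - 1L) %% dm[1])) <= 1L
      } else {
        keep <- abs(((cand - 1L) %% dm[1]) - ((src - 1L) %% dm[1])) <= 1L &
          abs((((cand - 1L) %/% dm[1]) %% dm[2]) -
                (((src - 1L) %/% dm[1]) %% dm[2])) <= 1L
      }
      cand <- unique(cand[keep])
      cand <- cand[inmask[cand] & !visited[cand]]
      visited[cand] <- TRUE
      frontier <- cand
    }
    sizes[comp] <- n
  }
  if (comp > 1L) {
    # renumber so that component 1 is the largest
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(comp)
    remap[ord] <- seq_len(comp)
    nz <- lab != 0L
    lab[nz] <- remap[lab[nz]]
  }
  lab
}

#' Largest connected component of a logical array
#'
#' @param mask Logical 2D or 3D array.
#' @return Logical array keeping only the largest component.
#' @export
largest_component <- function(mask) {
  label_components(mask) == 1L
}
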