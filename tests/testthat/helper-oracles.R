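# Independent brute-force oracles, written deliberately as plain loops over
# pixel pairs / runs / neighbors, separate from the package's vectorized
# implementations.

oracle_glcm <- function(lev) {
  n <- nrow(lev); m <- ncol(lev)
  vals <- sort(unique(as.vector(lev)))
  L <- length(vals)
  P <- matrix(0, L, L, dimnames = list(vals, vals))
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (off in offsets) {
    for (r in 1:n) for (c in 1:m) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > n || c2 < 1 || c2 > m) next
      a <- match(lev[r, c], vals); b <- match(lev[r2, c2], vals)
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  vals <- as.numeric(rownames(P))
  je <- 0; id <- 0; idm <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    d <- abs(vals[i] - vals[j])
    je <- je + P[i, j]^2
    id <- id + P[i, j] / (1 + d)
    idm <- idm + P[i, j] / (1 + d^2)
  }
  c(Id = id, Idm = idm, JointEnergy = je, MaximumProbability = max(P))
}

oracle_first_order <- function(window, lev, voxel_volume = 1) {
  eps <- 2.2e-16
  tab <- table(as.vector(lev))
  p <- as.numeric(tab) / length(lev)
  c(Entropy = -sum(p * log2(p + eps)),
    TotalEnergy = voxel_volume * sum(window^2),
    Uniformity = sum(p^2))
}

oracle_gldm_features <- function(lev, alpha = 0) {
  n <- nrow(lev); m <- ncol(lev)
  # build the full P(i, j) dependence matrix
  recs <- list()
  for (r in 1:n) for (c in 1:m) {
    dep <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > n || c2 < 1 || c2 > m) next
      if (abs(lev[r, c] - lev[r2, c2]) <= alpha) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(i = lev[r, c], j = dep)
  }
  recs <- do.call(rbind, recs)
  is <- sort(unique(recs[, "i"])); js <- sort(unique(recs[, "j"]))
  P <- matrix(0, length(is), length(js), dimnames = list(is, js))
  for (k in seq_len(nrow(recs)))
    P[as.character(recs[k, "i"]), as.character(recs[k, "j"])] <-
      P[as.character(recs[k, "i"]), as.character(recs[k, "j"])] + 1
  nz <- sum(P)
  jv <- as.numeric(colnames(P))
  mu <- sum(rep(jv, each = nrow(P)) * P) / nz
  c(DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    DependenceVariance = sum(sweep(P, 2, (jv - mu)^2, "*")) / nz,
    LargeDependenceEmphasis = sum(sweep(P, 2, jv^2, "*")) / nz)
}

# walk every maximal line of the matrix along one direction step
oracle_runs <- function(lev, step) {
  n <- nrow(lev); m <- ncol(lev)
  starts <- list()
  for (r in 1:n) for (c in 1:m) {
    rp <- r - step[1]; cp <- c - step[2]
    if (rp >= 1 && rp <= n && cp >= 1 && cp <= m) next  # not a line start
    starts[[length(starts) + 1]] <- c(r, c)
  }
  runs <- list()
  for (st in starts) {
    r <- st[1]; c <- st[2]
    line <- c()
    while (r >= 1 && r <= n && c >= 1 && c <= m) {
      line <- c(line, lev[r, c])
      r <- r + step[1]; c <- c + step[2]
    }
    k <- 1
    while (k <= length(line)) {
      len <- 1
      while (k + len <= length(line) && line[k + len] == line[k]) len <- len + 1
      runs[[length(runs) + 1]] <- c(level = line[k], length = len)
      k <- k + len
    }
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(lev) {
  steps <- list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  np <- length(lev)
  per <- sapply(steps, function(stp) {
    runs <- oracle_runs(lev, stp)
    nr <- nrow(runs)
    gl <- table(runs[, "level"]); rl <- table(runs[, "length"])
    c(GLNN = sum(as.numeric(gl)^2) / nr^2,
      RLNN = sum(as.numeric(rl)^2) / nr^2,
      RP = nr / np,
      SRE = sum(1 / runs[, "length"]^2) / nr)
  })
  rowMeans(per)
}

# all 14 features from a pre-discretized level matrix + raw window
oracle_all_features <- function(window, lev, voxel_volume = 1, alpha = 0) {
  c(oracle_first_order(window, lev, voxel_volume),
    oracle_glcm_features(oracle_glcm(lev)),
    oracle_gldm_features(lev, alpha),
    oracle_glrlm_features(lev))
}

# features of one window through the package path, from the same level matrix
package_all_features <- function(window, lev, voxel_volume = 1, alpha = 0) {
  dw <- structure(list(levels = lev, n_levels = max(lev),
                       bin_edges = seq_len(max(lev) + 1)),
                  class = "discretized_window")
  c(first_order_features(window, dw, voxel_volume),
    glcm_features(glcm_matrix(dw)),
    gldm_features(dw, alpha),
    glrlm_features(dw))
}

random_window <- function(side, n_levels) {
  lev <- matrix(sample(seq_len(n_levels), side * side, replace = TRUE), side, side)
  list(lev = lev, raw = lev * 10 + rnorm(side * side))
}

oracle_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force binary closing on small 3D masks
oracle_closing <- function(mask, radius) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dr = -radius:radius, dc = -radius:radius,
                                ds = -radius:radius))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  pad <- radius
  big <- array(FALSE, d + 2 * pad)
  big[pad + 1:d[1], pad + 1:d[2], pad + 1:d[3]] <- mask
  dil <- array(FALSE, dim(big))
  idx <- which(big, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    tgt <- sweep(offs, 2, idx[k, ], "+")
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= dim(big)[1] &
      tgt[, 2] >= 1 & tgt[, 2] <= dim(big)[2] &
      tgt[, 3] >= 1 & tgt[, 3] <= dim(big)[3]
    dil[tgt[ok, , drop = FALSE]] <- TRUE
  }
  ero <- array(FALSE, dim(big))
  cand <- which(dil, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    tgt <- sweep(offs, 2, cand[k, ], "+")
    inside <- tgt[, 1] >= 1 & tgt[, 1] <= dim(big)[1] &
      tgt[, 2] >= 1 & tgt[, 2] <= dim(big)[2] &
      tgt[, 3] >= 1 & tgt[, 3] <= dim(big)[3]
    if (all(inside) && all(dil[tgt])) ero[cand[k, 1], cand[k, 2], cand[k, 3]] <- TRUE
  }
  ero[pad + 1:d[1], pad + 1:d[2], pad + 1:d[3]]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
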