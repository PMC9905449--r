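# Six-class fully connected classifier with class-frequency-weighted
# cross-entropy. The network is dense(128) -> ReLU -> dense(128) -> dense(6)
# with per-class sigmoid outputs and one-hot targets; features are z-scored
# with training statistics. Trained by mini-batch Adam.

#' Per-class loss weights from sample counts
#'
#' Class imbalance is corrected by weighting each class's loss by the
#' inverse of its frequency, normalized so the weights sum to one:
#' `w_i` proportional to `1 / rho_i` with `rho_i = n_i / n`. The rarest
#' class therefore receives the largest weight. `inverse = FALSE` instead
#' uses the frequencies themselves (`w_i = rho_i`), which reproduces the
#' unweighted balance and is kept only for comparison.
#'
#' @param counts Named integer vector of per-class sample counts (names are
#'   tissue class names or codes); all counts must be positive.
#' @param inverse Use inverse frequencies (default TRUE).
#' @return List of class `class_weights`: `w`, `rho`, `n_samp`, `n_total`.
#' @export
compute_class_weights <- function(counts, inverse = TRUE) {
  nm <- names(counts)
  counts <- round(as.numeric(counts))
  names(counts) <- nm
  if (any(counts <= 0)) {
    bad <- if (!is.null(names(counts))) names(counts)[counts <= 0] else which(counts <= 0)
    stop("zero sample count for class(es): ", paste(bad, collapse = ", "))
  }
  n <- sum(counts)
  rho <- counts / n
  w <- if (inverse) (1 / rho) / sum(1 / rho) else rho
  structure(list(w = w, rho = rho, n_samp = as.integer(counts),
                 n_total = as.integer(n)),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat("<class_weights>\n")
  print(data.frame(n = x$n_samp, rho = round(x$rho, 4), w = round(x$w, 4)))
  invisible(x)
}

#' Class-weighted cross-entropy loss
#'
#' `Loss = sum_i w_i Loss_i`, where `Loss_i` is the mean natural-log
#' cross-entropy `-ln s` of the true-class sigmoid score over the samples of
#' class `i`; classes absent from the batch contribute zero. Scores exactly
#' 0 or 1 are clamped by `eps`.
#'
#' @param scores n x K matrix of per-class scores in `[0, 1]`.
#' @param targets Length-n vector of true class column indices (1..K).
#' @param weights A [compute_class_weights()] object whose `w` is named or
#'   ordered by the score columns, or a bare numeric weight vector.
#' @param eps Clamp for degenerate scores, default 1e-12.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(scores, targets, weights, eps = 1e-12) {
  scores <- as.matrix(scores)
  targets <- as.integer(targets)
  stopifnot(length(targets) == nrow(scores),
            all(targets >= 1), all(targets <= ncol(scores)))
  w <- if (inherits(weights, "class_weights")) weights$w else as.numeric(weights)
  stopifnot(length(w) == ncol(scores))
  s <- scores[cbind(seq_along(targets), targets)]
  s <- pmin(pmax(s, eps), 1 - eps)
  loss <- 0
  for (k in unique(targets)) {
    loss <- loss + w[k] * mean(-log(s[targets == k]))
  }
  loss
}

#' Class-weighted full cross-entropy for sigmoid outputs
#'
#' The training objective: per sample, the one-hot cross-entropy over all
#' output units, `-sum_k [y_k ln s_k + (1 - y_k) ln(1 - s_k)]`, averaged per
#' true class and combined as `sum_i w_i Loss_i`. Unlike
#' [weighted_cross_entropy()] (which scores only the true-class output and
#' is reported for comparability), this objective also pushes wrong-class
#' scores toward zero, which the argmax decision rule needs.
#'
#' @inheritParams weighted_cross_entropy
#' @return Scalar loss.
#' @export
weighted_full_cross_entropy <- function(scores, targets, weights, eps = 1e-12) {
  scores <- as.matrix(scores)
  targets <- as.integer(targets)
  stopifnot(length(targets) == nrow(scores))
  w <- if (inherits(weights, "class_weights")) weights$w else as.numeric(weights)
  s <- pmin(pmax(scores, eps), 1 - eps)
  Y <- matrix(0, nrow(s), ncol(s))
  Y[cbind(seq_along(targets), targets)] <- 1
  per_sample <- -rowSums(Y * log(s) + (1 - Y) * log(1 - s))
  loss <- 0
  for (k in unique(targets)) loss <- loss + w[k] * mean(per_sample[targets == k])
  loss
}

#' Model configuration for one of the four experiment arms
#'
#' @param window_side 3 or 5.
#' @param normalization `"MAX"` or `"PERCENTILE99"`.
#' @param seed Integer training seed.
#' @param hidden Hidden layer widths, default `c(128, 128)`.
#' @param learning_rate,batch_size,max_epochs Adam hyperparameters.
#' @param patience Early-stopping patience (epochs without a material
#'   held-out improvement), default 20.
#' @param min_delta Smallest held-out loss decrease that counts as an
#'   improvement for the patience clock, default 1e-3 (the best weights are
#'   still tracked at full precision).
#' @param val_fraction Held-out fraction for early stopping, default 0.1.
#' @param inverse_weights Use inverse-frequency class weights, default TRUE.
#' @return List of class `model_config`; `label` is `ModelMx3`,
#'   `ModelPrct3`, `ModelMx5` or `ModelPrct5`.
#' @export
model_config <- function(window_side = 3L, normalization = c("PERCENTILE99", "MAX"),
                         seed = 1L, hidden = c(128L, 128L),
                         learning_rate = 1e-3, batch_size = 256L,
                         max_epochs = 200L, patience = 20L, min_delta = 1e-3,
                         val_fraction = 0.1, inverse_weights = TRUE) {
  normalization <- match.arg(normalization)
  window_side <- as.integer(window_side)
  stopifnot(window_side %in% c(3L, 5L))
  label <- paste0("Model", if (normalization == "MAX") "Mx" else "Prct", window_side)
  structure(list(window_side = window_side, normalization = normalization,
                 label = label, seed = as.integer(seed), hidden = as.integer(hidden),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 min_delta = min_delta,
                 val_fraction = val_fraction, inverse_weights = inverse_weights),
            class = "model_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  layers <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    sd <- sqrt(2 / sizes[l])
    layers[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                 sizes[l], sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  }
  layers
}

# Forward pass; ReLU after the first hidden layer only, sigmoid at output.
mlp_forward <- function(layers, X) {
  Z1 <- sweep(X %*% layers[[1]]$W, 2, layers[[1]]$b, "+")
  H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% layers[[2]]$W, 2, layers[[2]]$b, "+")
  Z3 <- sweep(Z2 %*% layers[[3]]$W, 2, layers[[3]]$b, "+")
  list(Z1 = Z1, H1 = H1, Z2 = Z2, scores = sigmoid(Z3))
}

# Gradient of the class-weighted full cross-entropy w.r.t. all parameters
# for a batch; for sigmoid + one-hot cross-entropy, dLoss/dz = s - y scaled
# by w_class / n_class.
mlp_backward <- function(layers, X, fw, targets, w_batch) {
  n <- nrow(X)
  Y <- matrix(0, n, ncol(fw$scores))
  Y[cbind(seq_len(n), targets)] <- 1
  dZ3 <- (fw$scores - Y) * w_batch
  dW3 <- t(fw$Z2) %*% dZ3
  db3 <- colSums(dZ3)
  dZ2 <- dZ3 %*% t(layers[[3]]$W)
  dW2 <- t(fw$H1) %*% dZ2
  db2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(layers[[2]]$W)
  dZ1 <- dH1 * (fw$Z1 > 0)
  dW1 <- t(X) %*% dZ1
  db1 <- colSums(dZ1)
  list(list(W = dW1, b = db1), list(W = dW2, b = db2), list(W = dW3, b = db3))
}

#' Train the six-class window-sample classifier
#'
#' Features are z-scored with training statistics (frozen into the model),
#' the class weights are the inverse class frequencies normalized to sum
#' one, and the network is trained by mini-batch Adam on the weighted
#' cross-entropy with early stopping on a held-out split. Deterministic
#' under the configuration seed.
#'
#' @param train_table Sample table with feature columns (see
#'   [extract_features_for_samples()]); must contain at least two classes.
#' @param config A [model_config()].
#' @return Object of class `mlp_classifier`, with a per-epoch loss history
#'   in `$history`.
#' @export
train_classifier <- function(train_table, config = model_config()) {
  feat_cols <- setdiff(names(train_table), sample_table_base_cols)
  X <- as.matrix(train_table[feat_cols])
  if (!all(is.finite(X)))
    stop("non-finite features in rows: ",
         paste(utils::head(which(!stats::complete.cases(X) |
                                   apply(!is.finite(X), 1, any)), 10), collapse = ", "))
  y <- as.integer(train_table$label)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training table contains a single class")
  counts <- table(factor(y, levels = classes))
  cw <- compute_class_weights(stats::setNames(as.integer(counts), names(counts)),
                              inverse = config$inverse_weights)
  w6 <- rep(0, 6)
  w6[classes] <- cw$w
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  restore <- local_rng(config$seed)
  on.exit(restore())
  n <- nrow(Xs)
  n_val <- max(1L, floor(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2) stop("training split degenerate after validation hold-out")
  layers <- mlp_init(ncol(Xs), config$hidden, 6L)
  adam <- lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  best <- list(val = Inf, layers = layers)
  clock <- list(val = Inf, epoch = 0L)  # patience clock with min_delta margin
  min_delta <- if (is.null(config$min_delta)) 1e-3 else config$min_delta
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  # history losses are tracked on a capped subset of the training split so
  # monitoring stays cheap on large tables
  tr_mon <- tr_idx[seq_len(min(512L, length(tr_idx)))]
  batch_w <- function(targets) {
    # per-sample scale w_class / n_class(batch)
    tab <- tabulate(targets, nbins = 6)
    (w6 / pmax(tab, 1))[targets]
  }
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(tr_idx)
    starts <- seq(1, length(perm), by = config$batch_size)
    for (st in starts) {
      bi <- perm[st:min(st + config$batch_size - 1L, length(perm))]
      Xb <- Xs[bi, , drop = FALSE]
      yb <- y[bi]
      fw <- mlp_forward(layers, Xb)
      gr <- mlp_backward(layers, Xb, fw, yb, batch_w(yb))
      t_step <- t_step + 1
      for (l in seq_along(layers)) {
        adam[[l]]$mW <- b1 * adam[[l]]$mW + (1 - b1) * gr[[l]]$W
        adam[[l]]$vW <- b2 * adam[[l]]$vW + (1 - b2) * gr[[l]]$W^2
        adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * gr[[l]]$b
        adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * gr[[l]]$b^2
        mhW <- adam[[l]]$mW / (1 - b1^t_step)
        vhW <- adam[[l]]$vW / (1 - b2^t_step)
        mhb <- adam[[l]]$mb / (1 - b1^t_step)
        vhb <- adam[[l]]$vb / (1 - b2^t_step)
        layers[[l]]$W <- layers[[l]]$W - config$learning_rate * mhW / (sqrt(vhW) + eps)
        layers[[l]]$b <- layers[[l]]$b - config$learning_rate * mhb / (sqrt(vhb) + eps)
      }
    }
    tr_loss <- weighted_full_cross_entropy(
      mlp_forward(layers, Xs[tr_mon, , drop = FALSE])$scores, y[tr_mon], w6)
    val_loss <- weighted_full_cross_entropy(
      mlp_forward(layers, Xs[val_idx, , drop = FALSE])$scores, y[val_idx], w6)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = val_loss))
    if (val_loss < best$val) best <- list(val = val_loss, layers = layers)
    if (val_loss < clock$val - min_delta) {
      clock <- list(val = val_loss, epoch = epoch)
    } else if (epoch - clock$epoch >= config$patience) {
      break
    }
  }
  structure(list(layers = best$layers, center = center, scale = scale,
                 feature_names = feat_cols, classes = classes,
                 class_weights = cw, config = config, history = history),
            class = "mlp_classifier")
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat(sprintf("<mlp_classifier> %s: %d -> %s -> 6 (sigmoid), %d epochs, val loss %.4f\n",
              x$config$label, length(x$feature_names),
              paste(x$config$hidden, collapse = " -> "),
              max(x$history$epoch), min(x$history$val_loss)))
  invisible(x)
}

#' Predict tissue classes for a feature batch
#'
#' @param object A trained [train_classifier()] model.
#' @param newdata Sample table with the model's feature columns, or a bare
#'   feature matrix.
#' @param ... Unused.
#' @return Data frame, one row per input row: `score_1` .. `score_6`
#'   (per-class sigmoid scores in `[0, 1]`) and `pred_label` (argmax; ties
#'   broken toward the lowest class code).
#' @export
predict.mlp_classifier <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$feature_names])
  if (ncol(X) != length(object$feature_names))
    stop(sprintf("feature length mismatch: model expects %d, got %d",
                 length(object$feature_names), ncol(X)))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  scores <- mlp_forward(object$layers, Xs)$scores
  # argmax over the classes the model was trained on; output units of
  # classes never seen in training carry no information
  cls <- object$classes
  pred <- cls[apply(scores[, cls, drop = FALSE], 1, which.max)]
  out <- as.data.frame(scores)
  names(out) <- paste0("score_", 1:6)
  out$pred_label <- as.integer(pred)
  rownames(out) <- NULL
  out
}
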