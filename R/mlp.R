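# Multi-layer perceptron for postural sway classification.
#
# A small fully-connected net: rectifier activations on the input/hidden
# layers, softmax output over the four classes, trained with Adam on the
# categorical cross-entropy. The net is small enough (a few hundred weights)
# that plain vectorised R is entirely adequate; everything is deterministic
# under the training seed.

.relu <- function(z) pmax(z, 0)

.softmax <- function(z) {
  # row-wise, numerically stable
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; returns list of pre-activations and activations per layer.
.mlp_forward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) .relu(Z[[l]]) else .softmax(Z[[l]])
  }
  list(Z = Z, A = A)
}

.cross_entropy <- function(P, Y) {
  -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

#' Train the MLP classifier
#'
#' Fits a fully-connected network on the training split of a pattern dataset.
#' The default topology has a first trainable rectifier layer of the input
#' width followed by hidden layers of 8, 10 and 8 neurons and a 4-unit
#' softmax output, i.e. `n_features -> n_features -> 8 -> 10 -> 8 -> 4`;
#' `input_relu_layer = FALSE` drops the first layer. Features are z-scored
#' with training-split statistics by default (they span orders of magnitude,
#' metres vs square metres). Training uses mini-batch Adam on the categorical
#' cross-entropy with early stopping on a validation carve-out of the
#' training split, restoring the best weights.
#'
#' @param dataset a `pattern_dataset` (rows with `split == "train"` are
#'   used), or any data.frame with the feature columns and a `label` column
#'   (then all rows are used).
#' @param subset feature subset: `"all4"`, `"cea3"` or `"rms3"`.
#' @param hidden integer vector of hidden-layer widths (default `c(8, 10, 8)`).
#' @param input_relu_layer keep the extra first rectifier layer of input
#'   width (default `TRUE`).
#' @param epochs maximum training epochs (default 200).
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param validation_fraction fraction of the training patterns carved out
#'   for early stopping (default 0.15; 0 disables early stopping).
#' @param patience epochs without validation improvement before stopping
#'   (default 20).
#' @param standardize z-score features with training statistics (default
#'   `TRUE`).
#' @param seed integer; controls initialisation, the validation carve-out and
#'   batch shuffling. Identical seeds give identical weights.
#' @return Object of class `mlp_model`: weights, biases, feature names,
#'   class levels, standardisation constants and a training history.
#' @export
train_mlp <- function(dataset, subset = "all4", hidden = c(8, 10, 8),
                      input_relu_layer = TRUE, epochs = 200, batch_size = 32,
                      learning_rate = 1e-3, validation_fraction = 0.15,
                      patience = 20, standardize = TRUE, seed = 1) {
  feats <- .subset_features(subset)
  d <- if (!is.null(dataset$split)) dataset[dataset$split == "train", ] else
    dataset
  stop_if_not(nrow(d) > 0, "no training patterns")
  X <- as.matrix(d[, feats, drop = FALSE])
  stop_if_not(all(is.finite(X)), "non-finite feature values in training data")
  labs <- factor(d$label, levels = sway_classes())
  stop_if_not(nlevels(droplevels(labs)) >= 2,
              "training data must contain at least 2 classes")
  classes <- sway_classes()
  Y <- diag(length(classes))[as.integer(labs), , drop = FALSE]

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
  } else {
    center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  }
  names(center) <- names(scale_) <- feats
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)

  p <- ncol(Xs)
  widths <- c(p, if (input_relu_layer) p, hidden, length(classes))
  L <- length(widths) - 1L

  history <- NULL
  fit <- with_local_seed(seed, {
    # He-normal initialisation, biases at zero
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(widths[l] * widths[l + 1L],
                          sd = sqrt(2 / widths[l])),
             widths[l], widths[l + 1L]))
    b <- lapply(seq_len(L), function(l) rep(0, widths[l + 1L]))

    n <- nrow(Xs)
    if (validation_fraction > 0 && n >= 10) {
      n_val <- max(1L, round(validation_fraction * n))
      val_idx <- sample(n, n_val)
    } else val_idx <- integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_val <- Inf; best <- list(W = W, b = b); wait <- 0L
    hist_loss <- numeric(0); hist_val <- numeric(0)

    for (epoch in seq_len(epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (bi in batches) {
        fw <- .mlp_forward(W, b, Xs[bi, , drop = FALSE])
        P <- fw$A[[L + 1L]]
        dZ <- (P - Y[bi, , drop = FALSE]) / length(bi)
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$A[[l]], dZ)
          gb <- colSums(dZ)
          if (l > 1L) {
            dA <- tcrossprod(dZ, W[[l]])
            dZ <- dA * (fw$Z[[l - 1L]] > 0)
          }
          step_l <- step + 1L  # shared Adam step counter per update
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mW_hat <- mW[[l]] / (1 - beta1^step_l)
          vW_hat <- vW[[l]] / (1 - beta2^step_l)
          mb_hat <- mb[[l]] / (1 - beta1^step_l)
          vb_hat <- vb[[l]] / (1 - beta2^step_l)
          W[[l]] <- W[[l]] - learning_rate * mW_hat / (sqrt(vW_hat) + eps)
          b[[l]] <- b[[l]] - learning_rate * mb_hat / (sqrt(vb_hat) + eps)
        }
        step <- step + 1L
      }
      tr_loss <- .cross_entropy(
        .mlp_forward(W, b, Xs[tr_idx, , drop = FALSE])$A[[L + 1L]],
        Y[tr_idx, , drop = FALSE])
      hist_loss <- c(hist_loss, tr_loss)
      if (length(val_idx)) {
        val_loss <- .cross_entropy(
          .mlp_forward(W, b, Xs[val_idx, , drop = FALSE])$A[[L + 1L]],
          Y[val_idx, , drop = FALSE])
        hist_val <- c(hist_val, val_loss)
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss; best <- list(W = W, b = b); wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else best <- list(W = W, b = b)
    }
    list(W = lapply(best$W, unname), b = lapply(best$b, unname),
         history = list(train_loss = hist_loss, val_loss = hist_val,
                        epochs_run = length(hist_loss)))
  })

  structure(list(type = "mlp", weights = fit$W, biases = fit$b,
                 features = feats, subset = subset, classes = classes,
                 center = center, scale = scale_,
                 standardize = standardize,
                 topology = widths, seed = seed,
                 history = fit$history,
                 final_loss = utils::tail(fit$history$train_loss, 1)),
            class = "mlp_model")
}

# Shared: feature matrix from a dataset / data.frame / numeric vector.
.feature_matrix <- function(model, newdata) {
  feats <- model$features
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    stop_if_not(length(newdata) == length(feats),
                "feature dimensionality does not match the model")
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, feats))
  }
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  stop_if_not(all(feats %in% names(newdata)),
              paste("newdata lacks feature columns:",
                    paste(setdiff(feats, names(newdata)), collapse = ", ")))
  as.matrix(newdata[, feats, drop = FALSE])
}

#' Reliability index of a probability vector
#'
#' `RI = (P1 - P2) / P1` where `P1 >= P2` are the two largest predicted
#' class probabilities: the normalised margin between the winner and the
#' runner-up, usable as a confidence measure when the true class is unknown.
#' 1 for a certain prediction, 0 when the top two probabilities tie.
#'
#' @param probs numeric matrix (rows = patterns, columns = classes) or a
#'   single probability vector.
#' @return Numeric vector of RI values in `[0, 1]`.
#' @export
reliability_index <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  unname(apply(probs, 1L, function(p) {
    s <- sort(p, decreasing = TRUE)
    if (s[1] <= 0) return(0)
    (s[1] - s[2]) / s[1]
  }))
}

# Common prediction-result assembly used by both classifiers.
.prediction_result <- function(P, classes, predicted = NULL) {
  colnames(P) <- paste0("p_", classes)
  pred <- predicted %||% classes[max.col(P, ties.method = "first")]
  out <- data.frame(P, predicted = pred, ri = reliability_index(P),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict classes, probabilities and reliability with the MLP
#'
#' @param object an `mlp_model`.
#' @param newdata a `pattern_dataset`, data.frame or matrix with the model's
#'   feature columns, or a single numeric feature vector.
#' @param ... unused.
#' @return Data.frame with one row per pattern: class probabilities
#'   (`p_ST`, `p_AP`, `p_ML`, `p_UNST`), `predicted` (argmax class) and `ri`.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- .feature_matrix(object, newdata)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  P <- .mlp_forward(object$weights, object$biases, Xs)$A[[
    length(object$weights) + 1L]]
  .prediction_result(P, object$classes)
}
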