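# Threshold-rule baseline classifier with ROC-derived cutoffs.
#
# Each feature is compared against an optimal cutoff estimated on the
# training data by receiver-operating-characteristic analysis (maximum
# Youden J). A small if-then rule table maps the comparison outcomes to the
# four classes; a sigmoid-margin construction yields pseudo-probabilities so
# the same reliability index can be computed as for the MLP.

#' Optimal binary threshold by Youden's J
#'
#' Sweeps every candidate cutpoint (midpoints between consecutive sorted
#' unique scores, plus outer sentinels) of a one-dimensional score against a
#' binary outcome and returns the threshold maximising
#' `J = sensitivity + specificity - 1`, where a positive is declared when
#' `score > threshold`. Ties in J are broken toward the lower threshold.
#'
#' @param scores numeric scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return List with `threshold`, `J`, `sensitivity`, `specificity`, or
#'   `NULL` if the score is degenerate (constant).
#' @export
youden_threshold <- function(scores, positive) {
  stop_if_not(length(scores) == length(positive) && length(scores) > 0,
              "scores and positive must be equal-length and non-empty")
  stop_if_not(any(positive) && any(!positive),
              "both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) return(NULL)
  cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  best <- NULL
  for (th in cand) {  # candidates ascend, so '>' keeps the lowest tie
    sens <- sum(positive & scores > th) / n_pos
    spec <- sum(!positive & scores <= th) / n_neg
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12) {
      best <- list(threshold = th, J = J, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

#' Fit the threshold-rule baseline
#'
#' Learns three cutoffs on the training split:
#' * `T1` on DAPmax for the AP-excursion contrast (`AP` or `UNST` vs rest),
#' * `T2` on DMLmax for the ML-excursion contrast (`ML` or `UNST` vs rest),
#' * `T3` on the dispersion feature (CEA when available, else RMS) for the
#'   `UNST`-vs-`ST` contrast.
#'
#' The rule table is total: `DAPmax > T1 & DMLmax > T2 -> UNST`;
#' `DAPmax > T1` alone `-> AP`; `DMLmax > T2` alone `-> ML`; otherwise the
#' dispersion feature decides `UNST` vs `ST`. A degenerate (constant)
#' feature disables its rule with a warning. Training-split interquartile
#' ranges are stored as margin scales for the pseudo-probability map.
#'
#' @param dataset a `pattern_dataset` (training split used) or a labelled
#'   data.frame.
#' @param subset feature subset: `"all4"`, `"cea3"` or `"rms3"`.
#' @return Object of class `threshold_model`.
#' @export
fit_thresholds <- function(dataset, subset = "all4") {
  feats <- .subset_features(subset)
  d <- if (!is.null(dataset$split)) dataset[dataset$split == "train", ] else
    dataset
  stop_if_not(nrow(d) > 0, "no training patterns")
  stop_if_not(!is.null(d$label), "training patterns must be labelled")
  disp_feat <- if ("cea_m2" %in% feats) "cea_m2" else "rms_m"

  fit_one <- function(feature, positive) {
    th <- youden_threshold(d[[feature]], positive)
    if (is.null(th))
      warning("feature ", feature,
              " is constant on the training data; its rule is disabled",
              call. = FALSE)
    th
  }
  thresholds <- list(
    dapmax = fit_one("dapmax_m", d$label %in% c("AP", "UNST")),
    dmlmax = fit_one("dmlmax_m", d$label %in% c("ML", "UNST")),
    disp = if (any(d$label %in% c("ST", "UNST")))
      fit_one_sub(d, disp_feat) else NULL
  )
  scales <- vapply(feats, function(f) {
    iqr <- stats::IQR(d[[f]])
    if (iqr <= 0) max(stats::sd(d[[f]]), 1e-12) else iqr
  }, numeric(1))

  structure(list(type = "threshold", features = feats, subset = subset,
                 classes = sway_classes(), disp_feature = disp_feat,
                 thresholds = thresholds, scales = scales),
            class = "threshold_model")
}

# ST-vs-UNST contrast restricted to those two classes.
fit_one_sub <- function(d, feature) {
  sub <- d[d$label %in% c("ST", "UNST"), , drop = FALSE]
  if (!any(sub$label == "ST") || !any(sub$label == "UNST")) return(NULL)
  th <- youden_threshold(sub[[feature]], sub$label == "UNST")
  if (is.null(th))
    warning("feature ", feature,
            " is constant on the training data; its rule is disabled",
            call. = FALSE)
  th
}

# Signed, scale-normalised margins for the three rules; NA if disabled.
.threshold_margins <- function(model, X) {
  th <- model$thresholds
  m1 <- if (!is.null(th$dapmax))
    (X[, "dapmax_m"] - th$dapmax$threshold) / model$scales[["dapmax_m"]]
  m2 <- if (!is.null(th$dmlmax))
    (X[, "dmlmax_m"] - th$dmlmax$threshold) / model$scales[["dmlmax_m"]]
  m3 <- if (!is.null(th$disp))
    (X[, model$disp_feature] - th$disp$threshold) /
      model$scales[[model$disp_feature]]
  list(m1 = m1, m2 = m2, m3 = m3)
}

#' Pseudo-probabilities of the threshold baseline
#'
#' The rule table itself yields hard classes only; to obtain a reliability
#' index comparable with the MLP's, each class is scored by the mean of
#' logistic sigmoids of the signed, scale-normalised margins of its rules
#' (scale = training-set interquartile range of the feature), and the scores
#' are normalised to sum to one:
#' * `AP`:  wants DAPmax above `T1` and DMLmax below `T2`;
#' * `ML`:  the mirror image;
#' * `UNST`: all three margins positive;
#' * `ST`:  all three margins negative.
#' Features exactly at every threshold give uniform probabilities (RI = 0).
#'
#' @param model a `threshold_model`.
#' @param newdata features (same forms as [predict.mlp_model()]).
#' @return Matrix of class pseudo-probabilities, rows summing to 1.
#' @export
threshold_pseudo_probabilities <- function(model, newdata) {
  X <- .feature_matrix(model, newdata)
  mg <- .threshold_margins(model, X)
  sig <- function(m) 1 / (1 + exp(-m))
  n <- nrow(X)
  row_mean <- function(...) {
    cols <- Filter(Negate(is.null), list(...))
    if (!length(cols)) return(rep(0.5, n))  # all rules disabled
    Reduce(`+`, cols) / length(cols)
  }
  s_ap <- row_mean(if (!is.null(mg$m1)) sig(mg$m1),
                   if (!is.null(mg$m2)) sig(-mg$m2))
  s_ml <- row_mean(if (!is.null(mg$m1)) sig(-mg$m1),
                   if (!is.null(mg$m2)) sig(mg$m2))
  s_un <- row_mean(if (!is.null(mg$m1)) sig(mg$m1),
                   if (!is.null(mg$m2)) sig(mg$m2),
                   if (!is.null(mg$m3)) sig(mg$m3))
  s_st <- row_mean(if (!is.null(mg$m1)) sig(-mg$m1),
                   if (!is.null(mg$m2)) sig(-mg$m2),
                   if (!is.null(mg$m3)) sig(-mg$m3))
  S <- cbind(s_st, s_ap, s_ml, s_un)
  colnames(S) <- model$classes
  S / rowSums(S)
}

#' Predict with the threshold-rule baseline
#'
#' The predicted class comes from the if-then rule table (the defining
#' behaviour of the baseline); the pseudo-probabilities provide the
#' reliability index.
#'
#' @param object a `threshold_model`.
#' @param newdata features (same forms as [predict.mlp_model()]).
#' @param ... unused.
#' @return Data.frame with the same schema as [predict.mlp_model()].
#' @export
predict.threshold_model <- function(object, newdata, ...) {
  X <- .feature_matrix(object, newdata)
  mg <- .threshold_margins(object, X)
  n <- nrow(X)
  over1 <- if (!is.null(mg$m1)) mg$m1 > 0 else rep(FALSE, n)
  over2 <- if (!is.null(mg$m2)) mg$m2 > 0 else rep(FALSE, n)
  over3 <- if (!is.null(mg$m3)) mg$m3 > 0 else rep(FALSE, n)
  pred <- ifelse(over1 & over2, "UNST",
          ifelse(over1, "AP",
          ifelse(over2, "ML",
          ifelse(over3, "UNST", "ST"))))
  P <- threshold_pseudo_probabilities(object, newdata)
  .prediction_result(P, object$classes, predicted = pred)
}

# Doubles are stored as %.17g strings: 17 significant digits round-trip an
# IEEE-754 double exactly, which plain JSON number formatting does not
# guarantee.
.num_ser <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = sprintf("%.17g", x))
  else sprintf("%.17g", x)
}

.num_deser <- function(x, names = NULL) {
  out <- if (is.list(x) && !is.null(x$dim))
    matrix(as.numeric(x$data), x$dim[1], x$dim[2])
  else as.numeric(unlist(x))
  if (!is.null(names)) names(out) <- names
  out
}

#' Write a trained model to a self-describing JSON file
#'
#' Stores the model type, topology/thresholds, weights and standardisation
#' constants at full precision (17 significant digits, which round-trips an
#' IEEE-754 double exactly); [read_model()] restores a bit-exact copy.
#'
#' @param model an `mlp_model` or `threshold_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- unclass(model)
  payload$.class <- class(model)
  if ("mlp_model" %in% class(model)) {
    payload$weights <- lapply(payload$weights, .num_ser)
    payload$biases <- lapply(payload$biases, .num_ser)
    payload$center <- .num_ser(unname(payload$center))
    payload$scale <- .num_ser(unname(payload$scale))
    payload$history <- NULL  # training curves are not part of the model
    payload$final_loss <- NULL
  } else {
    payload$scales <- .num_ser(unname(payload$scales))
    payload$thresholds <- lapply(payload$thresholds, function(th)
      if (is.null(th)) NULL else lapply(th, .num_ser))
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path file path.
#' @return The restored model object.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  cls <- payload$.class
  payload$.class <- NULL
  if ("mlp_model" %in% cls) {
    payload$weights <- lapply(payload$weights, .num_deser)
    payload$biases <- lapply(payload$biases, .num_deser)
    payload$center <- .num_deser(payload$center, payload$features)
    payload$scale <- .num_deser(payload$scale, payload$features)
    payload$topology <- as.integer(payload$topology)
  } else {
    payload$scales <- .num_deser(payload$scales, payload$features)
    payload$thresholds <- lapply(payload$thresholds, function(th)
      if (is.null(th) || (is.list(th) && !length(th))) NULL
      else lapply(th, function(v) as.numeric(unlist(v))))
  }
  structure(payload, class = cls)
}
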