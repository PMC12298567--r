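# Sway features computed per analysis window, and assembly of labelled
# pattern datasets with a stratified train/test split.

#' Confidence scaling factor for the confidence-ellipse area
#'
#' The factor that converts per-axis standard deviations into the semi-axes
#' of the ellipse enclosing a given fraction of a bivariate-normal point
#' cloud: `CSF = sqrt(qchisq(confidence, df = 2))`. At the 95% level this
#' evaluates to 2.4477 (to 4 decimals). Computing it from the chi-square
#' quantile rather than hard-coding guards against transcription errors and
#' generalises to other confidence levels.
#'
#' @param confidence coverage fraction in (0, 1); default 0.95.
#' @return The scaling factor (scalar).
#' @export
csf <- function(confidence = 0.95) {
  stop_if_not(confidence > 0 && confidence < 1,
              "confidence must be in (0, 1)")
  sqrt(stats::qchisq(confidence, df = 2))
}

#' Maximum displacement ranges (DAPmax, DMLmax)
#'
#' Peak-to-peak range `max - min` of each displacement series over the
#' window. `method = "absmax"` gives the alternative reading (largest
#' absolute displacement).
#'
#' @param window a `stabilogram_trace` window.
#' @param method `"range"` (default, peak-to-peak) or `"absmax"`.
#' @return Named numeric vector `c(dapmax_m =, dmlmax_m =)`, both in metres.
#' @export
feature_dapmax_dmlmax <- function(window, method = c("range", "absmax")) {
  method <- match.arg(method)
  stop_if_not(nrow(window) >= 1, "window must be non-empty")
  f <- switch(method,
              range = function(x) max(x) - min(x),
              absmax = function(x) max(abs(x)))
  c(dapmax_m = f(window$dap_m), dmlmax_m = f(window$dml_m))
}

#' Confidence-ellipse area (CEA)
#'
#' Area of the ellipse enclosing `confidence` of the stabilogram plot,
#' `CEA = pi * (CSF * sigma_AP) * (CSF * sigma_ML)` in m^2, where the sigmas
#' are the sample standard deviations (n - 1 denominator) of the AP and ML
#' displacement over the window.
#'
#' @param window a `stabilogram_trace` window with at least 2 samples.
#' @param confidence coverage fraction (default 0.95, CSF = 2.4477).
#' @return CEA in square metres.
#' @export
feature_cea <- function(window, confidence = 0.95) {
  stop_if_not(nrow(window) >= 2, "window needs >= 2 samples (sd undefined)")
  k <- csf(confidence)
  pi * (k * stats::sd(window$dap_m)) * (k * stats::sd(window$dml_m))
}

#' Root-mean-square path displacement (RMS)
#'
#' `RMS = sqrt(sum(dp_i^2) / N)` where `dp_i` is the Euclidean distance in
#' the (AP, ML) plane between consecutive stabilogram points and `N` is the
#' number of such distances (window samples minus 1).
#'
#' @param window a `stabilogram_trace` window with at least 2 samples.
#' @return RMS in metres.
#' @export
feature_rms <- function(window) {
  stop_if_not(nrow(window) >= 2, "window needs >= 2 samples")
  dap <- diff(window$dap_m)
  dml <- diff(window$dml_m)
  sqrt(sum(dap^2 + dml^2) / length(dap))
}

#' All four sway features for one window
#'
#' @param window a `stabilogram_trace` window.
#' @param confidence CEA coverage fraction.
#' @param range_method passed to [feature_dapmax_dmlmax()].
#' @return Named numeric vector `dapmax_m`, `dmlmax_m`, `cea_m2`, `rms_m`.
#' @export
sway_features <- function(window, confidence = 0.95,
                          range_method = "range") {
  c(feature_dapmax_dmlmax(window, method = range_method),
    cea_m2 = feature_cea(window, confidence),
    rms_m = feature_rms(window))
}

#' Build a labelled pattern dataset from acceleration records
#'
#' Runs each record through displacement reconstruction, segments the trace
#' into sliding windows, computes the four sway features per window, and
#' assigns every pattern to the training or test split by stratified random
#' sampling within class (so the class balance survives the split). Records
#' failing the displacement-validity check are excluded with a message.
#'
#' All four features are always computed and stored; reduced feature subsets
#' are selected downstream at training/evaluation time.
#'
#' @param records list of `accel_record` objects (each carrying its own
#'   geometry, as produced by [simulate_record()]), or a single record.
#' @param window a [window_spec()].
#' @param split_fraction fraction assigned to training (default 0.75).
#' @param seed integer seed controlling the split.
#' @param confidence,range_method feature options, see [sway_features()].
#' @return A `data.frame` of class `pattern_dataset` with columns
#'   `record_id`, `case_id`, `window_start`, `dapmax_m`, `dmlmax_m`,
#'   `cea_m2`, `rms_m`, `label`, `split`; the seed and split fraction are
#'   stored as attributes.
#' @export
build_dataset <- function(records, window = window_spec(),
                          split_fraction = 0.75, seed = 1,
                          confidence = 0.95, range_method = "range") {
  if (inherits(records, "accel_record")) records <- list(records)
  stop_if_not(length(records) >= 1, "need at least one record")
  stop_if_not(split_fraction > 0 && split_fraction < 1,
              "split_fraction must be in (0, 1)")
  rows <- list()
  for (rec in records) {
    tr <- tryCatch(compute_displacements(rec), error = function(e) {
      message("excluding record ", attr(rec, "record_id") %||% "<unnamed>",
              ": ", conditionMessage(e))
      NULL
    })
    if (is.null(tr)) next
    wins <- segment_windows(tr, window)
    for (w in wins) {
      fv <- sway_features(w, confidence, range_method)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = attr(w, "record_id") %||% NA_character_,
        case_id = attr(w, "case_id") %||% NA_character_,
        window_start = attr(w, "window_start"),
        dapmax_m = fv[["dapmax_m"]], dmlmax_m = fv[["dmlmax_m"]],
        cea_m2 = fv[["cea_m2"]], rms_m = fv[["rms_m"]],
        label = attr(w, "label") %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  stop_if_not(length(rows) > 0, "no windows could be extracted")
  d <- do.call(rbind, rows)
  d$split <- assign_split(d$label, split_fraction, seed)
  structure(d, seed = seed, split_fraction = split_fraction,
            window = window,
            class = c("pattern_dataset", "data.frame"))
}

# Stratified train/test assignment: within each class, round(n * fraction)
# patterns (at least 1, at most n - 1 when n >= 2) go to training, chosen
# uniformly at random under the seed.
assign_split <- function(labels, split_fraction, seed) {
  split <- rep("test", length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(length(idx) * split_fraction)
      if (length(idx) >= 2) n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      split[sample(idx, n_tr)] <- "train"
    }
  })
  split
}

#' Per-class, per-case pattern counts
#'
#' Summary of a pattern dataset's composition: one row per (case, class,
#' split) with the number of patterns.
#'
#' @param dataset a `pattern_dataset`.
#' @return A `data.frame` with columns `case_id`, `label`, `split`, `n`.
#' @export
dataset_summary <- function(dataset) {
  agg <- stats::aggregate(list(n = rep(1L, nrow(dataset))),
                          by = list(case_id = dataset$case_id,
                                    label = dataset$label,
                                    split = dataset$split),
                          FUN = sum)
  agg[order(agg$case_id, agg$label, agg$split), , drop = FALSE]
}
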