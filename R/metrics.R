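# Performance indexes, Gaussian noise injection, noisy-training dataset
# construction and the full robustness condition grid.

#' Classification accuracy Q (percent)
#'
#' `Q% = 100 * (1 - sum(gamma_i) / N)` where `gamma_i` is 0 for an exact
#' class match and 1 otherwise, i.e. the percentage of patterns whose
#' predicted class equals the expected class.
#'
#' @param predicted character vector of predicted classes.
#' @param expected character vector of expected classes, same length.
#' @return Accuracy in percent.
#' @export
accuracy_q <- function(predicted, expected) {
  stop_if_not(length(predicted) == length(expected),
              "predicted and expected must have equal length")
  stop_if_not(length(predicted) > 0, "empty class vectors")
  100 * mean(as.character(predicted) == as.character(expected))
}

#' Aggregate reliability indexes (RIMean, RIStd, percent)
#'
#' Mean and standard deviation of the per-pattern reliability index over a
#' set of predictions, reported in percent. The standard deviation uses the
#' population convention (divide by n) by default, matching a plain "std"
#' operator; `sd_type = "sample"` gives the n - 1 convention.
#'
#' @param ri numeric vector of RI values in `[0, 1]` (e.g. the `ri` column
#'   of a prediction result).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Named numeric vector `c(ri_mean_pct =, ri_std_pct =)`.
#' @export
ri_aggregates <- function(ri, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stop_if_not(length(ri) > 0, "empty RI vector")
  n <- length(ri)
  s <- if (n == 1) 0 else switch(sd_type,
    population = sqrt(sum((ri - mean(ri))^2) / n),
    sample = stats::sd(ri))
  c(ri_mean_pct = 100 * mean(ri), ri_std_pct = 100 * s)
}

#' Noise-injection specification
#'
#' Defines the level grid of the robustness protocol. At level `l` (percent)
#' the per-feature noise standard deviation is
#' `sigma_j = (l / 100) * max_i |x_ij|`, with the maxima taken over the
#' training split only (the same sigmas are reused for the test split, so no
#' test-set information leaks into the corruption).
#'
#' @param levels percentages (default the study grid
#'   `c(0.1, 0.2, 0.3, 1, 3, 5, 7, 10, 15, 20)`).
#' @param seed integer seed for the noise draws.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(levels = c(0.1, 0.2, 0.3, 1, 3, 5, 7, 10, 15, 20),
                       seed = 1) {
  stop_if_not(all(levels >= 0), "noise levels must be non-negative")
  structure(list(levels = levels, seed = seed), class = "noise_spec")
}

#' Per-feature noise standard deviations at a given level
#'
#' @param dataset a `pattern_dataset`; maxima are computed on its training
#'   split (all rows if there is no `split` column).
#' @param level noise level in percent.
#' @return Named vector of sigmas for the four feature columns.
#' @export
feature_noise_sigmas <- function(dataset, level) {
  stop_if_not(level >= 0, "noise level must be non-negative")
  d <- if (!is.null(dataset$split)) dataset[dataset$split == "train", ] else
    dataset
  feats <- .subset_features("all4")
  vapply(feats, function(f) (level / 100) * max(abs(d[[f]])), numeric(1))
}

#' Corrupt a pattern dataset with Gaussian feature noise
#'
#' Adds independent zero-mean Gaussian draws to every feature of every
#' pattern, with per-feature standard deviations from
#' [feature_noise_sigmas()] (or supplied directly). Labels and split
#' assignments are untouched. Noisy values are deliberately not clipped to
#' physically admissible ranges (CEA and RMS can go negative): clipping would
#' change the noise distribution; `clip_nonnegative = TRUE` enables it for
#' sensitivity analysis.
#'
#' @param dataset a `pattern_dataset`.
#' @param level noise level in percent (0 returns the input unchanged).
#' @param sigmas optional named sigma vector overriding the level rule
#'   (useful to corrupt a test split with training-split sigmas).
#' @param seed integer seed for the draws.
#' @param clip_nonnegative clip CEA and RMS at zero (default `FALSE`).
#' @return The corrupted `pattern_dataset`.
#' @export
inject_noise <- function(dataset, level, sigmas = NULL, seed = 1,
                         clip_nonnegative = FALSE) {
  stop_if_not(level >= 0, "noise level must be non-negative")
  if (level == 0 && is.null(sigmas)) return(dataset)
  if (is.null(sigmas)) sigmas <- feature_noise_sigmas(dataset, level)
  n <- nrow(dataset)
  out <- dataset
  with_local_seed(seed, {
    for (f in names(sigmas)) {
      if (sigmas[[f]] > 0)
        out[[f]] <- out[[f]] + stats::rnorm(n, sd = sigmas[[f]])
    }
  })
  if (clip_nonnegative) {
    for (f in intersect(c("cea_m2", "rms_m"), names(out)))
      out[[f]] <- pmax(out[[f]], 0)
  }
  out
}

#' Build the noise-augmented training dataset
#'
#' Merges the clean training split with copies of itself corrupted at each
#' of the given noise levels, so the output holds `(1 + n_levels)` times the
#' clean training patterns. Class balance is preserved exactly in every copy
#' and each copy records its noise level in a `noise_pct` column.
#'
#' @param dataset a `pattern_dataset` with a training split.
#' @param levels corruption levels in percent (default the study's
#'   `c(0.1, 0.3, 1, 3, 5)`); an empty vector returns the clean training
#'   split unchanged.
#' @param seed integer master seed (one child seed per level).
#' @return A `pattern_dataset` containing only training patterns, with the
#'   added `noise_pct` provenance column.
#' @export
build_noisy_training_set <- function(dataset, levels = c(0.1, 0.3, 1, 3, 5),
                                     seed = 1) {
  d <- if (!is.null(dataset$split)) dataset[dataset$split == "train", ] else
    dataset
  stop_if_not(nrow(d) > 0, "empty training split")
  d$noise_pct <- 0
  if (!length(levels)) return(d)
  copies <- lapply(seq_along(levels), function(i) {
    sig <- feature_noise_sigmas(dataset, levels[i])
    ci <- inject_noise(d, levels[i], sigmas = sig,
                       seed = child_seed(seed, 900L, i))
    ci$noise_pct <- levels[i]
    ci
  })
  out <- do.call(rbind, c(list(d), copies))
  rownames(out) <- NULL
  attributes(out)[c("seed", "split_fraction", "window")] <-
    attributes(dataset)[c("seed", "split_fraction", "window")]
  class(out) <- c("pattern_dataset", "data.frame")
  out
}

#' Evaluate one model on one split at one noise level
#'
#' @param model fitted `mlp_model` or `threshold_model`.
#' @param dataset the clean `pattern_dataset`.
#' @param split `"train"` or `"test"`.
#' @param level noise level in percent (0 = clean evaluation).
#' @param seed seed for the noise draw.
#' @return One-row data.frame `q_pct`, `ri_mean_pct`, `ri_std_pct`, `n`.
#' @export
evaluate_model <- function(model, dataset, split = "test", level = 0,
                           seed = 1) {
  sig <- if (level > 0) feature_noise_sigmas(dataset, level) else NULL
  d <- dataset[dataset$split == split, , drop = FALSE]
  stop_if_not(nrow(d) > 0, "empty evaluation split")
  if (level > 0) d <- inject_noise(d, level, sigmas = sig, seed = seed)
  pr <- stats::predict(model, d)
  agg <- ri_aggregates(pr$ri)
  data.frame(q_pct = accuracy_q(pr$predicted, d$label),
             ri_mean_pct = agg[["ri_mean_pct"]],
             ri_std_pct = agg[["ri_std_pct"]], n = nrow(d))
}

#' Run the full robustness condition grid
#'
#' Trains one model per (model type x feature subset x training regime) and
#' evaluates each on the training and test splits at every noise level
#' (plus the clean level 0). `trained_on = "noisy"` uses the noise-augmented
#' training set of [build_noisy_training_set()]. Fresh noise draws are used
#' for every grid cell, all derived from the master seed via documented
#' child seeds, so the whole grid is reproducible end-to-end.
#'
#' @param dataset a `pattern_dataset` with train/test splits.
#' @param models character subset of `c("mlp", "threshold")`.
#' @param subsets character subset of `c("all4", "cea3", "rms3")`.
#' @param noise a [noise_spec()].
#' @param training character subset of `c("clean", "noisy")`.
#' @param noisy_levels corruption levels for the noisy training regime.
#' @param seed master seed.
#' @param mlp_args named list of extra arguments for [train_mlp()].
#' @return Tidy data.frame: `model`, `subset`, `trained_on`, `split`,
#'   `noise_pct`, `q_pct`, `ri_mean_pct`, `ri_std_pct`, `n`.
#' @export
run_condition_grid <- function(dataset, models = c("mlp", "threshold"),
                               subsets = c("all4", "cea3", "rms3"),
                               noise = noise_spec(),
                               training = c("clean", "noisy"),
                               noisy_levels = c(0.1, 0.3, 1, 3, 5),
                               seed = 1, mlp_args = list()) {
  models <- match.arg(models, several.ok = TRUE)
  subsets <- match.arg(subsets, several.ok = TRUE)
  training <- match.arg(training, several.ok = TRUE)
  levels_all <- c(0, noise$levels)
  rows <- list()
  cell <- 0L
  for (tr_on in training) {
    train_data <- if (tr_on == "noisy")
      build_noisy_training_set(dataset, levels = noisy_levels,
                               seed = child_seed(seed, 800L)) else dataset
    for (mod_name in models) {
      for (sub in subsets) {
        fit_seed <- child_seed(seed, match(mod_name, c("mlp", "threshold")),
                               match(sub, c("all4", "cea3", "rms3")),
                               match(tr_on, c("clean", "noisy")))
        model <- if (mod_name == "mlp")
          do.call(train_mlp, c(list(dataset = train_data, subset = sub,
                                    seed = fit_seed), mlp_args))
        else fit_thresholds(train_data, subset = sub)
        for (split in c("train", "test")) {
          for (lv in levels_all) {
            cell <- cell + 1L
            res <- evaluate_model(model, dataset, split = split, level = lv,
                                  seed = child_seed(noise$seed, cell))
            rows[[length(rows) + 1L]] <- cbind(
              data.frame(model = mod_name, subset = sub, trained_on = tr_on,
                         split = split, noise_pct = lv,
                         stringsAsFactors = FALSE),
              res)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a condition grid as aligned summary text
#'
#' Pivots a grid from [run_condition_grid()] into one text block per
#' (model, subset, training regime, split) with the Q/RIMean/RIStd trajectory
#' over the noise levels -- a plain-text analogue of the robustness curves.
#'
#' @param grid data.frame from [run_condition_grid()].
#' @return Character vector of report lines (also printed invisibly usable
#'   with `cat(..., sep = "\n")`).
#' @export
format_grid_report <- function(grid) {
  lines <- character(0)
  combos <- unique(grid[, c("model", "subset", "trained_on", "split")])
  for (i in seq_len(nrow(combos))) {
    cmb <- combos[i, ]
    g <- grid[grid$model == cmb$model & grid$subset == cmb$subset &
                grid$trained_on == cmb$trained_on & grid$split == cmb$split, ]
    g <- g[order(g$noise_pct), ]
    lines <- c(lines,
      sprintf("%s / %s / trained on %s / %s split (n = %d)",
              toupper(cmb$model), cmb$subset, cmb$trained_on, cmb$split,
              g$n[1]),
      sprintf("  noise %%: %s", paste(formatC(g$noise_pct, width = 6),
                                      collapse = " ")),
      sprintf("  Q %%    : %s", paste(formatC(g$q_pct, format = "f",
                                              digits = 1, width = 6),
                                      collapse = " ")),
      sprintf("  RImean%%: %s", paste(formatC(g$ri_mean_pct, format = "f",
                                              digits = 1, width = 6),
                                      collapse = " ")),
      sprintf("  RIstd %%: %s", paste(formatC(g$ri_std_pct, format = "f",
                                              digits = 1, width = 6),
                                      collapse = " ")),
      "")
  }
  lines
}
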