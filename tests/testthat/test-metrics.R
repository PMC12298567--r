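test_that("accuracy Q counts exact class matches in percent", {
  expect_equal(accuracy_q(c("ST", "AP", "ML", "UNST"),
                          c("ST", "AP", "ML", "UNST")), 100)
  expect_equal(accuracy_q(c("ST", "AP", "ML", "UNST"),
                          c("ST", "AP", "ML", "ST")), 75)
  # 3 errors at the full-study pattern count
  pred <- rep("ST", 1338); exp_ <- pred; exp_[1:3] <- "AP"
  expect_equal(accuracy_q(pred, exp_), 100 * (1 - 3 / 1338))
  expect_error(accuracy_q("ST", c("ST", "AP")), "equal length")
  set.seed(61)
  for (k in 1:50) {
    n <- sample(2:300, 1)
    p <- sample(sway_classes(), n, replace = TRUE)
    e <- sample(sway_classes(), n, replace = TRUE)
    expect_equal(accuracy_q(p, e), oracle_q(p, e), tolerance = 1e-12)
  }
})

test_that("Q is invariant under consistent class relabelling", {
  set.seed(62)
  p <- sample(sway_classes(), 200, replace = TRUE)
  e <- sample(sway_classes(), 200, replace = TRUE)
  perm <- setNames(sample(sway_classes()), sway_classes())
  expect_equal(accuracy_q(unname(perm[p]), unname(perm[e])),
               accuracy_q(p, e))
})

test_that("RI aggregates use the population std and match the oracle", {
  a <- ri_aggregates(rep(1, 10))
  expect_equal(unname(a), c(100, 0))
  a <- ri_aggregates(c(1, 0))
  expect_equal(unname(a), c(50, 50))  # population denominator
  a_s <- ri_aggregates(c(1, 0), sd_type = "sample")
  expect_equal(a_s[["ri_std_pct"]], 100 * sd(c(1, 0)))
  set.seed(63)
  for (k in 1:50) {
    ri <- runif(sample(2:200, 1))
    got <- ri_aggregates(ri)
    ora <- oracle_ri_aggregates(ri)
    expect_equal(unname(got), unname(ora), tolerance = 1e-12)
    expect_equal(ri_aggregates(rev(ri)), got, tolerance = 1e-12)
  }
  expect_error(ri_aggregates(numeric(0)), "empty")
})

test_that("noise sigmas follow the percent-of-training-maximum rule", {
  ds <- default_dataset()
  sig <- feature_noise_sigmas(ds, 20)
  tr <- ds[ds$split == "train", ]
  expect_equal(sig[["dapmax_m"]], 0.2 * max(abs(tr$dapmax_m)),
               tolerance = 1e-12)
  expect_equal(unname(feature_noise_sigmas(ds, 0)), rep(0, 4))
  expect_error(feature_noise_sigmas(ds, -1), "non-negative")
})

test_that("noise injection is Gaussian with the nominal sigma, zero level is identity", {
  ds <- default_dataset()
  expect_identical(inject_noise(ds, 0), ds)
  big <- ds[rep(seq_len(nrow(ds)), length.out = 1e5), ]
  noisy <- inject_noise(big, 10, seed = 5)
  sig <- feature_noise_sigmas(ds, 10)
  for (f in names(sig)) {
    emp <- sd(noisy[[f]] - big[[f]])
    expect_equal(emp, sig[[f]], tolerance = 0.02)
  }
  expect_identical(noisy$label, big$label)
  # negative CEA/RMS values are allowed unless clipping is requested
  noisy20 <- inject_noise(ds, 20, seed = 6)
  expect_true(any(noisy20$cea_m2 < 0))
  clipped <- inject_noise(ds, 20, seed = 6, clip_nonnegative = TRUE)
  expect_true(all(clipped$cea_m2 >= 0))
  expect_error(inject_noise(ds, -5), "non-negative")
})

test_that("noisy training set is (1 + levels) copies with balance preserved", {
  ds <- default_dataset()
  n_tr <- sum(ds$split == "train")
  aug <- build_noisy_training_set(ds, seed = 2)
  expect_equal(nrow(aug), 6 * n_tr)  # clean + 5 corrupted copies
  expect_equal(sort(unique(aug$noise_pct)), c(0, 0.1, 0.3, 1, 3, 5))
  tab <- table(aug$label, aug$noise_pct)
  base <- as.integer(table(ds$label[ds$split == "train"]))
  expect_true(all(apply(tab, 2, function(col) all(as.integer(col) == base))))
  id <- build_noisy_training_set(ds, levels = numeric(0))
  expect_equal(nrow(id), n_tr)
  expect_error(build_noisy_training_set(ds[0, ]), "empty")
})

test_that("condition grid covers every cell and reproduces clean metrics at level 0", {
  ds <- default_dataset()
  levels <- c(1, 10)
  grid <- run_condition_grid(ds, models = "threshold", subsets = "all4",
                             noise = noise_spec(levels, seed = 3),
                             training = "clean", seed = 3)
  expect_equal(nrow(grid), 1 * 1 * (length(levels) + 1) * 2 * 1)
  clean_row <- grid[grid$split == "test" & grid$noise_pct == 0, ]
  direct <- evaluate_model(threshold_clean(), ds, "test")
  expect_equal(clean_row$q_pct, direct$q_pct, tolerance = 1e-12)
  expect_equal(clean_row$ri_mean_pct, direct$ri_mean_pct, tolerance = 1e-12)
  rep_lines <- format_grid_report(grid)
  expect_true(any(grepl("THRESHOLD / all4", rep_lines)))
})

test_that("training-pattern order does not change evaluation metrics", {
  ds <- default_dataset()
  shuffled <- ds[sample(nrow(ds)), ]
  attributes(shuffled)[c("seed", "split_fraction", "class")] <-
    attributes(ds)[c("seed", "split_fraction", "class")]
  t1 <- fit_thresholds(ds)
  t2 <- fit_thresholds(shuffled)
  e1 <- evaluate_model(t1, ds, "test")
  e2 <- evaluate_model(t2, ds, "test")
  expect_equal(e1$q_pct, e2$q_pct, tolerance = 1e-9)
  expect_equal(e1$ri_mean_pct, e2$ri_mean_pct, tolerance = 1e-9)
})
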