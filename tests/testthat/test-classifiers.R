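test_that("reliability index evaluates the top-two probability margin", {
  expect_equal(reliability_index(c(1, 0, 0, 0)), 1)
  expect_equal(reliability_index(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(reliability_index(c(0.9, 0.05, 0.03, 0.02)),
               (0.9 - 0.05) / 0.9, tolerance = 1e-12)
  set.seed(7)
  for (k in 1:100) {
    p <- runif(4); p <- p / sum(p)
    expect_equal(reliability_index(p), oracle_ri(p), tolerance = 1e-12)
  }
})

test_that("MLP training is deterministic and respects the topology", {
  ds <- default_dataset()
  m1 <- train_mlp(ds, epochs = 5, seed = 77)
  m2 <- train_mlp(ds, epochs = 5, seed = 77)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_mlp(ds, epochs = 5, seed = 78)
  expect_false(identical(m3$weights, m1$weights))
  # default: extra input-width rectifier layer ahead of 8-10-8 hidden stack
  expect_equal(m1$topology, c(4, 4, 8, 10, 8, 4))
  m4 <- train_mlp(ds, epochs = 2, seed = 1, input_relu_layer = FALSE)
  expect_equal(m4$topology, c(4, 8, 10, 8, 4))
  # 3-feature subsets fit without code change
  m5 <- train_mlp(ds, subset = "rms3", epochs = 2, seed = 1,
                  input_relu_layer = FALSE)
  expect_equal(m5$topology, c(3, 8, 10, 8, 4))
})

test_that("MLP probabilities form a simplex for arbitrary inputs", {
  m <- mlp_clean()
  set.seed(11)
  X <- data.frame(dapmax_m = c(runif(200, 0, 0.5), 0, 1e6, -1e6),
                  dmlmax_m = c(runif(200, 0, 0.3), 0, 1e6, -1e6),
                  cea_m2 = c(runif(200, 0, 0.1), 0, 1e6, -1e6),
                  rms_m = c(runif(200, 0, 0.05), 0, 1e6, -1e6))
  pr <- predict(m, X)
  P <- as.matrix(pr[, paste0("p_", sway_classes())])
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(pr$ri >= 0 & pr$ri <= 1))
})

test_that("MLP rejects degenerate training input and mismatched features", {
  ds <- default_dataset()
  one_class <- ds[ds$label == "ST", ]
  expect_error(train_mlp(one_class, epochs = 1), "2 classes")
  bad <- ds; bad$cea_m2[1] <- NA
  expect_error(train_mlp(bad, epochs = 1), "non-finite")
  m <- mlp_clean()
  expect_error(predict(m, c(0.1, 0.2)), "dimensionality")
})

test_that("Youden threshold search matches a brute-force sweep and pROC", {
  # perfectly separated groups: cutoff strictly between them
  scores <- c(1, 2, 3, 10, 11)
  pos <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  th <- youden_threshold(scores, pos)
  expect_gt(th$threshold, 3); expect_lt(th$threshold, 10)
  expect_equal(th$sensitivity, 1); expect_equal(th$specificity, 1)

  set.seed(21)
  for (k in 1:25) {
    sc <- c(rnorm(40, 0), rnorm(40, runif(1, 0.5, 3)))
    po <- rep(c(FALSE, TRUE), each = 40)
    got <- youden_threshold(sc, po)
    ora <- oracle_youden(sc, po)
    expect_equal(got$threshold, ora$threshold, tolerance = 1e-12)
    expect_equal(got$J, ora$J, tolerance = 1e-12)
  }
  set.seed(22)
  sc <- c(rnorm(60, 0), rnorm(60, 1.5)); po <- rep(0:1, each = 60)
  got <- youden_threshold(sc, po == 1)
  r <- pROC::roc(po, sc, quiet = TRUE, direction = "<")
  best_J <- max(r$sensitivities + r$specificities - 1)
  expect_equal(got$J, best_J, tolerance = 1e-12)
})

test_that("threshold model fits, warns on constant features and predicts", {
  ds <- default_dataset()
  tm <- threshold_clean()
  expect_true(is.finite(tm$thresholds$dapmax$threshold))
  expect_true(is.finite(tm$thresholds$dmlmax$threshold))
  expect_true(is.finite(tm$thresholds$disp$threshold))
  pr <- predict(tm, ds[ds$split == "test", ])
  expect_true(all(pr$predicted %in% sway_classes()))

  const <- ds
  const$dapmax_m <- 1
  expect_warning(fit_thresholds(const), "constant")
})

test_that("threshold pseudo-probabilities are a valid simplex with zero RI at the thresholds", {
  tm <- threshold_clean()
  at_th <- c(dapmax_m = tm$thresholds$dapmax$threshold,
             dmlmax_m = tm$thresholds$dmlmax$threshold,
             cea_m2 = tm$thresholds$disp$threshold,
             rms_m = 0)
  P <- threshold_pseudo_probabilities(tm, at_th)
  expect_equal(as.numeric(P), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(reliability_index(P), 0, tolerance = 1e-12)
  # saturated margins push one class toward the top
  far_ap <- c(dapmax_m = 100, dmlmax_m = -100, cea_m2 = -100, rms_m = 0)
  pr <- predict(tm, far_ap)
  expect_equal(pr$predicted, "AP")
  expect_equal(which.max(as.numeric(pr[paste0("p_", sway_classes())])),
               which(sway_classes() == "AP"))
  set.seed(31)
  X <- data.frame(dapmax_m = rnorm(500, 0.1, 0.2),
                  dmlmax_m = rnorm(500, 0.05, 0.1),
                  cea_m2 = rnorm(500, 0.01, 0.05),
                  rms_m = rnorm(500, 0.005, 0.01))
  P <- threshold_pseudo_probabilities(tm, X)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, 500), tolerance = 1e-12)
})

test_that("models round-trip bit-exactly through their JSON serialization", {
  m <- train_mlp(default_dataset(), epochs = 3, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_model(m, p1)
  m2 <- read_model(p1)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$biases, lapply(m$biases, as.numeric))
  expect_identical(m2$center, m$center)
  expect_identical(m2$scale, m$scale)
  ds <- default_dataset()
  expect_identical(predict(m, ds[1:10, ]), predict(m2, ds[1:10, ]))

  tm <- threshold_clean()
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(tm, p2)
  tm2 <- read_model(p2)
  expect_identical(predict(tm, ds[1:10, ]), predict(tm2, ds[1:10, ]))
  expect_equal(tm2$thresholds$dapmax$threshold,
               tm$thresholds$dapmax$threshold, tolerance = 0)
})

test_that("cross-validated accuracy on clean synthetic data stays near perfect", {
  ds <- default_dataset()
  d <- as.data.frame(ds)
  set.seed(41)
  folds <- sample(rep(1:4, length.out = nrow(d)))
  for (f in 1:4) {
    tr <- d[folds != f, ]; te <- d[folds == f, ]
    tr$split <- "train"
    m <- train_mlp(tr, epochs = 60, seed = 50 + f)
    q <- accuracy_q(predict(m, te)$predicted, te$label)
    expect_gte(q, 95)
  }
})
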