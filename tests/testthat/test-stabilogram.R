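make_record <- function(ax, ay, az, fs = 100) {
  n <- max(length(ax), length(ay), length(az))
  structure(data.frame(t = (seq_len(n) - 1) / fs,
                       ax_g = rep_len(ax, n), ay_g = rep_len(ay, n),
                       az_g = rep_len(az, n)),
            fs = fs, class = c("accel_record", "data.frame"))
}

test_that("upright acceleration maps to the stabilogram origin", {
  tr <- compute_displacements(make_record(0, 1, 0, fs = 100),
                              node_geometry(1.3, 0.6))
  expect_equal(tr$dap_m, 0)
  expect_equal(tr$dml_m, 0)
})

test_that("pure tilts recover the lever-arm tangent closed forms", {
  th5 <- 5 * pi / 180
  tr <- compute_displacements(make_record(0, cos(th5), sin(th5)),
                              node_geometry(1.0, 0.5))
  expect_equal(tr$dap_m[1], tan(th5), tolerance = 1e-12)  # ~0.08749 m
  expect_equal(tr$dml_m[1], 0)

  th10 <- 10 * pi / 180
  tr <- compute_displacements(make_record(sin(th10), cos(th10), 0),
                              node_geometry(1.0, 0.5))
  expect_equal(tr$dml_m[1], 0.5 * tan(th10), tolerance = 1e-12)  # ~0.08816 m
  expect_equal(tr$dap_m[1], 0)
})

test_that("displacements match the brute-force oracle on random input", {
  set.seed(101)
  for (k in 1:20) {
    n <- sample(5:200, 1)
    ax <- rnorm(n, 0, 0.2); ay <- rnorm(n, 1, 0.1); az <- rnorm(n, 0, 0.2)
    g <- node_geometry(runif(1, 0.5, 2), runif(1, 0.2, 1))
    tr <- compute_displacements(make_record(ax, ay, az), g)
    expect_equal(tr$dap_m, oracle_dap(ax, ay, az, g$H1), tolerance = 1e-12)
    expect_equal(tr$dml_m, oracle_dml(ax, ay, az, g$H2), tolerance = 1e-12)
  }
})

test_that("small-angle response is linear to within 0.1%", {
  for (th in c(0.5, 1, 2) * pi / 180) {
    tr <- compute_displacements(make_record(0, cos(th), sin(th)),
                                node_geometry(1.2, 0.5))
    expect_lt(abs(tr$dap_m[1] - 1.2 * th) / (1.2 * th), 1e-3)
  }
})

test_that("displacements are antisymmetric and acceleration-scale invariant", {
  set.seed(55)
  ax <- rnorm(50, 0, 0.1); ay <- rnorm(50, 1, 0.05); az <- rnorm(50, 0, 0.1)
  g <- node_geometry(1.1, 0.45)
  base <- compute_displacements(make_record(ax, ay, az), g)
  neg_az <- compute_displacements(make_record(ax, ay, -az), g)
  expect_equal(neg_az$dap_m, -base$dap_m, tolerance = 1e-12)
  neg_ax <- compute_displacements(make_record(-ax, ay, az), g)
  expect_equal(neg_ax$dml_m, -base$dml_m, tolerance = 1e-12)
  # ratios of accelerations: converting g <-> m/s^2 changes nothing
  scaled <- compute_displacements(make_record(ax * 9.81, ay * 9.81,
                                              az * 9.81), g)
  expect_equal(scaled$dap_m, base$dap_m, tolerance = 1e-12)
  expect_equal(scaled$dml_m, base$dml_m, tolerance = 1e-12)
})

test_that("free-fall-like records are rejected, not clamped", {
  expect_error(compute_displacements(make_record(0, 1e-9, 0),
                                     node_geometry(1, 0.5)),
               "free-fall")
})

test_that("window counts follow floor((T - W)/S) + 1", {
  expect_equal(count_windows(60, window_spec(10, 1)), 51L)
  expect_equal(count_windows(10, window_spec(10, 1)), 1L)
  expect_equal(count_windows(9.9, window_spec(10, 1)), 0L)
  expect_equal(count_windows(87, window_spec(10, 1)), 78L)
  expect_equal(count_windows(60, window_spec(10, 9)), 6L)
})

test_that("segmentation yields correctly placed, label-carrying windows", {
  rec <- simulate_record(ideal_rig(), motion_spec("AP", duration = 60),
                         seed = 1)
  tr <- compute_displacements(rec)
  wins <- segment_windows(tr, window_spec(10, 1))
  expect_length(wins, 51)
  expect_true(all(vapply(wins, nrow, 1L) == 1000))
  starts <- vapply(wins, attr, 1.0, "window_start")
  expect_equal(starts, 0:50)
  expect_true(all(vapply(wins, attr, "", "label") == "AP"))
  # window content equals the corresponding trace slice
  expect_equal(wins[[5]]$dap_m, tr$dap_m[401:1400])
})

test_that("too-short traces give an empty window list with a warning", {
  rec <- simulate_record(ideal_rig(), motion_spec("ST", duration = 10),
                         seed = 1)
  tr <- compute_displacements(rec)
  tr9 <- structure(tr[1:990, ], fs = 100,
                   class = c("stabilogram_trace", "data.frame"))
  expect_warning(w <- segment_windows(tr9), "shorter than one window")
  expect_length(w, 0)
})

test_that("only a 1 s shift is compatible with the reported dataset size", {
  # 20 records of 60-87 s produced 1338 patterns; with a 10 s window the
  # 1 s shift bounds are 20*51..20*78 patterns, the 9 s shift gives at most
  # 20*9 -- an order of magnitude short.
  lo_1s <- 20 * count_windows(60, window_spec(10, 1))
  hi_1s <- 20 * count_windows(87, window_spec(10, 1))
  hi_9s <- 20 * count_windows(87, window_spec(10, 9))
  expect_true(lo_1s <= 1338 && 1338 <= hi_1s)
  expect_lt(hi_9s, 1338)
})
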