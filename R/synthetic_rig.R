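# Synthetic rigid-rig accelerometer signal generator.
#
# Emulates a chest-height sensor node mounted on a rigid structure with a
# floor joint (antero-posterior tilts), a belt joint (medio-lateral tilts), a
# standing-still condition and a randomly tilting unstable condition, so that
# the full processing chain can be exercised without hardware.

#' Rig / sensor configuration
#'
#' Describes one node-height case of the test structure plus the simulated
#' accelerometer front-end.
#'
#' @param H1 metres; distance from the sensor node to the floor joint.
#' @param H2 metres; distance from the sensor node to the belt joint.
#'   Must satisfy `H1 > H2 > 0` (the belt joint sits above the floor).
#' @param fs sampling rate in Hz (default 100).
#' @param full_scale accelerometer full scale in g (default 2, i.e. +/- 2 g).
#' @param quantization_bits ADC resolution; 0 disables quantization,
#'   otherwise 8..24 bits over `[-full_scale, +full_scale]` (default 16).
#' @param sensor_noise_sd additive white noise per axis, in g (default
#'   0.002 g, typical of a MEMS accelerometer at a 100 Hz output rate).
#' @param case_id identifier for this node-height case.
#' @param seed optional default seed used by [simulate_record()].
#' @return An object of class `rig_config`.
#' @export
rig_config <- function(H1 = 1.25, H2 = 0.48, fs = 100, full_scale = 2,
                       quantization_bits = 16, sensor_noise_sd = 0.002,
                       case_id = "case1", seed = NULL) {
  stop_if_not(is.numeric(H1) && is.numeric(H2) && H1 > H2 && H2 > 0,
              "rig geometry must satisfy H1 > H2 > 0")
  stop_if_not(fs > 0, "sampling rate fs must be positive")
  stop_if_not(full_scale > 0, "full_scale must be positive")
  stop_if_not(quantization_bits == 0 ||
                (quantization_bits >= 8 && quantization_bits <= 24),
              "quantization_bits must be 0 (off) or in 8..24")
  stop_if_not(sensor_noise_sd >= 0, "sensor_noise_sd must be non-negative")
  structure(list(H1 = H1, H2 = H2, fs = fs, full_scale = full_scale,
                 quantization_bits = as.integer(quantization_bits),
                 sensor_noise_sd = sensor_noise_sd,
                 case_id = as.character(case_id), seed = seed),
            class = "rig_config")
}

#' Default set of node-height cases
#'
#' Five rig configurations differing in sensor-node height, spanning a
#' plausible chest-mounting range (node-to-floor 1.10--1.40 m, node-to-belt
#' 0.40--0.55 m), used to probe robustness of the method against the exact
#' node position.
#'
#' @param n number of cases (default 5).
#' @param ... further arguments passed to [rig_config()] (e.g.
#'   `sensor_noise_sd`).
#' @return List of `rig_config` objects with case ids `"case1"..."caseN"`.
#' @export
default_rig_cases <- function(n = 5, ...) {
  H1 <- seq(1.10, 1.40, length.out = n)
  H2 <- seq(0.40, 0.55, length.out = n)
  lapply(seq_len(n), function(i)
    rig_config(H1 = H1[i], H2 = H2[i], case_id = paste0("case", i), ...))
}

#' Motion specification for one record
#'
#' Defines the tilt trajectory the rig follows. `ST` keeps the structure
#' essentially upright (a tiny bounded residual wander); `AP` and `ML` are
#' sinusoidal tilts about the floor and belt joints respectively (a
#' `tilt_frequency` of 0 yields a constant tilt at `tilt_amplitude`); `UNST`
#' is a pair of independent random walks in the two tilt planes, reflected at
#' `+/- tilt_amplitude`, producing simultaneous excursions in both directions.
#'
#' @param class one of `"ST"`, `"AP"`, `"ML"`, `"UNST"`.
#' @param duration record length in seconds; at least 10 s (one analysis
#'   window).
#' @param tilt_amplitude radians. Sinusoid amplitude for AP/ML (default
#'   0.10 rad), residual-wander bound for ST (default 0.005 rad), reflection
#'   bound for UNST (default 0.15 rad).
#' @param tilt_frequency Hz; AP/ML sinusoid frequency (default 0.25 Hz, slow
#'   enough for the quasi-static model).
#' @param unst_step_sd radians; per-sample step of the UNST random walk
#'   (default 0.01).
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(class = c("ST", "AP", "ML", "UNST"), duration = 60,
                        tilt_amplitude = NULL, tilt_frequency = 0.25,
                        unst_step_sd = 0.01) {
  class <- match.arg(class)
  if (is.null(tilt_amplitude)) {
    tilt_amplitude <- switch(class, ST = 0.005, AP = 0.10, ML = 0.10,
                             UNST = 0.15)
  }
  stop_if_not(duration >= 10,
              "duration must be at least 10 s (one full analysis window)")
  stop_if_not(tilt_amplitude >= 0 && tilt_amplitude < pi / 2,
              "tilt_amplitude must lie in [0, pi/2)")
  if (class %in% c("AP", "ML"))
    stop_if_not(tilt_frequency >= 0, "tilt_frequency must be non-negative")
  stop_if_not(unst_step_sd >= 0, "unst_step_sd must be non-negative")
  structure(list(class = class, duration = duration,
                 tilt_amplitude = tilt_amplitude,
                 tilt_frequency = tilt_frequency,
                 unst_step_sd = unst_step_sd),
            class = "motion_spec")
}

# Random walk reflected at +/- bound, starting at 0. Vectorised reflection via
# the standard triangular fold of the unbounded walk.
.reflected_walk <- function(n, step_sd, bound) {
  if (bound <= 0 || step_sd <= 0) return(numeric(n))
  w <- cumsum(stats::rnorm(n, sd = step_sd))
  period <- 4 * bound
  u <- (w + bound) %% period
  ifelse(u <= 2 * bound, u - bound, 3 * bound - u)
}

# Tilt trajectories (theta_ap, theta_ml) in radians for a motion spec.
.tilt_trajectory <- function(motion, n, fs) {
  t <- (seq_len(n) - 1) / fs
  switch(motion$class,
    ST = list(ap = .reflected_walk(n, motion$tilt_amplitude / 10,
                                   motion$tilt_amplitude),
              ml = .reflected_walk(n, motion$tilt_amplitude / 10,
                                   motion$tilt_amplitude)),
    AP = list(ap = if (motion$tilt_frequency > 0)
                     motion$tilt_amplitude *
                       sin(2 * pi * motion$tilt_frequency * t)
                   else rep(motion$tilt_amplitude, n),
              ml = numeric(n)),
    ML = list(ap = numeric(n),
              ml = if (motion$tilt_frequency > 0)
                     motion$tilt_amplitude *
                       sin(2 * pi * motion$tilt_frequency * t)
                   else rep(motion$tilt_amplitude, n)),
    UNST = list(ap = .reflected_walk(n, motion$unst_step_sd,
                                     motion$tilt_amplitude),
                ml = .reflected_walk(n, motion$unst_step_sd,
                                     motion$tilt_amplitude))
  )
}

#' Simulate one accelerometer record
#'
#' Generates a triaxial acceleration record under the quasi-static model: the
#' accelerometer reads only the gravity vector projected onto its axes, so for
#' tilt angles (thAP, thML) the noiseless axes are
#' `Az = sin(thAP) cos(thML)`, `Ax = cos(thAP) sin(thML)` and
#' `Ay = sqrt(1 - Ax^2 - Az^2)` (units of g; y is the longitudinal axis,
#' gravity-aligned in upright stance; z antero-posterior; x medio-lateral).
#' The vector norm is exactly 1 g before noise. White sensor noise is then
#' added per axis, the signal is quantized to the configured ADC resolution
#' over `+/- full_scale`, and finally clipped to the full scale -- mimicking
#' the physical signal chain.
#'
#' @param rig a [rig_config()].
#' @param motion a [motion_spec()].
#' @param seed integer; overrides `rig$seed`. If both are `NULL` the current
#'   RNG state is used.
#' @param record_id identifier stored on the record.
#' @return A `data.frame` of class `accel_record` with columns `t`, `ax_g`,
#'   `ay_g`, `az_g` and attributes `label`, `case_id`, `fs`, `H1`, `H2`,
#'   `record_id`.
#' @export
simulate_record <- function(rig, motion, seed = rig$seed,
                            record_id = NULL) {
  stop_if_not(inherits(rig, "rig_config"), "rig must be a rig_config")
  stop_if_not(inherits(motion, "motion_spec"), "motion must be a motion_spec")
  n <- round(motion$duration * rig$fs)
  gen <- function() {
    th <- .tilt_trajectory(motion, n, rig$fs)
    az <- sin(th$ap) * cos(th$ml)
    ax <- cos(th$ap) * sin(th$ml)
    ay <- sqrt(pmax(0, 1 - ax^2 - az^2))
    if (rig$sensor_noise_sd > 0) {
      ax <- ax + stats::rnorm(n, sd = rig$sensor_noise_sd)
      ay <- ay + stats::rnorm(n, sd = rig$sensor_noise_sd)
      az <- az + stats::rnorm(n, sd = rig$sensor_noise_sd)
    }
    if (rig$quantization_bits > 0) {
      lsb <- 2 * rig$full_scale / 2^rig$quantization_bits
      ax <- round(ax / lsb) * lsb
      ay <- round(ay / lsb) * lsb
      az <- round(az / lsb) * lsb
    }
    fsg <- rig$full_scale
    list(ax = pmin(pmax(ax, -fsg), fsg),
         ay = pmin(pmax(ay, -fsg), fsg),
         az = pmin(pmax(az, -fsg), fsg))
  }
  a <- if (is.null(seed)) gen() else with_local_seed(seed, gen())
  rec <- data.frame(t = (seq_len(n) - 1) / rig$fs,
                    ax_g = a$ax, ay_g = a$ay, az_g = a$az)
  structure(rec,
            label = motion$class, case_id = rig$case_id, fs = rig$fs,
            H1 = rig$H1, H2 = rig$H2,
            record_id = record_id %||%
              paste(rig$case_id, motion$class, sep = "_"),
            class = c("accel_record", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a balanced labelled dataset of records
#'
#' Produces `per_class_records` records of every class for every node-height
#' case, with durations drawn uniformly from `duration_range`. The study
#' conditions this emulates: 100 Hz sampling, +/- 2 g full scale, four motion
#' classes, record lengths of 60--87 s, five node-height cases.
#'
#' @param rig_cases non-empty list of [rig_config()] objects.
#' @param per_class_records records per class per case (>= 1).
#' @param duration_range length-2 numeric, seconds (default `c(60, 87)`).
#' @param classes classes to simulate (default all four).
#' @param seed master seed; every record draws a child seed from it, so the
#'   whole dataset is reproducible.
#' @param motion_args named list of overrides passed to [motion_spec()]
#'   (e.g. `list(tilt_amplitude = 0.2)` -- applied to every class).
#' @return List of `accel_record` objects.
#' @export
simulate_dataset <- function(rig_cases, per_class_records = 1,
                             duration_range = c(60, 87),
                             classes = sway_classes(), seed = 1,
                             motion_args = list()) {
  stop_if_not(length(rig_cases) >= 1, "rig_cases must be non-empty")
  stop_if_not(per_class_records >= 1, "per_class_records must be >= 1")
  stop_if_not(length(duration_range) == 2 &&
                duration_range[1] <= duration_range[2] &&
                duration_range[1] >= 10,
              "duration_range must be an increasing pair with minimum >= 10 s")
  out <- list()
  idx <- 0L
  for (ci in seq_along(rig_cases)) {
    rig <- rig_cases[[ci]]
    stop_if_not(inherits(rig, "rig_config"),
                "rig_cases must contain rig_config objects")
    for (cl in classes) {
      for (r in seq_len(per_class_records)) {
        idx <- idx + 1L
        s <- child_seed(seed, ci, match(cl, sway_classes()), r)
        dur <- with_local_seed(s, stats::runif(1, duration_range[1],
                                               duration_range[2]))
        args <- c(list(class = cl, duration = dur), motion_args)
        motion <- do.call(motion_spec, args)
        out[[idx]] <- simulate_record(
          rig, motion, seed = child_seed(s, 1L),
          record_id = sprintf("%s_%s_%02d", rig$case_id, cl, r))
      }
    }
  }
  out
}
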