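# Shared fixtures, built once per test run and cached. The default dataset
# reproduces the study conditions: five node-height cases, one record per
# class per case, durations 60-87 s, 100 Hz, +/- 2 g.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_dataset <- function() {
  fixture("default_dataset", function() {
    recs <- simulate_dataset(default_rig_cases(5), per_class_records = 1,
                             seed = 42)
    build_dataset(recs, seed = 7)
  })
}

mlp_clean <- function(subset = "all4") {
  fixture(paste0("mlp_clean_", subset), function()
    train_mlp(default_dataset(), subset = subset, seed = 5))
}

mlp_noisy_trained <- function() {
  fixture("mlp_noisy_trained", function() {
    noisy <- build_noisy_training_set(default_dataset(), seed = 11)
    train_mlp(noisy, seed = 5)
  })
}

threshold_clean <- function(subset = "all4") {
  fixture(paste0("threshold_clean_", subset), function()
    fit_thresholds(default_dataset(), subset = subset))
}

# A tiny noiseless, unquantised rig for closed-form checks.
ideal_rig <- function(...) {
  rig_config(H1 = 1.0, H2 = 0.5, sensor_noise_sd = 0,
             quantization_bits = 0, case_id = "ideal", ...)
}
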