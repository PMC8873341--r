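# Small in-code fixtures shared across the suite. Everything is generated
# at test time; sizes are kept tiny so individual tests run in seconds.

# two-session schedule: 6 series of 62 s at 10 Hz (2 series per class, the
# minimum that allows series-level held-out evaluation)
tiny_schedule <- function(sampling_rate = 10) {
  build_schedule(sessions = 2, series_per_session = 3,
                 sampling_rate = sampling_rate)
}

# low-noise, well-separated subject for quick learnability checks
clean_profile <- function(n_channels = 8, seed = 7,
                          noise = list(mayer = 0.05, respiratory = 0.02,
                                       cardiac = 0.02, white = 0.05)) {
  subject_profile(sprintf("T%02d", seed),
                  amplitudes = c("0-back" = 0.2, "2-back" = 0.6,
                                 "3-back" = 1.0),
                  channel_gains = rep(1, n_channels),
                  noise = noise, rng_seed = seed)
}

# small epoch set straight from the forward model (2 Hz windows)
tiny_epochs <- function(seed = 7, n_channels = 8, schedule = tiny_schedule(),
                        profile = clean_profile(n_channels, seed)) {
  hemo <- hemodynamic_forward(schedule, profile)
  hemo <- lowpass_filter(hemo)
  segment_epochs(hemo, window_s = 10, step_s = 5, decimate = 5)
}

# network matched to tiny_epochs geometry (8 channels x 20 samples x 2)
tiny_spec <- function(n_channels = 8, n_samples = 20, n_classes = 3) {
  cnn_spec(c(n_channels, n_samples, 2),
           list(layer_conv(4, c(3, 3)), layer_conv(4, c(3, 3)),
                layer_maxpool(c(2, 2)), layer_flatten(),
                layer_dense(16), layer_output(n_classes)),
           n_classes)
}

# deterministic small cohort for split/sweep contracts
tiny_cohort_epochs <- function(n_subjects = 4, master_seed = 3,
                               n_channels = 8) {
  cohort <- make_cohort(n_subjects = n_subjects,
                        schedule = tiny_schedule(),
                        n_channels = n_channels,
                        master_seed = master_seed)
  cfg <- default_run_config(master_seed)
  cfg$preprocess$decimate <- 5
  prepare_cohort_epochs(cohort, cfg)
}
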