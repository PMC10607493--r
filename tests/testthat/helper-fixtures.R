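# Shared fixtures: tiny configurations and scenes that exercise every code
# path in well under a second.

tiny_model_config <- function(...) {
  args <- list(...)
  defaults <- list(rnn_type = "gru", rnn_depth = 1L, n_blocks = 1L,
                   feature_dim = 6L, hidden_dim = 4L, chunk_len = 5L,
                   n_heads = 2L, n_sources = 2L, frame_len = 8L,
                   use_msam = TRUE, seed = 3L)
  defaults[names(args)] <- args
  do.call(model_config, defaults)
}

tiny_scene_spec <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 0.05, sample_rate_hz = 4000,
                   n_sensors = 3L, pulse_rate_hz = 40,
                   pulse_band_hz = c(600, 1500),
                   sensor_delays_samples = c(0L, 2L, 4L),
                   sensor_gains = c(1, 0.9, 0.8), snr_db = 5, seed = 9L)
  defaults[names(args)] <- args
  do.call(scene_spec, defaults)
}

# access to internal helpers under test
ns <- asNamespace("multisams")
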