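# Small phantom configurations shared across tests. Grids are kept small so
# the suite runs quickly; the physics (spacing, frame interval, PRFS
# constants) matches the package defaults.

quiet_config <- function(grid_size = c(32L, 32L), n_frames = 60L,
                         resp_amplitude = 0, snr = Inf, drift_rate = 0,
                         heat_peak = 0,
                         heat_onset_frame = max(2L, n_frames %/% 2L),
                         heat_duration_frames = 10L, ...) {
  # all perturbations off unless overridden
  phantom_config(grid_size = grid_size, n_frames = n_frames,
                 resp_amplitude = resp_amplitude, snr = snr,
                 drift_rate = drift_rate, heat_peak = heat_peak,
                 heat_onset_frame = heat_onset_frame,
                 heat_duration_frames = heat_duration_frames, ...)
}

fast_pipeline_config <- function(...) {
  # compact timing: 10 learning frames, 5-frame baseline, RF at frame 16
  pipeline_config(n_learn = 10L, sigma_baseline_window = 5L,
                  rf_start_frame = 16L, ...)
}

centre_px <- function(config) (config$grid_size + 1) / 2

interior_mask <- function(dim, margin = 8L) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[(margin + 1):(dim[1] - margin), (margin + 1):(dim[2] - margin)] <- TRUE
  m
}
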