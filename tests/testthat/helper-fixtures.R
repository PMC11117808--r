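# Shared fixture builders.  Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# channels x time matrix of a pure sinusoid with per-channel amplitudes
sine_matrix <- function(amps, freq, srate, duration) {
  t <- seq(0, duration - 1 / srate, by = 1 / srate)
  outer(amps, sin(2 * pi * freq * t))
}

sine_recording <- function(amps, freq, srate = 1000, duration = 2) {
  continuous_recording(sine_matrix(amps, freq, srate, duration), srate)
}

# small epoched recording with deterministic content
toy_epochs <- function(n_ch = 3, n_tr = 4, n_t = 200, srate = 200, seed = 42) {
  set.seed(seed)
  data <- array(rnorm(n_ch * n_tr * n_t), dim = c(n_ch, n_tr, n_t))
  epoched_recording(data, srate, times = (seq_len(n_t) - 1 - 40) / srate)
}

# scaled-down simulated study: fewer trials than the 300-trial default so
# module tests run quickly; all other settings at the study defaults
small_dataset <- function(seed = 1, n_trials = 30, ...) {
  simulate_dataset(sim_config(n_trials = n_trials, ...), seed = seed)
}

sim_windows <- function() analysis_windows(0, 0.5, -0.2, 0, 9, 11)

# cache for expensive shared computations (filled lazily by tests)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
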