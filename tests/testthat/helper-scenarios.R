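# Shared fixtures: small seeded recordings used across test files.

quiet_spec <- function(duration = 120, seed = 42, ...) {
  scenario_spec("seated", duration = duration, seed = seed,
                breathing = list(cv = 0), cardiac_amplitude = 0,
                motion_amplitude = 0, noise_sd = 0, ...)
}

# constant-acceleration stream (gravity only) on the front/back time grids
const_stream <- function(t, g = c(0, 0, 1)) {
  data.frame(t_s = t, ax_g = rep(g[1], length(t)),
             ay_g = rep(g[2], length(t)), az_g = rep(g[3], length(t)))
}

front_times <- function(duration, fs = 100) (seq_len(duration * fs) - 0.5) / fs
back_times  <- function(duration, fs = 100) (0:(duration * fs)) / fs
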