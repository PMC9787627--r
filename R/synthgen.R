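# Seeded synthetic dual-IMU scenario generator with ground truth.
#
# Emulates the chest-band geometry: a front (chest) accelerometer sees
# gravity + breathing modulation + cardiac micro-artifact + body motion +
# sensor noise; the back accelerometer sees the same gravity and (almost) the
# same body motion but no breathing and no cardiac component. Both streams
# are pre-filtered at 21 Hz (the IMU's integrated low-pass) and clipped to
# the +/-2 g measurement range.

#' Breathing acceleration kernel for one respiratory cycle
#'
#' Bipolar kernel with independent inhalation and exhalation durations,
#' shaped like the measured differential chest signal. Inhalation rises
#' from 0 to `+amplitude` over `TI` seconds (`sin(pi*u/(2*TI))`, brisk
#' onset, plateauing toward the peak at end-inspiration). Exhalation is a
#' fast elastic recoil: over the first fifth of `TE` the signal plunges
#' from `+amplitude` through baseline to an undershoot of
#' `-0.5*amplitude` (the chest decelerating inward), relaxes smoothly back
#' to 0 by `0.45*TE`, and stays at baseline for the remainder of the phase
#' (the end-expiratory pause). Zero outside the cycle and continuous at
#' all phase boundaries, so consecutive non-overlapping cycles concatenate
#' smoothly.
#'
#' The bipolar shape is essential: the chest experiences positive
#' acceleration while expanding and negative acceleration while
#' contracting, so the differential signal oscillates about zero with its
#' steep plunge exactly at exhalation onset. Those onset-locked transitions
#' are what the dispersion detector keys on (+1 runs on the inspiratory
#' rise, -1 runs on the expiratory plunge), pinning detected event times to
#' the true phase onsets. (The kernel is deliberately not time-reversal
#' symmetric for `TI = TE`: expiration at rest is passive recoil, faster
#' than active inspiration.)
#'
#' @param t Numeric vector of times, seconds.
#' @param t_start Cycle start (inhalation onset), seconds.
#' @param TI,TE Inhalation / exhalation durations, seconds, both `> 0`.
#' @param amplitude Peak chest acceleration modulation, g-units, `>= 0`.
#' @return Numeric vector of accelerations (g) the same length as `t`.
#' @export
breathing_waveform <- function(t, t_start, TI, TE, amplitude) {
  stopifnot(TI > 0, TE > 0, amplitude >= 0)
  beta <- 0.5   # undershoot depth, fraction of amplitude
  rho <- 0.2    # recoil (plunge) fraction of the expiratory phase
  eta <- 0.45   # end of the undershoot recovery, fraction of TE
  out <- numeric(length(t))
  u <- t - t_start
  inh <- u >= 0 & u < TI
  out[inh] <- amplitude * sin(pi * u[inh] / (2 * TI))
  v <- u - TI
  rec <- v >= 0 & v < rho * TE
  out[rec] <- amplitude *
    ((1 + beta) / 2 * (1 + cos(pi * v[rec] / (rho * TE))) - beta)
  rel <- v >= rho * TE & v < eta * TE
  out[rel] <- -beta * amplitude *
    (1 + cos(pi * (v[rel] - rho * TE) / ((eta - rho) * TE))) / 2
  # [eta*TE, TE): end-expiratory pause, exactly 0
  out
}

#' Generate a table of breath cycles
#'
#' Draws back-to-back respiratory cycles covering `duration` seconds, with
#' lognormal cycle-to-cycle variability around the nominal inhalation and
#' exhalation durations. With `cv = 0` the rhythm is perfectly regular.
#'
#' @param duration Recording length to cover, seconds.
#' @param ti_mean,te_mean Nominal inhalation / exhalation durations, seconds.
#' @param amplitude Nominal peak acceleration modulation, g.
#' @param cv Coefficient of variation of TI, TE and amplitude across cycles.
#' @param t_start Onset of the first cycle, seconds.
#' @return A data.frame with columns `t_start`, `TI`, `TE`, `amplitude`,
#'   cycles ordered and non-overlapping.
#' @export
breath_cycles <- function(duration, ti_mean = 1.5, te_mean = 2.0,
                          amplitude = 0.02, cv = 0.1, t_start = 0) {
  stopifnot(duration > 0, ti_mean > 0, te_mean > 0, amplitude >= 0, cv >= 0)
  sdl <- sqrt(log(1 + cv^2))     # lognormal sdlog for a given CV
  t0 <- t_start
  rows <- list()
  while (t0 < duration) {
    ti <- ti_mean * exp(stats::rnorm(1, -sdl^2 / 2, sdl))
    te <- te_mean * exp(stats::rnorm(1, -sdl^2 / 2, sdl))
    am <- amplitude * exp(stats::rnorm(1, -sdl^2 / 2, sdl))
    rows[[length(rows) + 1L]] <- c(t0, ti, te, am)
    t0 <- t0 + ti + te
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t_start", "TI", "TE", "amplitude")
  out
}

#' Gait acceleration model
#'
#' Sum of the first three harmonics of the step frequency (relative
#' amplitudes 1, 0.4, 0.25 on the body axis, scaled by 0.3 / 0.5 on the
#' lateral / antero-posterior axes), the standard low-order harmonic
#' decomposition of trunk acceleration during walking.
#'
#' @param t Numeric vector of times, seconds.
#' @param motion_amplitude Fundamental amplitude on the body axis, g.
#' @param step_freq Step frequency, Hz (about 1.8 Hz at 1 m/s).
#' @param phases Length-3 numeric, harmonic phase offsets in radians.
#' @return An `length(t) x 3` matrix of accelerations (g), columns x, y, z.
#' @export
walking_motion <- function(t, motion_amplitude, step_freq = 1.8,
                           phases = c(0, 0, 0)) {
  stopifnot(motion_amplitude >= 0, step_freq > 0, length(phases) == 3)
  if (motion_amplitude == 0) return(matrix(0, length(t), 3))
  h <- function(w) w[1] * sin(2 * pi * step_freq * t + phases[1]) +
                   w[2] * sin(2 * pi * 2 * step_freq * t + phases[2]) +
                   w[3] * sin(2 * pi * 3 * step_freq * t + phases[3])
  base <- c(1, 0.4, 0.25)
  motion_amplitude * cbind(h(base), 0.3 * h(base), 0.5 * h(base))
}

#' Specify a simulation scenario
#'
#' Captures everything the generator needs: posture condition, recording
#' length, sampling rate, breathing cycle table (or the parameters to draw
#' one), artifact amplitudes and the random seed. Identical specs reproduce
#' identical recordings bit-for-bit.
#'
#' Default amplitudes are typical for a torso-worn MEMS accelerometer:
#' ~20 mg breathing modulation, 3 mg cardiac artifact at 1.2 Hz, 3 mg RMS
#' sensor noise, body sway of 5 mg (seated) / 10 mg (standing) and a 0.3 g
#' gait fundamental at 1.8 Hz (walking), of which a `motion_mismatch`
#' fraction is not common to the two sensors.
#'
#' @param condition `"seated"`, `"standing"` or `"walking"`.
#' @param duration Recording length, seconds, `> 0`.
#' @param fs Per-sensor sampling rate, Hz, `> 0`.
#' @param breathing Either a cycle data.frame as from [breath_cycles()] or a
#'   named list of arguments passed to [breath_cycles()] (drawn under the
#'   scenario seed). `list(amplitude = 0)` gives an apnoeic record.
#' @param breathing_axis Axis carrying the breathing modulation, `"x"`,
#'   `"y"` or `"z"` (default `"z"`, the chest-normal device axis).
#' @param cardiac_amplitude,cardiac_freq Precordial artifact burst amplitude
#'   (g) and repetition rate (Hz).
#' @param motion_amplitude Body-motion amplitude, g; `NULL` picks the
#'   condition default (0.005 seated, 0.01 standing, 0.3 walking).
#' @param motion_mismatch Fraction in `[0, 1]` of the motion NOT common to
#'   the two sensors (applied as a `1 - motion_mismatch` gain on the back).
#' @param noise_sd Per-axis white sensor noise SD, g.
#' @param step_freq Gait step frequency, Hz (walking only).
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(condition = c("seated", "standing", "walking"),
                          duration = 300, fs = 100, breathing = list(),
                          breathing_axis = c("z", "y", "x"),
                          cardiac_amplitude = 0.003, cardiac_freq = 1.2,
                          motion_amplitude = NULL, motion_mismatch = 0.02,
                          noise_sd = 0.003, step_freq = 1.8, seed = 1L) {
  condition <- match.arg(condition)
  breathing_axis <- match.arg(breathing_axis)
  if (fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  stopifnot(duration > 0, motion_mismatch >= 0, motion_mismatch <= 1,
            cardiac_amplitude >= 0, noise_sd >= 0)
  if (is.null(motion_amplitude))
    motion_amplitude <- switch(condition, seated = 0.005, standing = 0.01,
                               walking = 0.3)
  structure(list(condition = condition, duration = duration, fs = fs,
                 breathing = breathing, breathing_axis = breathing_axis,
                 cardiac_amplitude = cardiac_amplitude,
                 cardiac_freq = cardiac_freq,
                 motion_amplitude = motion_amplitude,
                 motion_mismatch = motion_mismatch, noise_sd = noise_sd,
                 step_freq = step_freq, seed = as.integer(seed)),
            class = "scenario_spec")
}

# Evaluate the summed breathing waveform of a cycle table at times t.
.breathing_signal <- function(t, cycles) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(cycles)))
    out <- out + breathing_waveform(t, cycles$t_start[i], cycles$TI[i],
                                    cycles$TE[i], cycles$amplitude[i])
  out
}

# Cardiac micro-artifact: a ~10 Hz wiggle gated by a narrow Gaussian envelope
# repeating at cardiac_freq (a precordial thump train).
.cardiac_signal <- function(t, amplitude, freq) {
  if (amplitude == 0) return(numeric(length(t)))
  phase <- (t * freq) %% 1
  amplitude * exp(-((phase - 0.3) / 0.08)^2) * sin(2 * pi * 10 * t)
}

# Causal 21 Hz second-order Butterworth, the IMU's integrated low-pass.
.imu_prefilter <- function(x, fs) {
  bf <- signal::butter(2, min(21 / (fs / 2), 0.99), type = "low")
  as.numeric(signal::filter(bf, x))
}

#' Simulate a dual-IMU chest-band recording
#'
#' Generates the front (chest) and back (reference) accelerometer streams for
#' a [scenario_spec()], together with the ground truth needed for
#' parameter-recovery testing. The two sensors sample at the same rate `fs`
#' but offset by half a sample period: back samples at `k/fs` bracket each
#' front sample at `(k + 1/2)/fs`, reproducing the interleaved
#' back-front-back acquisition order in which consecutive triples share a
#' back sample.
#'
#' @param spec A [scenario_spec()].
#' @param Tw Window length used to tabulate per-window ground truth, seconds.
#' @return A list of class `dual_imu_recording`:
#'   * `front`, `back`: data.frames `t_s`, `ax_g`, `ay_g`, `az_g`;
#'   * `truth`: list with `cycles` (the realised cycle table) and `windows`
#'     (per-window true breath count and mean TI/TE, see
#'     [ground_truth_windows()]);
#'   * `spec`: the input spec.
#' @export
simulate_dual_imu <- function(spec, Tw = 30) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  fs <- spec$fs
  n_front <- floor(spec$duration * fs)
  t_back  <- (0:n_front) / fs                 # n_front + 1 samples
  t_front <- (seq_len(n_front) - 0.5) / fs    # bracketed by t_back

  cycles <- if (is.data.frame(spec$breathing)) spec$breathing
            else do.call(breath_cycles, c(list(duration = spec$duration),
                                          spec$breathing))
  stopifnot(all(cycles$TI > 0), all(cycles$TE > 0), all(cycles$amplitude >= 0),
            !is.unsorted(cycles$t_start))

  # Motion common to both sensors, built on the combined half-step grid so
  # the band-limited sway component is a single continuous process.
  t_all <- sort(c(t_back, t_front))
  idx_back  <- match(t_back, t_all)
  idx_front <- match(t_front, t_all)
  motion <- matrix(0, length(t_all), 3)
  if (spec$motion_amplitude > 0) {
    if (spec$condition == "walking") {
      phases <- stats::runif(3, 0, 2 * pi)
      motion <- walking_motion(t_all, spec$motion_amplitude, spec$step_freq,
                               phases)
      sway_amp <- 0.1 * spec$motion_amplitude
    } else {
      sway_amp <- spec$motion_amplitude
    }
    # band-limited (< 2 Hz) postural sway on all three axes
    bf <- signal::butter(2, 2 / (length(t_all) / spec$duration / 2), "low")
    sway <- sapply(1:3, function(i) {
      w <- as.numeric(signal::filter(bf, stats::rnorm(length(t_all))))
      s <- stats::sd(w)
      if (s > 0) w / s * sway_amp else w
    })
    motion <- motion + sway
  }

  # The quasi-static gravity projection is placed on the breathing axis, so
  # the magnitude difference is first-order sensitive to the modulation
  # (|g + b| = g + b for b parallel to g); a gravity vector orthogonal to
  # the breathing axis would hide the modulation at second order.
  axis_i <- match(spec$breathing_axis, c("x", "y", "z"))
  gravity <- c(0, 0, 0); gravity[axis_i] <- 1

  breath_f <- .breathing_signal(t_front, cycles)
  card_f <- .cardiac_signal(t_front, spec$cardiac_amplitude, spec$cardiac_freq)

  make_stream <- function(t, idx, gain, breath, cardiac) {
    a <- matrix(rep(gravity, each = length(t)), ncol = 3) +
      gain * motion[idx, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(t), sd = spec$noise_sd), ncol = 3)
    a[, axis_i] <- a[, axis_i] + breath + cardiac
    a <- apply(a, 2, .imu_prefilter, fs = fs)
    a <- pmin(pmax(a, -2), 2)                 # +/-2 g range clipping
    data.frame(t_s = t, ax_g = a[, 1], ay_g = a[, 2], az_g = a[, 3])
  }

  front <- make_stream(t_front, idx_front, 1, breath_f, card_f)
  back  <- make_stream(t_back, idx_back, 1 - spec$motion_mismatch, 0, 0)

  truth <- list(cycles = cycles,
                windows = ground_truth_windows(cycles, spec$duration, Tw))
  if (spec$duration < Tw)
    attr(truth, "short_recording") <- TRUE
  structure(list(front = front, back = back, truth = truth, spec = spec),
            class = "dual_imu_recording")
}

#' Per-window ground truth from a cycle table
#'
#' A breath is attributed to the half-open window `[k*Tw, (k+1)*Tw)` that
#' contains its exhalation onset (`t_start + TI`), the instant the pipeline's
#' debounced exhalation detector targets.
#'
#' @param cycles Cycle data.frame (`t_start`, `TI`, `TE`, ...).
#' @param duration Recording length, seconds.
#' @param Tw Window length, seconds.
#' @return data.frame `window_start`, `n_breaths`, `TI_mean`, `TE_mean`
#'   (means are `NA` for windows without breaths).
#' @export
ground_truth_windows <- function(cycles, duration, Tw = 30) {
  stopifnot(Tw > 0)
  starts <- seq(0, by = Tw, length.out = max(1, floor(duration / Tw)))
  onset <- cycles$t_start + cycles$TI
  out <- lapply(starts, function(s) {
    in_w <- onset >= s & onset < s + Tw
    data.frame(window_start = s, n_breaths = sum(in_w),
               TI_mean = if (any(in_w)) mean(cycles$TI[in_w]) else NA_real_,
               TE_mean = if (any(in_w)) mean(cycles$TE[in_w]) else NA_real_)
  })
  do.call(rbind, out)
}
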