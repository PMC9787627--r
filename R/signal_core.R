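# Differential signal construction, causal low-pass filtering, and the
# streaming dispersion (smoothed z-score) peak detector.

#' Estimate the back-sensor reading at a front sample time
#'
#' The two IMUs are read in the interleaved order back, front, back; the
#' back reading synchronous with the front sample is estimated as the
#' component-wise mean of the two bracketing back samples. For a
#' component-wise linear signal the estimate is exact.
#'
#' @param back_prev,back_next Numeric length-3 vectors (g), the bracketing
#'   back samples.
#' @return Numeric length-3 vector, the interpolated back reading.
#' @export
estimate_back_at_front <- function(back_prev, back_next) {
  stopifnot(length(back_prev) == 3, length(back_next) == 3)
  (back_prev + back_next) / 2
}

#' Euclidean magnitude of an acceleration vector
#'
#' @param v Numeric length-3 vector, or an `n x 3` matrix of row vectors (g).
#' @return The Euclidean norm(s), g.
#' @export
vec_magnitude <- function(v) {
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

#' Build the differential acceleration signal
#'
#' For every front sample bracketed by two back samples, computes
#' `da = |a_front| - |a_back_est|`, where the back estimate is the mean of
#' the bracketing back samples. Body motion common to both sensors cancels
#' in this difference; the breathing modulation, present only on the chest,
#' survives. Front samples at the stream edges without both bracketing back
#' samples are dropped and counted.
#'
#' @param front,back data.frames with columns `t_s`, `ax_g`, `ay_g`, `az_g`,
#'   timestamps strictly increasing within each stream.
#' @return An object of class `diff_signal`: list with `t` (s), `da` (g),
#'   `fs` (Hz, median front rate) and `n_dropped` (front samples without
#'   brackets).
#' @export
build_diff_signal <- function(front, back) {
  need <- c("t_s", "ax_g", "ay_g", "az_g")
  stopifnot(all(need %in% names(front)), all(need %in% names(back)),
            !is.unsorted(front$t_s, strictly = TRUE),
            !is.unsorted(back$t_s, strictly = TRUE))
  tb <- back$t_s
  # index of the last back sample at or before each front sample
  i_prev <- findInterval(front$t_s, tb)
  ok <- i_prev >= 1 & i_prev < length(tb)
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no front sample is bracketed by back samples",
                     call. = FALSE)
  fa <- as.matrix(front[ok, c("ax_g", "ay_g", "az_g")])
  bp <- as.matrix(back[i_prev[ok], c("ax_g", "ay_g", "az_g")])
  bn <- as.matrix(back[i_prev[ok] + 1L, c("ax_g", "ay_g", "az_g")])
  da <- unname(vec_magnitude(fa) - vec_magnitude((bp + bn) / 2))
  t <- front$t_s[ok]
  fs <- 1 / stats::median(diff(t))
  structure(list(t = t, da = da, fs = fs, n_dropped = n_dropped),
            class = "diff_signal")
}

#' Causal Butterworth low-pass filter
#'
#' Applies a causal (streaming-capable) Butterworth low-pass with unit DC
#' gain, the real-time filter that isolates the 0.2-0.6 Hz respiratory band
#' from cardiac and residual motion components.
#'
#' @param x A `diff_signal` or a numeric vector.
#' @param fc Cutoff frequency, Hz; must satisfy `0 < fc < fs/2`.
#' @param order Filter order, `>= 1` (default 1, the lightest IIR a
#'   firmware implementation would use; it also preserves the expiratory
#'   transition that the peak detector keys on at brisk breathing rates).
#' @param fs Sampling rate, Hz; taken from `x` when it is a `diff_signal`.
#' @return Same shape as `x`: a `diff_signal` with filtered `da`, or a
#'   numeric vector.
#' @export
lowpass_filter <- function(x, fc = 0.6, order = 1L, fs = NULL) {
  if (inherits(x, "diff_signal")) {
    x$da <- lowpass_filter(x$da, fc = fc, order = order, fs = x$fs)
    return(x)
  }
  stopifnot(order >= 1, !is.null(fs))
  if (fc <= 0 || fc >= fs / 2)
    stop("cutoff must lie in (0, fs/2), got fc = ", fc, " at fs = ", fs,
         call. = FALSE)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  as.numeric(signal::filter(bf, x))
}

#' Streaming dispersion (smoothed z-score) peak labels
#'
#' Labels each sample +1, 0 or -1 by how far it deviates from the moving
#' mean of the last `lag` points of an influence-weighted filtered history:
#' a new point more than `threshold` moving standard deviations above
#' (below) the moving mean is labelled +1 (-1) and enters the history as
#' `influence * x + (1 - influence) * previous`, damping the statistics
#' against the peak itself; other points are labelled 0 and enter unchanged.
#' The first `lag` samples seed the window with raw values and are labelled
#' 0. The moving SD is the population form (divide by `lag`). On the
#' filtered differential signal, +1 runs mark inhalation (chest rising) and
#' -1 runs mark exhalation.
#'
#' @param x A `diff_signal` or numeric vector, length `> lag`.
#' @param lag Moving-window length, samples, `>= 2`.
#' @param threshold Deviation threshold in SD multiples, `> 0`.
#' @param influence Weight in `[0, 1]` of labelled samples in the history.
#' @param min_sd Floor on the moving SD, g. Defaults to one LSB of a 16-bit
#'   +/-2 g accelerometer (`2^-14` g): deviations below the sensor's own
#'   resolution are quantisation residue, not signal, and without the floor
#'   the scale-invariant z-score would label them. With `min_sd = 0` a
#'   zero-SD window labels any nonzero deviation by its sign.
#' @return Integer vector of labels in `{-1, 0, +1}`, aligned to the input.
#' @export
dispersion_labels <- function(x, lag = 60L, threshold = 2.87,
                              influence = 0.58, min_sd = 2^-14) {
  if (inherits(x, "diff_signal")) x <- x$da
  lag <- as.integer(lag)
  stopifnot(lag >= 2, threshold > 0, influence >= 0, influence <= 1,
            min_sd >= 0)
  n <- length(x)
  if (n <= lag) stop("series must be longer than lag (", lag, " samples)",
                     call. = FALSE)
  labels <- integer(n)
  filt <- x                      # filtered history; first lag values raw
  # running window sums over the filtered history, O(1) per sample
  s1 <- sum(filt[1:lag])
  s2 <- sum(filt[1:lag]^2)
  for (i in (lag + 1L):n) {
    avg <- s1 / lag
    v <- s2 / lag - avg^2
    sdw <- max(sqrt(max(v, 0)), min_sd)  # population SD with resolution floor
    dev <- x[i] - avg
    exceeds <- if (sdw == 0) dev != 0 else abs(dev) > threshold * sdw
    if (exceeds) {
      labels[i] <- if (dev > 0) 1L else -1L
      filt[i] <- influence * x[i] + (1 - influence) * filt[i - 1L]
    } else {
      labels[i] <- 0L
      filt[i] <- x[i]
    }
    s1 <- s1 + filt[i] - filt[i - lag]
    s2 <- s2 + filt[i]^2 - filt[i - lag]^2
  }
  labels
}

#' Export the intermediate signal chain for debugging
#'
#' @param x A `diff_signal` (unfiltered).
#' @param config A [pipeline_config()].
#' @param path CSV file to write (`t_s,da_g,da_filt_g,label`).
#' @return The debug data.frame, invisibly.
#' @export
write_debug_csv <- function(x, config, path) {
  stopifnot(inherits(x, "diff_signal"), inherits(config, "pipeline_config"))
  filt <- lowpass_filter(x$da, fc = config$fc, order = config$filter_order,
                         fs = x$fs)
  lab <- dispersion_labels(filt, lag = config$lag,
                           threshold = config$threshold,
                           influence = config$influence)
  out <- data.frame(t_s = x$t, da_g = x$da, da_filt_g = filt, label = lab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
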