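# Pipeline configuration and firmware parameter presets.

# Firmware optimisation grid: cutoff (Hz), detector lag (samples), threshold
# (SD multiples), influence, minimum accepted-peak distance (ms, converted to
# seconds once at this boundary).
.preset_table <- data.frame(
  preset_id  = 0:5,
  fc         = c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6),
  lag        = c(56L, 52L, 56L, 56L, 58L, 60L),
  threshold  = c(2.95, 2.95, 2.90, 2.85, 2.85, 2.87),
  influence  = c(0.58, 0.58, 0.58, 0.58, 0.58, 0.58),
  t_min_peak = c(1100, 1100, 1100, 1000, 1000, 1000) / 1000
)

#' Build a pipeline configuration
#'
#' Collects every tunable of the processing chain: sampling rate, low-pass
#' cutoff and order, dispersion-detector parameters, exhalation debounce time,
#' observation window length and the physiological plausibility bounds applied
#' to candidate inhalation/exhalation durations.
#'
#' @param fs Sampling rate of each sensor, Hz.
#' @param fc Low-pass filter cutoff, Hz. Must satisfy `0 < fc < fs/2`.
#' @param filter_order Butterworth filter order (causal IIR), `>= 1`.
#'   Default 1: the gentle first-order roll-off keeps enough of the
#'   expiratory transition for the peak detector across the validated
#'   20-32 BrPM range, where a second-order filter smears brisk breaths
#'   below the detection threshold.
#' @param lag Detector moving-window length, samples, `>= 2`.
#' @param threshold Detector threshold in multiples of the moving SD, `> 0`.
#' @param influence Weight in `[0, 1]` given to labelled samples when updating
#'   the detector's filtered history.
#' @param t_min_peak Minimum time between accepted exhalation peaks, seconds
#'   (debounce against double-counted breaths).
#' @param Tw Observation window length, seconds.
#' @param ti_bounds,te_bounds Length-2 numeric, plausibility bounds in seconds
#'   for candidate inhalation / exhalation durations.
#' @param preset_id Integer 0-5 if the configuration came from a preset,
#'   otherwise `NA` ("custom").
#' @return An object of class `pipeline_config` (a named list).
#' @seealso [load_preset()]
#' @export
pipeline_config <- function(fs = 100, fc = 0.6, filter_order = 1L,
                            lag = 60L, threshold = 2.87, influence = 0.58,
                            t_min_peak = 1.0, Tw = 30,
                            ti_bounds = c(0.4, 8), te_bounds = c(0.4, 8),
                            preset_id = NA_integer_) {
  stopifnot(fs > 0, filter_order >= 1, lag >= 2, threshold > 0,
            influence >= 0, influence <= 1, t_min_peak > 0, Tw > 0,
            length(ti_bounds) == 2, length(te_bounds) == 2,
            ti_bounds[1] > 0, diff(ti_bounds) > 0,
            te_bounds[1] > 0, diff(te_bounds) > 0)
  if (fc <= 0 || fc >= fs / 2)
    stop("cutoff frequency must lie in (0, fs/2), got fc = ", fc,
         " with fs = ", fs, call. = FALSE)
  structure(list(fs = fs, fc = fc, filter_order = as.integer(filter_order),
                 lag = as.integer(lag), threshold = threshold,
                 influence = influence, t_min_peak = t_min_peak, Tw = Tw,
                 ti_bounds = as.numeric(ti_bounds),
                 te_bounds = as.numeric(te_bounds),
                 preset_id = as.integer(preset_id)),
            class = "pipeline_config")
}

#' Load a firmware parameter preset
#'
#' Returns one of the six parameter sets explored during firmware
#' optimisation. Set 0 is the starting set (0.5 Hz cutoff, lag 56, threshold
#' 2.95, influence 0.58, 1100 ms debounce); set 5 is the optimised set
#' (0.6 Hz, lag 60, threshold 2.87, influence 0.58, 1000 ms) and is the
#' package default.
#'
#' @param id Integer preset id, 0 to 5.
#' @param fs Sampling rate, Hz (the presets fix everything but `fs` and `Tw`).
#' @param Tw Window length, seconds.
#' @return A [pipeline_config()] object.
#' @export
load_preset <- function(id, fs = 100, Tw = 30) {
  if (length(id) != 1 || is.na(id) || id != as.integer(id) ||
      !(id %in% .preset_table$preset_id))
    stop("unknown preset id: ", id, " (valid ids are 0-5)", call. = FALSE)
  row <- .preset_table[.preset_table$preset_id == id, ]
  pipeline_config(fs = fs, fc = row$fc, lag = row$lag,
                  threshold = row$threshold, influence = row$influence,
                  t_min_peak = row$t_min_peak, Tw = Tw,
                  preset_id = as.integer(id))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>",
      if (!is.na(x$preset_id)) sprintf(" preset %d", x$preset_id) else " custom",
      "\n", sep = "")
  cat(sprintf("  fs %g Hz | fc %g Hz (order %d) | lag %d, threshold %g, influence %g\n",
              x$fs, x$fc, x$filter_order, x$lag, x$threshold, x$influence))
  cat(sprintf("  debounce %g s | Tw %g s | TI bounds [%g, %g] s | TE bounds [%g, %g] s\n",
              x$t_min_peak, x$Tw, x$ti_bounds[1], x$ti_bounds[2],
              x$te_bounds[1], x$te_bounds[2]))
  invisible(x)
}

#' Subject profile for tidal-volume estimation
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm Body height in centimetres, `> 0`.
#' @param weight_kg Body weight in kilograms, `> 0` (recorded for reporting;
#'   the tidal-volume estimate uses ideal body weight, not actual weight).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(sex, height_cm, weight_kg) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(height_cm > 0, weight_kg > 0)
  structure(list(sex = sex, height_cm = height_cm, weight_kg = weight_kg),
            class = "subject_profile")
}

#' Serialize / parse a pipeline configuration
#'
#' Round-trips a [pipeline_config()] (and optionally a subject profile)
#' through YAML so that runs are reproducible from a config file.
#'
#' @param config A `pipeline_config`.
#' @param subject Optional `subject_profile`.
#' @param path File to write.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   list with elements `config` and (possibly `NULL`) `subject`.
#' @export
write_config <- function(config, path, subject = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(pipeline = unclass(config))
  if (!is.null(subject)) {
    stopifnot(inherits(subject, "subject_profile"))
    x$subject <- unclass(subject)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$pipeline)) stop("config file has no 'pipeline' section", call. = FALSE)
  p <- x$pipeline
  cfg <- pipeline_config(fs = p$fs, fc = p$fc, filter_order = p$filter_order,
                         lag = p$lag, threshold = p$threshold,
                         influence = p$influence, t_min_peak = p$t_min_peak,
                         Tw = p$Tw, ti_bounds = unlist(p$ti_bounds),
                         te_bounds = unlist(p$te_bounds),
                         preset_id = if (is.null(p$preset_id) ||
                                         is.na(p$preset_id)) NA_integer_
                                     else p$preset_id)
  subj <- NULL
  if (!is.null(x$subject))
    subj <- subject_profile(x$subject$sex, x$subject$height_cm,
                            x$subject$weight_kg)
  list(config = cfg, subject = subj)
}
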