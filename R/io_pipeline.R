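# CSV formats, the end-to-end pipeline composition, and the run log.

#' Read / write sensor streams and ground truth as CSV
#'
#' Sensor streams use columns `t_s,ax_g,ay_g,az_g` (seconds and g-units,
#' comma-separated, `.` decimal, header mandatory). `read_imu_csv` also
#' accepts a single-file dialect with an extra `sensor` column in
#' `{front, back}`, from which one sensor is selected. Ground-truth cycle
#' tables use `t_start_s,TI_s,TE_s,amplitude_g`. Unparseable rows are
#' dropped with their count attached as attribute `n_skipped`.
#'
#' @param x Stream data.frame (`t_s`, `ax_g`, `ay_g`, `az_g`) or cycle
#'   data.frame (`t_start`, `TI`, `TE`, `amplitude`).
#' @param path CSV file path.
#' @param sensor For the single-file dialect: which sensor to extract.
#' @return Writers return `path` invisibly; readers return a data.frame.
#' @export
write_imu_csv <- function(x, path) {
  stopifnot(all(c("t_s", "ax_g", "ay_g", "az_g") %in% names(x)))
  utils::write.csv(x[, c("t_s", "ax_g", "ay_g", "az_g")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, sensor = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(x$sensor)) {
    if (is.null(sensor))
      stop("file has a 'sensor' column; pass sensor = \"front\" or \"back\"",
           call. = FALSE)
    x <- x[x$sensor == sensor, setdiff(names(x), "sensor"), drop = FALSE]
  }
  need <- c("t_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(x)))
    stop("expected columns ", paste(need, collapse = ","), " in ", path,
         call. = FALSE)
  for (nm in need) x[[nm]] <- suppressWarnings(as.numeric(x[[nm]]))
  ok <- stats::complete.cases(x[, need])
  out <- x[ok, need, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' @rdname write_imu_csv
#' @export
write_truth_csv <- function(x, path) {
  stopifnot(all(c("t_start", "TI", "TE", "amplitude") %in% names(x)))
  out <- data.frame(t_start_s = x$t_start, TI_s = x$TI, TE_s = x$TE,
                    amplitude_g = x$amplitude)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_truth_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start_s", "TI_s", "TE_s", "amplitude_g")
  stopifnot(all(need %in% names(x)))
  data.frame(t_start = x$t_start_s, TI = x$TI_s, TE = x$TE_s,
             amplitude = x$amplitude_g)
}

#' Run the full breathing pipeline on a dual-IMU recording
#'
#' Deterministic composition of the whole chain: differential signal,
#' causal low-pass filter, dispersion labels, run collapse, exhalation
#' debounce, TI/TE accumulation and window finalisation. Identical inputs
#' and configuration give identical output.
#'
#' @param front,back Sensor stream data.frames (`t_s`, `ax_g`, `ay_g`,
#'   `az_g`) or paths to their CSV files.
#' @param config A [pipeline_config()]; default is preset 5.
#' @param subject Optional [subject_profile()]; when given, tidal volume
#'   (7 mL/kg of ideal body weight) and flow rate are estimated.
#' @return list of class `pipeline_result`: `windows` (window-summary
#'   data.frame), `Vt_l` (tidal volume, litres, or `NA`), and `log` (run
#'   log: dropped-sample and skipped-row counts, undefined-window count,
#'   the configuration used).
#' @export
run_pipeline <- function(front, back, config = load_preset(5),
                         subject = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n_skipped <- 0L
  if (is.character(front)) {
    front <- read_imu_csv(front, sensor = "front")
    n_skipped <- n_skipped + attr(front, "n_skipped")
  }
  if (is.character(back)) {
    back <- read_imu_csv(back, sensor = "back")
    n_skipped <- n_skipped + attr(back, "n_skipped")
  }
  if (nrow(front) <= config$lag)
    stop("front stream shorter than detector lag (", config$lag,
         " samples)", call. = FALSE)

  Vt_l <- NA_real_
  if (!is.null(subject)) {
    stopifnot(inherits(subject, "subject_profile"))
    Vt_l <- tidal_volume(ideal_body_weight(subject$height_cm,
                                           subject$sex)) / 1000
  }

  ds <- build_diff_signal(front, back)
  filt <- lowpass_filter(ds, fc = config$fc, order = config$filter_order)
  labels <- dispersion_labels(filt, lag = config$lag,
                              threshold = config$threshold,
                              influence = config$influence)
  windows <- track_breaths(labels, filt$t, config, Vt = Vt_l)

  log <- list(n_dropped_front = ds$n_dropped,
              n_skipped_rows = n_skipped,
              n_undefined_windows = sum(is.na(windows$TI_med_s) |
                                          is.na(windows$TE_med_s)),
              n_windows = nrow(windows),
              config = unclass(config))
  structure(list(windows = windows, Vt_l = Vt_l, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$log$n_windows, "windows\n")
  print(x$windows, digits = 4)
  invisible(x)
}

#' Write window summaries / run log
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param path Output file (CSV for summaries, JSON for the log).
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  w <- result$windows
  out <- data.frame(window_start_s = w$window_start, NP = w$NP,
                    RR_brpm = w$RR_brpm, TI_med_s = w$TI_med_s,
                    TE_med_s = w$TE_med_s, IER = w$IER, V_lpm = w$V_lpm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
write_runlog_json <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  jsonlite::write_json(result$log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
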