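# From peak labels to debounced breath events, per-cycle TI/TE, and
# per-window breathing parameters (RR, TI_med, TE_med, IER, V).

#' Collapse label runs into breath events
#'
#' Each maximal run of identical nonzero labels becomes a single event at
#' the time of the run's first sample: +1 runs are inhalation onsets, -1
#' runs exhalation onsets (the firmware's "wait for the peak end" rule that
#' avoids multiple increments within one peak).
#'
#' @param labels Integer vector in `{-1, 0, +1}`.
#' @param t Numeric vector of sample times, seconds, aligned to `labels`.
#' @return data.frame with columns `t` (s) and `kind`
#'   (`"inhalation"`/`"exhalation"`), time-ordered; zero rows if no peaks.
#' @export
collapse_runs <- function(labels, t) {
  stopifnot(length(labels) == length(t), all(labels %in% c(-1L, 0L, 1L)))
  empty <- data.frame(t = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (length(labels) == 0) return(empty)
  r <- rle(labels)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values != 0L
  if (!any(keep)) return(empty)
  data.frame(t = t[starts[keep]],
             kind = ifelse(r$values[keep] > 0, "inhalation", "exhalation"),
             stringsAsFactors = FALSE)
}

#' Debounce exhalation events
#'
#' An exhalation event is accepted (counts as a breath) only if it occurs
#' more than `t_min` seconds after the previously accepted exhalation; the
#' first exhalation is always accepted and discarded events do not move the
#' reference time. This suppresses double peaks that a single breath can
#' produce under body motion. Inhalation events pass through untouched.
#'
#' @param events Event data.frame from [collapse_runs()], time-ordered.
#' @param t_min Minimum accepted-peak spacing, seconds.
#' @return list with `events` (inhalations plus accepted exhalations,
#'   time-ordered) and `NP` (number of accepted exhalations).
#' @export
debounce_exhalations <- function(events, t_min) {
  stopifnot(t_min > 0, !is.unsorted(events$t))
  keep <- rep(TRUE, nrow(events))
  last_acc <- -Inf
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] != "exhalation") next
    if (events$t[i] - last_acc > t_min) {
      last_acc <- events$t[i]
    } else {
      keep[i] <- FALSE
    }
  }
  kept <- events[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(events = kept, NP = sum(kept$kind == "exhalation"))
}

#' Fresh breath-tracker state
#'
#' The running variables of the firmware loop: last exhalation time `t1`,
#' last inhalation time `t2`, their previous values, the accepted-peak
#' counter `NP`, and the TI/TE accumulators for the current window.
#'
#' @param start_time Window start, seconds.
#' @return list of class `breath_tracker_state`.
#' @export
new_tracker_state <- function(start_time = 0) {
  structure(list(t1 = NA_real_, t2 = NA_real_,
                 t1_prev = NA_real_, t2_prev = NA_real_,
                 peak_time_prev = -Inf, NP = 0L,
                 TI_sum = 0, TI_count = 0L, TE_sum = 0, TE_count = 0L,
                 n_rejected = 0L, last_event_t = -Inf,
                 start_time = start_time),
            class = "breath_tracker_state")
}

#' Update cycle times with one breath event
#'
#' On an accepted exhalation at `t1` preceded by a newer inhalation `t2`,
#' the candidate inhalation duration is `TI = t1 - t2`; on an inhalation at
#' `t2` following an exhalation `t1`, the candidate exhalation duration is
#' `TE = t2 - t1`. Candidates are accumulated only when inside the
#' physiological plausibility bounds; `NP` increments on every accepted
#' exhalation. Events must arrive in time order; out-of-order events are
#' rejected and counted.
#'
#' @param state A [new_tracker_state()].
#' @param event_t Event time, seconds.
#' @param kind `"inhalation"` or `"exhalation"` (exhalations are assumed
#'   already debounced, see [debounce_exhalations()]).
#' @param ti_bounds,te_bounds Length-2 plausibility bounds, seconds.
#' @return The updated state.
#' @export
update_cycle_times <- function(state, event_t, kind,
                               ti_bounds = c(0.4, 8), te_bounds = c(0.4, 8)) {
  stopifnot(inherits(state, "breath_tracker_state"),
            kind %in% c("inhalation", "exhalation"))
  if (event_t < state$last_event_t) {
    state$n_rejected <- state$n_rejected + 1L
    return(state)
  }
  state$last_event_t <- event_t
  if (kind == "exhalation") {
    prev_exh <- if (is.na(state$t1)) -Inf else state$t1
    if (!is.na(state$t2) && state$t2 > prev_exh) {
      ti <- event_t - state$t2
      if (ti >= ti_bounds[1] && ti <= ti_bounds[2]) {
        state$TI_sum <- state$TI_sum + ti
        state$TI_count <- state$TI_count + 1L
      }
    }
    state$t1_prev <- state$t1
    state$t1 <- event_t
    state$peak_time_prev <- event_t
    state$NP <- state$NP + 1L
  } else {
    prev_inh <- if (is.na(state$t2)) -Inf else state$t2
    if (!is.na(state$t1) && state$t1 > prev_inh) {
      te <- event_t - state$t1
      if (te >= te_bounds[1] && te <= te_bounds[2]) {
        state$TE_sum <- state$TE_sum + te
        state$TE_count <- state$TE_count + 1L
      }
    }
    state$t2_prev <- state$t2
    state$t2 <- event_t
  }
  state
}

#' Close an observation window and compute its breathing parameters
#'
#' Computes `RR = NP * 60 / Tw` (breaths per minute), the mean inhalation
#' and exhalation durations `TI_med`/`TE_med`, their ratio `IER`, and the
#' flow rate `V = Vt * 60 / TI_med` (litres per minute for `Vt` in litres).
#' Quantities whose accumulators are empty are `NA`; `RR = 0` for an empty
#' window is meaningful, not missing. A fresh state with `start_time`
#' advanced by `Tw` is returned alongside.
#'
#' @param state A `breath_tracker_state` at the end of its window.
#' @param config A [pipeline_config()] (supplies `Tw`).
#' @param Vt Tidal volume in litres (`NA` to skip flow-rate estimation).
#' @return list with `summary` (one-row data.frame: `window_start`, `NP`,
#'   `RR_brpm`, `TI_med_s`, `TE_med_s`, `IER`, `V_lpm`) and `state` (reset).
#' @export
finalize_window <- function(state, config, Vt = NA_real_) {
  stopifnot(inherits(state, "breath_tracker_state"),
            inherits(config, "pipeline_config"))
  Tw <- config$Tw
  ti_med <- if (state$TI_count > 0) state$TI_sum / state$TI_count else NA_real_
  te_med <- if (state$TE_count > 0) state$TE_sum / state$TE_count else NA_real_
  ier <- if (!is.na(ti_med) && !is.na(te_med)) ti_med / te_med else NA_real_
  v <- if (!is.na(Vt) && !is.na(ti_med)) Vt * 60 / ti_med else NA_real_
  summary <- data.frame(window_start = state$start_time, NP = state$NP,
                        RR_brpm = state$NP * 60 / Tw,
                        TI_med_s = ti_med, TE_med_s = te_med,
                        IER = ier, V_lpm = v)
  list(summary = summary, state = new_tracker_state(state$start_time + Tw))
}

#' Track breaths over consecutive windows
#'
#' Runs the full lower half of the firmware loop on a label sequence:
#' collapse runs to events, then, per `Tw` window (state clears at each
#' window boundary, as the firmware does), debounce exhalations, accumulate
#' plausible TI/TE candidates, and close the window.
#'
#' @param labels Integer label vector from [dispersion_labels()].
#' @param t Sample times, seconds.
#' @param config A [pipeline_config()].
#' @param Vt Tidal volume, litres (`NA` to skip flow rate).
#' @return data.frame of window summaries, one row per elapsed window.
#' @export
track_breaths <- function(labels, t, config, Vt = NA_real_) {
  stopifnot(inherits(config, "pipeline_config"), length(labels) == length(t))
  events <- collapse_runs(labels, t)
  dt <- stats::median(diff(t))
  n_win <- floor((t[length(t)] + dt) / config$Tw + 1e-9)
  if (n_win < 1)
    stop("recording shorter than one observation window (Tw = ",
         config$Tw, " s)", call. = FALSE)
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    s <- (k - 1) * config$Tw
    in_w <- events$t >= s & events$t < s + config$Tw
    deb <- debounce_exhalations(events[in_w, , drop = FALSE],
                                config$t_min_peak)
    state <- new_tracker_state(s)
    for (i in seq_len(nrow(deb$events)))
      state <- update_cycle_times(state, deb$events$t[i], deb$events$kind[i],
                                  config$ti_bounds, config$te_bounds)
    out[[k]] <- finalize_window(state, config, Vt)$summary
  }
  do.call(rbind, out)
}

#' Ideal body weight (Devine-style formula)
#'
#' `50 + 0.91 * (height - 152.4)` kg for men and `45.5 + 0.91 *
#' (height - 152.4)` kg for women. For heights so small that the formula
#' goes negative the result is clamped at 0 with a warning.
#'
#' @param height_cm Body height, centimetres, `> 0`.
#' @param sex `"male"` or `"female"`.
#' @return Ideal body weight, kg.
#' @export
ideal_body_weight <- function(height_cm, sex) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(height_cm > 0)
  base <- if (sex == "male") 50 else 45.5
  ibw <- base + 0.91 * (height_cm - 152.4)
  if (ibw < 0) {
    warning("ideal body weight formula negative at height ", height_cm,
            " cm; clamped to 0", call. = FALSE)
    ibw <- 0
  }
  ibw
}

#' Tidal volume from ideal body weight
#'
#' The standard 7 mL per kg of ideal body weight.
#'
#' @param ibw Ideal body weight, kg, `>= 0`.
#' @return Tidal volume, millilitres.
#' @export
tidal_volume <- function(ibw) {
  stopifnot(ibw >= 0)
  7 * ibw
}

#' Check front/back sensor alignment
#'
#' During a still, breath-held calibration interval the differential signal
#' of well-aligned sensors is proximal to zero; a residual mean magnitude
#' above `tol` indicates misalignment (e.g., a rotated back sensor).
#'
#' @param da Numeric vector, the differential signal over the calibration
#'   segment (g), or a `diff_signal`.
#' @param tol Tolerance on `mean(|da|)`, g.
#' @return `TRUE` if aligned (`mean(|da|) <= tol`), else `FALSE`.
#' @export
alignment_check <- function(da, tol) {
  if (inherits(da, "diff_signal")) da <- da$da
  stopifnot(tol > 0)
  if (length(da) == 0) stop("empty calibration segment", call. = FALSE)
  mean(abs(da)) <= tol
}
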