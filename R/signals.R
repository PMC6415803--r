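#' Calibrate a raw three-axis accelerometer trace against gravity
#'
#' Uses a quiescent (static) window of the trace, during which the sensor
#' reads gravity alone, to map raw ADC counts to g (1 g = 9.8 m/s^2). A
#' single static window cannot identify a full six-parameter affine map, so
#' two practical modes are supported:
#'
#' * `sensitivity` given (counts per g, per axis, e.g. from the datasheet):
#'   the per-axis zero-g offsets are estimated from the static window,
#'   assuming the sensor sits z-up so the static readings are (0, 0, 1) g.
#' * `zero_g_offset` given (counts, per axis): a shared sensitivity scale is
#'   estimated so the static-window mean magnitude equals 1 g.
#'
#' In both modes the calibrated static-window mean magnitude is 1 g.
#'
#' @param trace data.frame with `t`, `ax`, `ay`, `az` in raw counts.
#' @param static_window `c(t0, t1)` seconds delimiting the quiescent
#'   segment; must contain at least 500 samples.
#' @param sensitivity Per-axis counts per g (length 1 or 3), or `NULL`.
#' @param zero_g_offset Per-axis zero-g counts (length 3), or `NULL`.
#' @param max_static_sd Maximum tolerated per-axis SD within the static
#'   window, in g (default 0.5); larger variance means the window was not
#'   static and calibration fails.
#' @return data.frame of class `accel_g` with `t`, `ax`, `ay`, `az` in g and
#'   attribute `calib` (list `offset`, `scale`).
#' @export
calibrate_accel <- function(trace, static_window, sensitivity = NULL,
                            zero_g_offset = NULL, max_static_sd = 0.5) {
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(trace)))
  if (length(static_window) != 2)
    stop("static_window must be c(t0, t1)", call. = FALSE)
  w <- trace$t >= static_window[1] & trace$t <= static_window[2]
  if (sum(w) < 500)
    stop("static window holds fewer than 500 samples", call. = FALSE)
  mu <- c(mean(trace$ax[w]), mean(trace$ay[w]), mean(trace$az[w]))
  sdv <- c(stats::sd(trace$ax[w]), stats::sd(trace$ay[w]),
           stats::sd(trace$az[w]))
  if (!is.null(sensitivity)) {
    scale <- rep_len(sensitivity, 3)
    offset <- mu - c(0, 0, 1) * scale        # static assumed z-up
  } else if (!is.null(zero_g_offset)) {
    offset <- rep_len(zero_g_offset, 3)
    scale <- rep(sqrt(sum((mu - offset)^2)), 3)  # |static| = 1 g
  } else {
    stop("provide either 'sensitivity' or 'zero_g_offset'", call. = FALSE)
  }
  if (any(sdv / scale > max_static_sd))
    stop("static window variance too high for calibration", call. = FALSE)
  out <- data.frame(t = trace$t,
                    ax = (trace$ax - offset[1]) / scale[1],
                    ay = (trace$ay - offset[2]) / scale[2],
                    az = (trace$az - offset[3]) / scale[3])
  attr(out, "calib") <- list(offset = offset, scale = scale)
  class(out) <- c("accel_g", "data.frame")
  out
}

#' Total acceleration magnitude
#'
#' The square root of the sum of squares of the three calibrated axes,
#' `sqrt(ax^2 + ay^2 + az^2)`, in g. A static sensor reads 1 g (gravity).
#'
#' @param trace Calibrated trace (`accel_g` or any data.frame with `ax`,
#'   `ay`, `az` in g).
#' @return data.frame with `t` and `mag` (g).
#' @export
accel_magnitude <- function(trace) {
  data.frame(t = trace$t,
             mag = sqrt(trace$ax^2 + trace$ay^2 + trace$az^2))
}

#' Detect contacts (hits) in a total-acceleration series
#'
#' A hit is a local maximum of the total acceleration exceeding
#' `threshold_g`; candidate peaks are scanned in time order and accepted
#' only when at least `min_separation_ms` after the previously accepted
#' hit, so one physical contact's ring-down is not double-counted. The
#' threshold applies to the full magnitude including the static 1 g gravity
#' component; set `subtract_gravity = TRUE` to threshold `|mag - 1|`
#' instead.
#'
#' @param mag data.frame with `t` (s) and `mag` (g), e.g. from
#'   [accel_magnitude()].
#' @param threshold_g Hit threshold in g (default 3).
#' @param min_separation_ms Minimum spacing between accepted hits (default
#'   50 ms, about one ring-down period of the 18.4 Hz support wire).
#' @param subtract_gravity Threshold the deviation from the 1 g baseline
#'   instead of the raw magnitude.
#' @return Numeric vector of hit times, s.
#' @export
detect_hits <- function(mag, threshold_g = 3, min_separation_ms = 50,
                        subtract_gravity = FALSE) {
  m <- if (subtract_gravity) abs(mag$mag - 1) else mag$mag
  n <- length(m)
  if (n < 3) return(numeric(0))
  peak <- which(m[2:(n - 1)] > m[1:(n - 2)] &
                m[2:(n - 1)] >= m[3:n] &
                m[2:(n - 1)] > threshold_g) + 1L
  if (length(peak) == 0) return(numeric(0))
  sep <- min_separation_ms / 1000
  keep <- numeric(0)
  last <- -Inf
  for (i in peak) {
    if (mag$t[i] - last >= sep) {
      keep <- c(keep, mag$t[i])
      last <- mag$t[i]
    }
  }
  keep
}

#' Extract events from an infrared beam-state series
#'
#' Debounces the binary series (state runs shorter than `debounce_ms` are
#' absorbed into the surrounding state) and labels the remaining
#' transitions. In stage 2 the beam monitors the nectar reservoir: a rise
#' (beam received, nectar gone) is an `EMPTIED` event and a fall (reservoir
#' refilled) a `REFILLED` event. In stage 1 the beam crosses the nectary
#' mouth, so any beam break is a `PROBE`.
#'
#' @param beam data.frame with `t` (s) and `state` (0/1) at the sensor
#'   sampling rate.
#' @param stage `"stage2"` (default) or `"stage1"`.
#' @param debounce_ms Debounce window, ms (default 20).
#' @param broken_state For stage 1: the state value meaning "beam broken"
#'   (default 1).
#' @return data.frame of class `beam_event_log` with `time` and `kind`
#'   (`EMPTIED`/`REFILLED` or `PROBE`), times non-decreasing.
#' @export
beam_events <- function(beam, stage = c("stage2", "stage1"),
                        debounce_ms = 20, broken_state = 1) {
  stage <- match.arg(stage)
  stopifnot(all(c("t", "state") %in% names(beam)))
  s <- as.integer(beam$state)
  n <- length(s)
  if (n == 0)
    return(structure(data.frame(time = numeric(0), kind = character(0)),
                     class = c("beam_event_log", "data.frame")))
  dt <- if (n > 1) stats::median(diff(beam$t)) else 1e-3
  min_run <- max(1L, ceiling(debounce_ms / 1000 / dt))
  r <- rle(s)
  # absorb sub-debounce runs into the preceding stable state
  if (length(r$lengths) > 1) {
    vals <- r$values; lens <- r$lengths
    stable_v <- vals[1]; out_v <- vals[1]; out_l <- lens[1]
    for (i in 2:length(vals)) {
      if (lens[i] < min_run) {
        out_l[length(out_l)] <- out_l[length(out_l)] + lens[i]
      } else if (vals[i] == out_v[length(out_v)]) {
        out_l[length(out_l)] <- out_l[length(out_l)] + lens[i]
      } else {
        out_v <- c(out_v, vals[i]); out_l <- c(out_l, lens[i])
      }
    }
    r <- list(values = out_v, lengths = out_l)
  }
  if (length(r$values) < 2)
    return(structure(data.frame(time = numeric(0), kind = character(0)),
                     class = c("beam_event_log", "data.frame")))
  trans_idx <- cumsum(r$lengths)[-length(r$lengths)] + 1L
  new_state <- r$values[-1]
  kind <- if (stage == "stage2") {
    ifelse(new_state == 1, "EMPTIED", "REFILLED")
  } else {
    ifelse(new_state == broken_state, "PROBE", NA_character_)
  }
  out <- data.frame(time = beam$t[trans_idx], kind = kind)
  out <- out[!is.na(out$kind), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("beam_event_log", "data.frame")
  out
}

#' Evaluate the stage-2 trial termination rules
#'
#' A trial ends when either the nectar has been emptied 25 times (the
#' refiller's capacity) or four minutes have passed since the last visit.
#' Returns the first satisfied condition and its time.
#'
#' @param events A `beam_event_log` (EMPTIED/REFILLED events).
#' @param visits A `visit_events` data.frame (or anything with `start` and
#'   `end` columns); may have zero rows.
#' @param clock Current trial clock, s.
#' @param max_empties Refiller capacity (default 25).
#' @param idle_timeout_s Idle rule, s (default 240).
#' @return List with `status` (`"ongoing"`, `"ENDED_25_REFILLS"` or
#'   `"ENDED_4MIN_IDLE"`) and `time` (`NA` while ongoing).
#' @export
check_termination <- function(events, visits, clock, max_empties = 25L,
                              idle_timeout_s = 240) {
  emp <- events$time[events$kind == "EMPTIED"]
  if (length(emp) >= max_empties) {
    t_cap <- sort(emp)[max_empties]
    if (t_cap <= clock)
      return(list(status = "ENDED_25_REFILLS", time = t_cap))
  }
  last_visit <- if (!is.null(visits) && nrow(visits) > 0) max(visits$end) else 0
  if (clock - last_visit >= idle_timeout_s)
    return(list(status = "ENDED_4MIN_IDLE", time = last_visit + idle_timeout_s))
  list(status = "ongoing", time = NA_real_)
}

#' Attribute hits to visit intervals
#'
#' Each hit time is assigned to the visit interval `[start, end)` containing
#' it; hits falling outside every visit are returned separately rather than
#' dropped.
#'
#' @param hit_times Numeric vector of hit times, s.
#' @param visits A `visit_events` data.frame.
#' @return List with `per_visit` (integer hit count per visit row) and
#'   `orphan_times` (hits outside all visits).
#' @export
assign_hits <- function(hit_times, visits) {
  n <- if (is.null(visits)) 0L else nrow(visits)
  per <- integer(n)
  orphan <- numeric(0)
  for (h in hit_times) {
    i <- if (n > 0) which(h >= visits$start & h < visits$end) else integer(0)
    if (length(i) >= 1) per[i[1]] <- per[i[1]] + 1L
    else orphan <- c(orphan, h)
  }
  list(per_visit = per, orphan_times = orphan)
}
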