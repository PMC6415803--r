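#' Visit model for instrumented-flower simulations
#'
#' Describes the visit process of a stage-2 trial: how many approaches the
#' moth makes, how long each lasts (log-normal; positive and right-skewed),
#' the probability that a visit reaches the nectar (emptying the reservoir),
#' and the distribution of gaps between visits. Gaps are truncated below the
#' idle-timeout so a planned visit sequence is not cut short by the
#' four-minute rule.
#'
#' @param n_visits Number of visits the moth attempts.
#' @param duration_meanlog,duration_sdlog Log-normal visit-duration
#'   parameters (defaults give a median of 8 s).
#' @param feed_prob Probability a visit empties the nectar reservoir.
#' @param gap_mean_s Mean inter-visit gap, s (exponential).
#' @param gap_min_s,gap_max_s Truncation of gaps, s. The minimum keeps
#'   distinct visits separated by several video frames; the maximum must stay
#'   below the 240 s idle timeout.
#' @return A `visit_model` list.
#' @export
visit_model <- function(n_visits = 6, duration_meanlog = log(8),
                        duration_sdlog = 0.35, feed_prob = 0.8,
                        gap_mean_s = 12, gap_min_s = 1, gap_max_s = 230) {
  stopifnot(n_visits >= 0, feed_prob >= 0, feed_prob <= 1, gap_max_s < 240,
            gap_min_s > 0, gap_min_s < gap_max_s)
  structure(list(n_visits = as.integer(n_visits),
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog, feed_prob = feed_prob,
                 gap_mean_s = gap_mean_s, gap_min_s = gap_min_s,
                 gap_max_s = gap_max_s),
            class = "visit_model")
}

#' Contact (hit) model for instrumented-flower simulations
#'
#' Describes the accelerometer channel: per-visit contact counts, transient
#' amplitude, the supporting wire's ring-down, and the noise floor. Each
#' contact is injected as a damped cosine `amp * exp(-dt/tau) * cos(2*pi*f*dt)`
#' along a random horizontal direction, so the total-acceleration peak sits at
#' the contact time. The default ring-down time constant (25 ms) keeps the
#' half-period rebound of the oscillation inside the hit detector's 50 ms
#' separation window. The noise floor (0.3 g RMS about the 1 g gravity
#' baseline) keeps the quiescent total acceleration far below the 3 g hit
#' threshold.
#'
#' @param hits_mean Mean contacts per visit (Poisson).
#' @param amp_range_g Uniform range of transient peak amplitudes in g; the
#'   lower end must exceed the 3 g detection threshold or the injected truth
#'   would be unrecoverable.
#' @param ringdown_hz Wire natural frequency (default 18.4 Hz).
#' @param ringdown_tau_s Ring-down decay constant, s.
#' @param noise_g_rms Total RMS of the three-axis noise, g.
#' @param min_sep_s Minimum spacing enforced between injected contacts, s.
#' @return A `hit_model` list.
#' @export
hit_model <- function(hits_mean = 8, amp_range_g = c(4, 8),
                      ringdown_hz = 18.4, ringdown_tau_s = 0.025,
                      noise_g_rms = 0.3, min_sep_s = 0.06) {
  if (amp_range_g[1] <= 3)
    stop("hit amplitude at or below the 3 g detection threshold: injected ",
         "contacts would be indistinguishable from the noise floor",
         call. = FALSE)
  stopifnot(hits_mean >= 0, noise_g_rms >= 0, min_sep_s > 0)
  structure(list(hits_mean = hits_mean, amp_range_g = amp_range_g,
                 ringdown_hz = ringdown_hz, ringdown_tau_s = ringdown_tau_s,
                 noise_g_rms = noise_g_rms, min_sep_s = min_sep_s),
            class = "hit_model")
}

#' Simulate one instrumented-flower trial (sensor bundle)
#'
#' Generates the three synchronized channels of a stage-2 trial on a common
#' clock starting at 0 s: a 1 kHz three-axis accelerometer trace in raw ADC
#' counts (with known calibration), a 1 kHz binary infrared-beam state
#' series, and a 5 fps moth trajectory from which video frames can be
#' rendered with [render_frames()]. The trial starts with a quiescent
#' pre-roll used as the calibration window, then runs the visit sequence;
#' it is truncated at the 25th nectar emptying (the refiller's capacity) and
#' otherwise ends by the 240 s idle rule. Ground truth (every visit
#' interval, contact time, emptying event, and the moth's position) is
#' retained in the `truth` element.
#'
#' @param visits A [visit_model()].
#' @param hits A [hit_model()].
#' @param seed Integer RNG seed.
#' @param fs Accelerometer/beam sampling rate, Hz (default 1000).
#' @param fps Video frame rate (default 5).
#' @param pre_roll_s Quiescent pre-roll, s (default 2; the calibration
#'   window).
#' @param refill_s Delay before the reservoir is refilled after emptying, s.
#' @param max_empties Refiller capacity (default 25).
#' @param idle_timeout_s Idle termination rule, s (default 240). The recorded
#'   channels stop `idle_tail_s` after the last event (an idle tail carries
#'   no information); the nominal termination time is reported in
#'   `truth$termination`.
#' @param idle_tail_s Recorded tail after the last event, s.
#' @param calib_offset,calib_sens Per-axis ADC zero-g offsets (counts) and
#'   sensitivities (counts per g) used to encode the raw trace.
#' @param glitch_rate Rate of 1-3 ms spurious beam flips, per s.
#' @return A `sensor_bundle`: list with `accel` (data.frame `t`, `ax`, `ay`,
#'   `az`; raw counts), `beam` (data.frame `t`, `state`; 1 = beam received,
#'   i.e. nectar absent), `calib` (offsets, sensitivities, static window),
#'   `fs`, `fps`, and `truth`.
#' @export
simulate_stage2 <- function(visits = visit_model(), hits = hit_model(),
                            seed = 1L, fs = 1000, fps = 5, pre_roll_s = 2,
                            refill_s = 2, max_empties = 25L,
                            idle_timeout_s = 240, idle_tail_s = 5,
                            calib_offset = c(506, 502, 512),
                            calib_sens = c(102, 103, 101),
                            glitch_rate = 0.01) {
  stopifnot(inherits(visits, "visit_model"), inherits(hits, "hit_model"))
  set.seed(as.integer(seed))

  # ---- visit timeline ------------------------------------------------------
  nv <- visits$n_visits
  gaps <- pmin(pmax(stats::rexp(max(nv, 1), 1 / visits$gap_mean_s),
                    visits$gap_min_s), visits$gap_max_s)
  durs <- stats::rlnorm(max(nv, 1), visits$duration_meanlog, visits$duration_sdlog)
  start <- pre_roll_s + cumsum(gaps) + c(0, cumsum(durs))[seq_len(max(nv, 1))]
  end <- start + durs
  fed <- stats::runif(max(nv, 1)) < visits$feed_prob
  if (nv == 0) { start <- end <- durs <- numeric(0); fed <- logical(0) }
  empty_time <- ifelse(fed, start + 0.6 * durs, NA_real_)

  # refiller capacity: truncate after the visit producing the 25th emptying
  n_emp <- cumsum(fed)
  if (nv > 0 && any(n_emp >= max_empties)) {
    last <- which(n_emp >= max_empties)[1]
    start <- start[seq_len(last)]; end <- end[seq_len(last)]
    durs <- durs[seq_len(last)]; fed <- fed[seq_len(last)]
    empty_time <- empty_time[seq_len(last)]
    termination <- list(status = "ENDED_25_REFILLS",
                        time = empty_time[last])
  } else {
    termination <- list(
      status = "ENDED_4MIN_IDLE",
      time = (if (nv > 0) max(end) else pre_roll_s) + idle_timeout_s)
  }
  t_end <- (if (length(end) > 0) max(c(end, empty_time + refill_s),
                                     na.rm = TRUE) else pre_roll_s) + idle_tail_s

  # ---- contacts ------------------------------------------------------------
  hit_times <- numeric(0); hit_visit <- integer(0); hit_amp <- numeric(0)
  for (i in seq_along(start)) {
    k <- stats::rpois(1, hits$hits_mean)
    # place k contacts in the visit with the minimum separation built in
    # (uniform gaps on the residual span), capping k at what the visit fits
    span <- max(end[i] - start[i] - 0.1, 0.01)
    k <- min(k, floor(span / hits$min_sep_s))
    if (k == 0) next
    slack <- span - k * hits$min_sep_s
    gaps <- if (k > 1) diff(c(0, sort(stats::runif(k - 1)), 1)) else 1
    tt <- start[i] + 0.05 + cumsum(gaps * slack) +
      (seq_len(k) - 1) * hits$min_sep_s
    hit_times <- c(hit_times, tt)
    hit_visit <- c(hit_visit, rep(i, length(tt)))
    hit_amp <- c(hit_amp, stats::runif(length(tt), hits$amp_range_g[1],
                                       hits$amp_range_g[2]))
  }

  # ---- accelerometer trace -------------------------------------------------
  n <- floor(t_end * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  sd_axis <- hits$noise_g_rms / sqrt(3)
  ax <- stats::rnorm(n, 0, sd_axis)
  ay <- stats::rnorm(n, 0, sd_axis)
  az <- 1 + stats::rnorm(n, 0, sd_axis)
  win <- ceiling(6 * hits$ringdown_tau_s * fs)
  for (j in seq_along(hit_times)) {
    i0 <- floor(hit_times[j] * fs) + 1L
    ii <- i0:min(i0 + win, n)
    dt <- t[ii] - hit_times[j]
    w <- hit_amp[j] * exp(-dt / hits$ringdown_tau_s) *
      cos(2 * pi * hits$ringdown_hz * dt)
    phi <- stats::runif(1, 0, 2 * pi)   # horizontal contact direction
    ax[ii] <- ax[ii] + w * cos(phi)
    ay[ii] <- ay[ii] + w * sin(phi)
  }
  accel <- data.frame(
    t = t,
    ax = round(ax * calib_sens[1] + calib_offset[1]),
    ay = round(ay * calib_sens[2] + calib_offset[2]),
    az = round(az * calib_sens[3] + calib_offset[3]))

  # ---- infrared beam -------------------------------------------------------
  state <- integer(n)                   # 0 = blocked (nectar present)
  for (i in seq_along(start)) {
    if (!fed[i]) next
    i1 <- floor(empty_time[i] * fs) + 1L
    i2 <- min(floor((empty_time[i] + refill_s) * fs) + 1L, n)
    state[i1:i2] <- 1L
  }
  n_glitch <- stats::rpois(1, glitch_rate * t_end)
  if (n_glitch > 0) {
    gt <- stats::runif(n_glitch, 0, t_end)
    for (g in gt) {
      i1 <- floor(g * fs) + 1L
      i2 <- min(i1 + sample(1:3, 1), n)
      state[i1:i2] <- 1L - state[i1:i2]
    }
  }
  beam <- data.frame(t = t, state = state)

  # ---- moth trajectory at frame times -------------------------------------
  ft <- seq(0, t_end, by = 1 / fps)
  inside <- vapply(ft, function(tk)
    any(tk >= start & tk < end), logical(1))
  xy <- matrix(NA_real_, length(ft), 2)
  pos <- c(0, 0)
  for (k in seq_along(ft)) {
    if (inside[k]) {
      pos <- 0.8 * pos + stats::rnorm(2, 0, 20)
      d <- sqrt(sum(pos^2))
      if (d > 115) pos <- pos * 115 / d
      xy[k, ] <- pos
    } else {
      pos <- c(0, 0)
    }
  }
  trajectory <- data.frame(t = ft, x_mm = xy[, 1], y_mm = xy[, 2],
                           present = inside)

  structure(list(
    accel = accel, beam = beam, fs = fs, fps = fps,
    calib = list(offset = calib_offset, sensitivity = calib_sens,
                 static_window = c(0, pre_roll_s)),
    truth = list(
      visits = data.frame(start = start, end = end, duration = durs,
                          emptied = fed, empty_time = empty_time),
      hit_times = hit_times, hit_visit = hit_visit, hit_amp = hit_amp,
      trajectory = trajectory, termination = termination, seed = seed),
    params = list(visits = visits, hits = hits, refill_s = refill_s,
                  max_empties = max_empties, idle_timeout_s = idle_timeout_s)),
    class = "sensor_bundle")
}

#' Arena / camera configuration for frame rendering
#'
#' @param width_px,height_px Frame size (default 640 x 480, webcam-like).
#' @param mm_per_pixel Image scale (default 0.8 mm/px).
#' @param flower_center_px Pixel coordinates `(x, y)` of the flower center
#'   (default: image center).
#' @param blob_diam_mm Apparent moth diameter, mm (default 24).
#' @param bg Background grey level in `[0, 1]`.
#' @param noise_sd Per-frame sensor noise SD (grey levels).
#' @param n_speckle Small distractor specks per frame, strictly smaller than
#'   the moth blob.
#' @return An `arena_config` list.
#' @export
arena_config <- function(width_px = 640, height_px = 480, mm_per_pixel = 0.8,
                         flower_center_px = c(width_px / 2, height_px / 2),
                         blob_diam_mm = 24, bg = 0.12, noise_sd = 0.006,
                         n_speckle = 2) {
  stopifnot(mm_per_pixel > 0, blob_diam_mm / mm_per_pixel >= 5)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 mm_per_pixel = mm_per_pixel,
                 flower_center_px = flower_center_px,
                 blob_diam_mm = blob_diam_mm, bg = bg, noise_sd = noise_sd,
                 n_speckle = as.integer(n_speckle)),
            class = "arena_config")
}

# paint an elliptical Gaussian blob into a local window of `img`
paint_blob <- function(img, cx, cy, sx, sy, peak) {
  h <- nrow(img); w <- ncol(img)
  x1 <- max(1L, floor(cx - 3 * sx)); x2 <- min(w, ceiling(cx + 3 * sx))
  y1 <- max(1L, floor(cy - 3 * sy)); y2 <- min(h, ceiling(cy + 3 * sy))
  if (x1 > x2 || y1 > y2) return(img)
  gx <- exp(-0.5 * ((x1:x2 - cx) / sx)^2)
  gy <- exp(-0.5 * ((y1:y2 - cy) / sy)^2)
  img[y1:y2, x1:x2] <- pmin(1, img[y1:y2, x1:x2] + peak * outer(gy, gx))
  img
}

#' Render video frames for a moth trajectory
#'
#' Produces a moth-free reference frame plus one 8-bit grayscale frame per
#' trajectory sample. Present moths are drawn as a bright elliptical blob at
#' the true position; each frame also receives sensor noise and a few small
#' distractor specks, strictly smaller than the blob, that the
#' largest-contour rule must ignore. If the blob center would leave the
#' image bounds the frame is marked absent in the returned truth.
#'
#' @param trajectory data.frame with `t`, `x_mm`, `y_mm`, `present` (e.g.
#'   `truth$trajectory` of a [simulate_stage2()] bundle); coordinates are mm
#'   relative to the flower center, y increasing down the image.
#' @param arena An [arena_config()].
#' @param seed Integer RNG seed.
#' @return A `frame_set`: list with `reference` (matrix, grey in `[0, 1]`),
#'   `frames` (list of matrices), `t`, `truth_px` (data.frame `t`, `x_px`,
#'   `y_px`, `present`; pixel coordinates are 1-based image columns/rows),
#'   and `arena`.
#' @export
render_frames <- function(trajectory, arena = arena_config(), seed = 1L) {
  stopifnot(all(c("t", "x_mm", "y_mm", "present") %in% names(trajectory)))
  set.seed(as.integer(seed))
  h <- arena$height_px; w <- arena$width_px
  # static scene: smooth illumination gradient + dark flower mark
  ref <- matrix(arena$bg, h, w)
  ref <- ref + outer(seq(-0.02, 0.02, length.out = h),
                     seq(-0.015, 0.015, length.out = w), "+")
  fc <- arena$flower_center_px
  ref <- paint_blob(ref, fc[1], fc[2], 8, 8, -0.06)
  sb <- arena$blob_diam_mm / arena$mm_per_pixel / 4   # blob sigma, px
  margin <- 2.5 * sb
  n <- nrow(trajectory)
  frames <- vector("list", n)
  tp <- data.frame(t = trajectory$t, x_px = NA_real_, y_px = NA_real_,
                   present = FALSE)
  for (k in seq_len(n)) {
    img <- ref + matrix(stats::rnorm(h * w, 0, arena$noise_sd), h, w)
    if (isTRUE(trajectory$present[k])) {
      cx <- fc[1] + trajectory$x_mm[k] / arena$mm_per_pixel
      cy <- fc[2] + trajectory$y_mm[k] / arena$mm_per_pixel
      if (cx >= 1 + margin && cx <= w - margin &&
          cy >= 1 + margin && cy <= h - margin) {
        img <- paint_blob(img, cx, cy, sx = 1.15 * sb, sy = 0.85 * sb,
                          peak = 0.75)
        tp$x_px[k] <- cx; tp$y_px[k] <- cy; tp$present[k] <- TRUE
      }
    }
    for (s in seq_len(arena$n_speckle)) {
      img <- paint_blob(img, stats::runif(1, 5, w - 5),
                        stats::runif(1, 5, h - 5), 0.8, 0.8, 0.4)
    }
    # paint_blob clamps its window at 1; only sub-zero noise needs fixing
    if (min(img) < 0) img[img < 0] <- 0
    frames[[k]] <- img
  }
  structure(list(reference = pmin(pmax(ref, 0), 1), frames = frames,
                 t = trajectory$t, truth_px = tp, arena = arena),
            class = "frame_set")
}
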