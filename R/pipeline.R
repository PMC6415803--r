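#' Analyse one stage-2 sensor bundle end to end
#'
#' Runs the full measurement chain on one trial: video tracking (reference
#' subtraction, largest-contour centroid), visit segmentation at the 125 mm
#' radius, accelerometer calibration against gravity, 3 g hit detection,
#' beam-event extraction, and the per-visit join (hits attributed to their
#' containing visit; a visit is "emptied" when an EMPTIED beam event falls
#' inside it).
#'
#' @param bundle A `sensor_bundle` from [simulate_stage2()].
#' @param frames A `frame_set` for the trial; when `NULL` the bundle's true
#'   trajectory is rendered first with [render_frames()] and `arena`.
#' @param arena [arena_config()] used when rendering.
#' @param radius_mm,gap_frames Passed to [segment_visits()].
#' @param frame_seed Seed for the rendering step.
#' @return List with `visits` (data.frame `start`, `end`, `duration`,
#'   `emptied`, `hits`), `orphan_hits`, `trajectory`, `events`,
#'   `termination`.
#' @export
analyze_bundle <- function(bundle, frames = NULL, arena = arena_config(),
                           radius_mm = 125, gap_frames = 1,
                           frame_seed = 1L) {
  stopifnot(inherits(bundle, "sensor_bundle"))
  if (is.null(frames))
    frames <- render_frames(bundle$truth$trajectory, arena, seed = frame_seed)
  traj <- track(frames)
  vis <- segment_visits(traj, radius_mm = radius_mm, gap_frames = gap_frames,
                        fps = bundle$fps)
  cal <- calibrate_accel(bundle$accel, bundle$calib$static_window,
                         sensitivity = bundle$calib$sensitivity)
  mag <- accel_magnitude(cal)
  hits <- detect_hits(mag)
  ah <- assign_hits(hits, vis)
  ev <- beam_events(bundle$beam, stage = "stage2")
  emp_t <- ev$time[ev$kind == "EMPTIED"]
  emptied <- vapply(seq_len(nrow(vis)), function(i)
    any(emp_t >= vis$start[i] & emp_t < vis$end[i]), logical(1))
  term <- check_termination(ev, vis, clock = max(bundle$beam$t),
                            max_empties = bundle$params$max_empties,
                            idle_timeout_s = bundle$params$idle_timeout_s)
  list(visits = data.frame(start = vis$start, end = vis$end,
                           duration = vis$duration, emptied = emptied,
                           hits = ah$per_visit),
       orphan_hits = ah$orphan_times, trajectory = traj, events = ev,
       termination = term)
}

#' Default stage-2 pipeline configuration
#'
#' The conditions of the instrumented-flower experiment: four corolla
#' curvatures (flat disc, trumpet, gentle trumpet, bowl) at a 3 mm nectary
#' diameter, L = 30 mm, R = 23.5 mm, around 15 moths per morph. Per-curvature
#' feeding probabilities and contact intensities encode the fitness surfaces
#' the generator emulates: nectar access peaks at the gentle trumpet and
#' collapses at the extremes, while contacts decrease monotonically from the
#' flat disc to the bowl.
#'
#' @param curvatures Corolla curvatures tested.
#' @param n_moths Moths (trials) per curvature.
#' @param n_visits Visits attempted per trial.
#' @param feed_prob Named per-curvature feeding probability.
#' @param hits_mean Named per-curvature mean contacts per visit.
#' @param duration_meanlog,duration_sdlog Visit-duration model (log-normal).
#' @param seed Root seed; everything downstream derives from it.
#' @param arena [arena_config()] for frame rendering. The default uses a
#'   320 x 240 px camera at 1.25 mm/px, which keeps the 125 mm presence
#'   radius comfortably inside the field of view.
#' @param out_dir Optional output directory for CSV tables and the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(curvatures = c(-Inf, -3, -1, 1),
                       n_moths = 15,
                       n_visits = 5,
                       feed_prob = c("-Inf" = 0.24, "-3" = 0.65,
                                     "-1" = 0.885, "1" = 0.325),
                       hits_mean = c("-Inf" = 28.7, "-3" = 22,
                                     "-1" = 18, "1" = 15.5),
                       duration_meanlog = log(9.6),
                       duration_sdlog = 0.35,
                       seed = 1L,
                       arena = arena_config(width_px = 320, height_px = 240,
                                            mm_per_pixel = 1.25),
                       out_dir = NULL) {
  ck <- as.character(curvatures)
  if (!all(ck %in% names(feed_prob)) || !all(ck %in% names(hits_mean)))
    stop("feed_prob and hits_mean must be named for every curvature",
         call. = FALSE)
  structure(list(curvatures = curvatures, n_moths = as.integer(n_moths),
                 n_visits = as.integer(n_visits), feed_prob = feed_prob,
                 hits_mean = hits_mean, duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog, seed = as.integer(seed),
                 arena = arena, out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic stage-2 pipeline
#'
#' For every curvature x moth cell: simulates an instrumented-flower trial,
#' renders its video frames, and pushes the three channels through the
#' analysis chain ([analyze_bundle()]); then aggregates per-visit energy-gain
#' rates and hit counts into the per-morphology fitness table and runs the
#' one-way ANOVAs of both fitness metrics on curvature. Deterministic given
#' the config seed. Any stage failure is re-raised naming the stage and the
#' trial.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `visits` (per-visit rows with
#'   curvature labels), `fitness` (per-morph [visit_quality_table()]),
#'   `anova_energy`, `anova_hits`, `manifest`. When `config$out_dir` is set,
#'   `visits.csv`, `fitness.csv` and `manifest.json` are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  n_trial <- length(config$curvatures) * config$n_moths
  seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_trial), ncol = 2)
  all_visits <- list()
  counts <- list()
  k <- 0L
  for (ci in seq_along(config$curvatures)) {
    cc <- config$curvatures[ci]
    ck <- as.character(cc)
    for (m in seq_len(config$n_moths)) {
      k <- k + 1L
      trial_id <- sprintf("c%s_moth%02d", ck, m)
      vm <- visit_model(n_visits = config$n_visits,
                        duration_meanlog = config$duration_meanlog,
                        duration_sdlog = config$duration_sdlog,
                        feed_prob = config$feed_prob[[ck]],
                        gap_mean_s = 6)
      hm <- hit_model(hits_mean = config$hits_mean[[ck]])
      bundle <- with_stage("synth", trial_id,
                           simulate_stage2(vm, hm, seed = seeds[k, 1]))
      res <- with_stage("analysis", trial_id,
                        analyze_bundle(bundle, arena = config$arena,
                                       frame_seed = seeds[k, 2]))
      v <- res$visits
      if (nrow(v) > 0) {
        v$morph <- ck
        v$moth <- m
        v$trial <- trial_id
        all_visits[[length(all_visits) + 1L]] <- v
      }
      counts[[trial_id]] <- c(visits = nrow(v),
                              hits = sum(v$hits),
                              emptied = sum(v$emptied))
    }
  }
  visits <- do.call(rbind, all_visits)
  fitness <- visit_quality_table(visits)
  # order morphs by curvature value, flat disc first
  ord <- order(as.numeric(fitness$morph))
  fitness <- fitness[ord, , drop = FALSE]
  rownames(fitness) <- NULL
  visits$energy_rate <- energy_gain_rate(visits$duration, visits$emptied)
  anova_energy <- one_way_anova(visits, "energy_rate", "morph")
  anova_hits <- one_way_anova(visits, "hits", "morph")
  manifest <- list(
    package = "corolla",
    package_version = as.character(utils::packageVersion("corolla")),
    r_version = R.version.string,
    seed = config$seed,
    curvatures = config$curvatures,
    n_moths = config$n_moths,
    n_visits_per_trial = config$n_visits,
    arena = config$arena[c("width_px", "height_px", "mm_per_pixel")],
    per_trial_counts = counts)
  out <- structure(list(visits = visits, fitness = fitness,
                        anova_energy = anova_energy,
                        anova_hits = anova_hits, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(visits, file.path(config$out_dir, "visits.csv"))
    write_table_csv(fitness, file.path(config$out_dir, "fitness.csv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# re-raise any stage error with the stage name and trial id attached
with_stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for trial '%s': %s", stage, id,
                 conditionMessage(e)), call. = FALSE))
}

#' One-way ANOVA of a response on a single factor
#'
#' @param data data.frame.
#' @param response,factor Column names.
#' @return data.frame with `term`, `sum_sq`, `df`, `F`, `p`.
#' @export
one_way_anova <- function(data, response, factor) {
  d <- data.frame(y = data[[response]], f = as.factor(data[[factor]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$f)) < 2)
    stop("factor needs at least 2 observed levels", call. = FALSE)
  a <- stats::anova(stats::lm(y ~ f, data = d))
  out <- data.frame(term = c(factor, "Residuals"), sum_sq = a$`Sum Sq`,
                    df = a$Df, F = a$`F value`, p = a$`Pr(>F)`)
  rownames(out) <- NULL
  out
}

#' Analyse a recorded stage-2 bundle directory
#'
#' Reads the plain-text capture layout written by [write_bundle()] (accel
#' and beam CSVs, meta sidecar, PNG frames) and runs the same analysis chain
#' as [analyze_bundle()]. Missing inputs are reported with the stage that
#' needs them.
#'
#' @param dir Bundle directory.
#' @param radius_mm,gap_frames Passed to [segment_visits()].
#' @return Same structure as [analyze_bundle()].
#' @export
analyze_bundle_dir <- function(dir, radius_mm = 125, gap_frames = 1) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("stage 'signals': missing meta.json in '%s'", dir),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  accel_path <- file.path(dir, "accel.csv")
  if (!file.exists(accel_path))
    stop(sprintf("stage 'signals': missing accelerometer file '%s'",
                 accel_path), call. = FALSE)
  beam_path <- file.path(dir, "beam.csv")
  if (!file.exists(beam_path))
    stop(sprintf("stage 'signals': missing beam file '%s'", beam_path),
         call. = FALSE)
  frames_dir <- file.path(dir, "frames")
  if (!dir.exists(frames_dir))
    stop(sprintf("stage 'vision': missing frames directory '%s'", frames_dir),
         call. = FALSE)
  accel <- utils::read.csv(accel_path)
  beam <- utils::read.csv(beam_path)
  frames <- read_frames(frames_dir)
  traj <- track(frames)
  vis <- segment_visits(traj, radius_mm = radius_mm, gap_frames = gap_frames,
                        fps = meta$fps)
  cal <- calibrate_accel(accel, unlist(meta$calib$static_window),
                         sensitivity = unlist(meta$calib$sensitivity))
  mag <- accel_magnitude(cal)
  hits <- detect_hits(mag)
  ah <- assign_hits(hits, vis)
  ev <- beam_events(beam, stage = "stage2")
  emp_t <- ev$time[ev$kind == "EMPTIED"]
  emptied <- vapply(seq_len(nrow(vis)), function(i)
    any(emp_t >= vis$start[i] & emp_t < vis$end[i]), logical(1))
  term <- check_termination(ev, vis, clock = max(beam$t))
  list(visits = data.frame(start = vis$start, end = vis$end,
                           duration = vis$duration, emptied = emptied,
                           hits = ah$per_visit),
       orphan_hits = ah$orphan_times, trajectory = traj, events = ev,
       termination = term)
}
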