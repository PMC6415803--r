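test_that("stage-1 trials respect the flower pool and the end rules", {
  # all-success, stop when one morph is fully emptied
  cfg <- stage1_config(visit_rate = rep(2, 6), success_prob = rep(1, 6),
                       end_rule = "ALL_OF_ONE_MORPH_EMPTIED")
  tr <- simulate_stage1(cfg, 20, seed = 5)
  for (id in unique(tr$trial_id)) {
    d <- tr[tr$trial_id == id, ]
    expect_equal(max(d$emptied), 6)          # the winning morph
    expect_true(all(d$emptied <= d$visits))
    expect_lt(d$duration_s[1], cfg$max_duration_s)
  }
  # no successes anywhere
  cfg0 <- stage1_config(success_prob = rep(0, 6))
  tr0 <- simulate_stage1(cfg0, 5, seed = 5)
  expect_true(all(tr0$emptied == 0))
  # conservation under arbitrary settings
  cfgr <- stage1_config(success_prob = c(0.9, 0.8, 0.5, 0.2, 0.7, 1))
  trr <- simulate_stage1(cfgr, 50, seed = 9)
  expect_true(all(trr$emptied <= 6))
  expect_true(all(trr$emptied <= trr$visits))
})

test_that("stage-1 emptying follows the configured Bernoulli law", {
  cfg <- stage1_config(success_prob = c(0.45, 0.45, 0.45, 0.45, 0.45, 0.45))
  tr <- simulate_stage1(cfg, 1700, seed = 21)
  v <- sum(tr$visits); e <- sum(tr$emptied)
  expect_gt(v, 10000)
  se <- sqrt(0.45 * 0.55 / v)
  expect_lt(abs(e / v - 0.45), 3 * se)
})

test_that("stage-1 generation is deterministic given config and seed", {
  cfg <- stage1_config()
  expect_identical(simulate_stage1(cfg, 10, seed = 7),
                   simulate_stage1(cfg, 10, seed = 7))
  expect_false(identical(simulate_stage1(cfg, 10, seed = 7),
                         simulate_stage1(cfg, 10, seed = 8)))
})

test_that("degenerate stage-1 configurations are rejected", {
  expect_error(stage1_config(visit_rate = rep(0, 6)), "degenerate")
  expect_error(stage1_config(success_prob = c(2, 0, 0, 0, 0, 0)), "\\[0, 1\\]")
  expect_error(stage1_config(visit_rate = c(1, 1)), "per morph")
})

test_that("stage-2 bundles carry complete, recoverable ground truth", {
  for (seed in 1:4) {
    b <- simulate_stage2(visit_model(n_visits = 3), hit_model(), seed = seed)
    tr <- b$truth
    # channels share the clock from 0 at the declared rates
    expect_equal(b$accel$t[1], 0)
    expect_equal(diff(b$accel$t[1:3]), rep(1 / b$fs, 2))
    expect_equal(nrow(b$accel), nrow(b$beam))
    # every injected contact lies inside its visit
    expect_true(all(tr$hit_times >= tr$visits$start[tr$hit_visit]))
    expect_true(all(tr$hit_times <= tr$visits$end[tr$hit_visit]))
    # injected transients are recovered exactly by the detection chain
    cal <- calibrate_accel(b$accel, b$calib$static_window,
                           sensitivity = b$calib$sensitivity)
    hits <- detect_hits(accel_magnitude(cal))
    expect_length(hits, length(tr$hit_times))
    expect_lt(max(abs(hits - tr$hit_times)), 0.005)
    # beam transitions match the emptying record
    ev <- beam_events(b$beam, stage = "stage2")
    expect_equal(sum(ev$kind == "EMPTIED"), sum(tr$visits$emptied))
  }
})

test_that("stage-2 trial is truncated at the refiller capacity", {
  b <- simulate_stage2(visit_model(n_visits = 30, feed_prob = 1),
                       hit_model(hits_mean = 1), seed = 2)
  expect_equal(sum(b$truth$visits$emptied), 25)
  expect_equal(nrow(b$truth$visits), 25)
  expect_equal(b$truth$termination$status, "ENDED_25_REFILLS")
})

test_that("a visitless stage-2 trial is noise only", {
  b <- simulate_stage2(visit_model(n_visits = 0), hit_model(), seed = 3)
  expect_equal(nrow(b$truth$visits), 0)
  expect_length(b$truth$hit_times, 0)
  expect_true(all(b$beam$state == b$beam$state[1]))
  cal <- calibrate_accel(b$accel, b$calib$static_window,
                         sensitivity = b$calib$sensitivity)
  expect_lt(max(accel_magnitude(cal)$mag), 3)
})

test_that("undetectable hit amplitudes are rejected at configuration", {
  expect_error(hit_model(amp_range_g = c(2, 5)), "threshold")
})

test_that("stage-2 generation is deterministic given seed", {
  args <- list(visit_model(n_visits = 4), hit_model(), seed = 11)
  expect_identical(do.call(simulate_stage2, args),
                   do.call(simulate_stage2, args))
})

test_that("rendered frames place the blob at the true position", {
  ar <- arena_config(width_px = 200, height_px = 160, mm_per_pixel = 1)
  # static moth at the flower center for 10 frames
  traj <- data.frame(t = (0:9) / 5, x_mm = 10, y_mm = -5, present = TRUE)
  fs <- render_frames(traj, ar, seed = 4)
  cents <- t(vapply(fs$frames, function(f)
    locate_moth(f, fs$reference), numeric(2)))
  expect_lt(max(abs(cents[, 1] - (100 + 10))), 1)
  expect_lt(max(abs(cents[, 2] - (80 - 5))), 1)
  expect_lt(max(apply(cents, 2, function(x) diff(range(x)))), 1)
  # oracle: intensity-weighted centroid of the painted pixels
  d <- abs(fs$frames[[1]] - fs$reference)
  oc <- oracle_centroid(d, floor = 0.1)
  expect_lt(abs(cents[1, 1] - oc[["x"]]), 1)
  expect_lt(abs(cents[1, 2] - oc[["y"]]), 1)
})

test_that("absent moths leave frames at the reference up to noise and specks", {
  ar <- arena_config(width_px = 200, height_px = 160, mm_per_pixel = 1)
  traj <- data.frame(t = (0:4) / 5, x_mm = NA, y_mm = NA, present = FALSE)
  fs <- render_frames(traj, ar, seed = 4)
  for (f in fs$frames)
    expect_null(locate_moth(f, fs$reference))
})

test_that("a blob leaving the image bounds is marked absent in truth", {
  ar <- arena_config(width_px = 200, height_px = 160, mm_per_pixel = 1)
  traj <- data.frame(t = c(0, 0.2), x_mm = c(0, 500), y_mm = 0,
                     present = TRUE)
  fs <- render_frames(traj, ar, seed = 4)
  expect_true(fs$truth_px$present[1])
  expect_false(fs$truth_px$present[2])
})
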