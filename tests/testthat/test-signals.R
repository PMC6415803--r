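make_raw_trace <- function(offset = c(510, 500, 520), scale = c(100, 101, 99),
                           n = 2000, noise_sd = 0.002, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / 1000
  g <- cbind(rnorm(n, 0, noise_sd), rnorm(n, 0, noise_sd),
             1 + rnorm(n, 0, noise_sd))
  data.frame(t = t,
             ax = g[, 1] * scale[1] + offset[1],
             ay = g[, 2] * scale[2] + offset[2],
             az = g[, 3] * scale[3] + offset[3])
}

test_that("gravity calibration recovers the encoding map", {
  off <- c(510, 500, 520); sc <- c(100, 101, 99)
  raw <- make_raw_trace(off, sc)
  # sensitivity known: offsets recovered within 1%
  cal <- calibrate_accel(raw, c(0, 2), sensitivity = sc)
  expect_lt(max(abs(attr(cal, "calib")$offset - off) / off), 0.01)
  m <- accel_magnitude(cal)
  expect_equal(mean(m$mag), 1, tolerance = 0.01)
  # zero-g offsets known: shared scale recovered within 1%
  cal2 <- calibrate_accel(raw, c(0, 2), zero_g_offset = off)
  expect_lt(abs(attr(cal2, "calib")$scale[1] - mean(sc)) / mean(sc), 0.02)
  expect_equal(mean(accel_magnitude(cal2)$mag), 1, tolerance = 0.01)
})

test_that("an already-calibrated trace maps to the identity", {
  raw <- make_raw_trace(offset = c(0, 0, 0), scale = c(1, 1, 1))
  cal <- calibrate_accel(raw, c(0, 2), sensitivity = c(1, 1, 1))
  expect_lt(max(abs(attr(cal, "calib")$offset)), 1e-3)
  expect_equal(cal$az, raw$az, tolerance = 1e-4)
})

test_that("calibration rejects unusable static windows", {
  raw <- make_raw_trace()
  expect_error(calibrate_accel(raw, c(0, 0.1), sensitivity = c(100, 100, 100)),
               "fewer than 500")
  shaky <- raw
  shaky$ax <- shaky$ax + 300 * sin(seq_len(nrow(raw)))   # ~3 g swings
  expect_error(calibrate_accel(shaky, c(0, 2), sensitivity = c(100, 100, 100)),
               "variance")
  expect_error(calibrate_accel(raw, c(0, 2)), "sensitivity|zero_g")
})

test_that("total acceleration is the three-axis quadrature sum", {
  tr <- data.frame(t = 0:2 / 1000, ax = c(0, 3, 1), ay = c(0, 4, 2),
                   az = c(1, 0, 2))
  m <- accel_magnitude(tr)
  expect_equal(m$mag, c(1, 5, 3))
  # element-wise brute force on a random trace
  set.seed(4)
  tr2 <- data.frame(t = 1:50, ax = rnorm(50), ay = rnorm(50), az = rnorm(50))
  expect_equal(accel_magnitude(tr2)$mag,
               vapply(1:50, function(i)
                 sqrt(tr2$ax[i]^2 + tr2$ay[i]^2 + tr2$az[i]^2), numeric(1)))
})

ring <- function(t0, amp, t, tau = 0.02, f = 18.4) {
  dt <- t - t0
  ifelse(dt >= 0 & dt < 6 * tau, amp * exp(-dt / tau) * cos(2 * pi * f * dt), 0)
}

test_that("hit detection counts separated supra-threshold transients", {
  t <- (0:2999) / 1000
  m <- 1 + ring(0.5, 5, t) + ring(0.7, 5, t) + ring(0.9, 5, t)
  hits <- detect_hits(data.frame(t = t, mag = m))
  expect_length(hits, 3)
  expect_equal(hits, c(0.5, 0.7, 0.9), tolerance = 2e-3)
  # sub-threshold trace
  expect_length(detect_hits(data.frame(t = t, mag = 1 + ring(0.5, 1.5, t))), 0)
  # two peaks 10 ms apart collapse under the 50 ms separation rule
  m2 <- 1 + pmax(ring(0.5, 5, t), ring(0.51, 5, t))
  expect_length(detect_hits(data.frame(t = t, mag = m2)), 1)
})

test_that("hit detection matches the exhaustive peak-scan oracle", {
  set.seed(31)
  for (rep in 1:100) {
    t <- (0:1999) / 1000
    m <- 1 + abs(rnorm(2000, 0, 0.3))
    for (k in seq_len(sample(0:5, 1)))
      m <- m + ring(runif(1, 0.1, 1.8), runif(1, 3.5, 8), t)
    got <- detect_hits(data.frame(t = t, mag = m))
    want <- oracle_peaks(t, m, thr = 3, sep = 0.05)
    expect_equal(got, want)
  }
})

test_that("beam event extraction labels debounced transitions", {
  t <- (0:999) / 1000
  s <- integer(1000); s[301:600] <- 1L
  ev <- beam_events(data.frame(t = t, state = s), stage = "stage2")
  expect_equal(ev$kind, c("EMPTIED", "REFILLED"))
  expect_equal(ev$time, c(0.300, 0.600))
  # constant series
  expect_equal(nrow(beam_events(data.frame(t = t, state = rep(1L, 1000)))), 0)
  # a 1 ms glitch vanishes under the 20 ms debounce
  sg <- s; sg[101:102] <- 1L
  evg <- beam_events(data.frame(t = t, state = sg), debounce_ms = 20)
  expect_equal(evg$kind, c("EMPTIED", "REFILLED"))
  o <- oracle_debounce_transitions(sg, min_run = 20)
  expect_equal(evg$time, t[o$idx])
  # stage-1 convention: every break is a probe
  ev1 <- beam_events(data.frame(t = t, state = s), stage = "stage1")
  expect_equal(ev1$kind, "PROBE")
})

test_that("termination rules fire in order of occurrence", {
  visits <- data.frame(start = 10, end = 20)
  evs <- data.frame(time = seq_len(25) * 30, kind = rep("EMPTIED", 25))
  got <- check_termination(evs, visits, clock = 800)
  expect_equal(got$status, "ENDED_25_REFILLS")
  expect_equal(got$time, 750)
  idle <- check_termination(evs[1:10, ], visits, clock = 20 + 240)
  expect_equal(idle$status, "ENDED_4MIN_IDLE")
  expect_equal(idle$time, 260)
  expect_equal(check_termination(evs[1:24, ], visits, clock = 100)$status,
               "ongoing")
})

test_that("hits are attributed to containing visits, never dropped", {
  visits <- data.frame(start = c(0, 10), end = c(5, 15))
  a <- assign_hits(c(1, 2, 7, 12, 20), visits)
  expect_equal(a$per_visit, c(2L, 1L))
  expect_equal(a$orphan_times, c(7, 20))
  expect_equal(length(a$orphan_times) + sum(a$per_visit), 5)
})

test_that("a static calibrated trace never registers hits", {
  b <- simulate_stage2(visit_model(n_visits = 0), hit_model(), seed = 17)
  cal <- calibrate_accel(b$accel, b$calib$static_window,
                         sensitivity = b$calib$sensitivity)
  m <- accel_magnitude(cal)
  expect_equal(mean(m$mag), 1, tolerance = 0.05)
  expect_length(detect_hits(m), 0)
})
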