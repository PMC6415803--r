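# Independent brute-force oracles used to check the package's vectorised /
# incremental implementations on small cases.

# intensity-weighted centroid of all pixels above a floor, in (x, y) pixels
oracle_centroid <- function(img, floor = 0) {
  pix <- which(img > floor, arr.ind = TRUE)
  w <- img[pix]
  c(x = sum(pix[, 2] * w) / sum(w), y = sum(pix[, 1] * w) / sum(w))
}

# run-length scan of a logical presence vector: maximal TRUE runs after
# merging FALSE gaps of at most `gap` elements that sit between TRUE runs
oracle_runs <- function(inside, gap) {
  n <- length(inside)
  merged <- inside
  i <- 1
  while (i <= n) {
    if (!merged[i]) {
      j <- i
      while (j <= n && !merged[j]) j <- j + 1
      if (i > 1 && j <= n && (j - i) <= gap) merged[i:(j - 1)] <- TRUE
      i <- j
    } else i <- i + 1
  }
  runs <- list()
  i <- 1
  while (i <= n) {
    if (merged[i]) {
      j <- i
      while (j <= n && merged[j]) j <- j + 1
      runs[[length(runs) + 1]] <- c(first = i, last = j - 1)
      i <- j
    } else i <- i + 1
  }
  runs
}

# exhaustive peak scan with a separation rule: local maxima above the
# threshold, accepted in time order when no previously accepted peak lies
# within `sep` seconds
oracle_peaks <- function(t, m, thr, sep) {
  acc <- numeric(0)
  for (i in seq_along(m)) {
    if (i == 1 || i == length(m)) next
    if (m[i] > thr && m[i] > m[i - 1] && m[i] >= m[i + 1]) {
      if (all(abs(t[i] - acc) >= sep)) acc <- c(acc, t[i])
    }
  }
  acc
}

# run-length debounce: successive states shorter than min_run samples are
# absorbed into the running stable state; returns indices of surviving
# transitions
oracle_debounce_transitions <- function(s, min_run) {
  r <- rle(s)
  v <- r$values; l <- r$lengths
  ov <- v[1]; ol <- l[1]
  for (i in seq_along(v)[-1]) {
    if (l[i] < min_run) {
      ol[length(ol)] <- ol[length(ol)] + l[i]
    } else if (v[i] == ov[length(ov)]) {
      ol[length(ol)] <- ol[length(ol)] + l[i]
    } else {
      ov <- c(ov, v[i]); ol <- c(ol, l[i])
    }
  }
  if (length(ov) < 2) return(integer(0))
  list(idx = cumsum(ol)[-length(ol)] + 1L, new_state = ov[-1])
}

# paint one elliptical Gaussian blob on a flat image (test-side renderer)
paint_test_blob <- function(h, w, cx, cy, sigma, peak = 0.8, bg = 0) {
  img <- matrix(bg, h, w)
  for (r in seq_len(h)) for (cl in seq_len(w)) {
    d2 <- ((cl - cx)^2 + (r - cy)^2) / (2 * sigma^2)
    if (d2 < 12) img[r, cl] <- img[r, cl] + peak * exp(-d2)
  }
  img
}
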