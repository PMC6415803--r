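#' Locate the moth in one frame by reference-frame subtraction
#'
#' Subtracts the moth-free reference frame, thresholds the absolute
#' difference image, labels connected components, and returns the centroid
#' of the largest component provided its area reaches `min_area_px`
#' (the largest-contour rule; smaller specks are ignored).
#'
#' @param frame,reference Grayscale matrices of equal size, values in
#'   `[0, 1]` (rows = image y, columns = image x).
#' @param intensity_threshold Difference threshold in `[0, 1]`; `NULL`
#'   (default) uses Otsu's threshold on the difference image, floored at
#'   10/255.
#' @param min_area_px Minimum blob area in pixels (default 30).
#' @return Numeric `c(x, y)` centroid in 1-based pixel coordinates, or
#'   `NULL` when no sufficiently large blob is present (ABSENT).
#' @export
locate_moth <- function(frame, reference, intensity_threshold = NULL,
                        min_area_px = 30) {
  if (!identical(dim(frame), dim(reference)))
    stop("frame and reference dimensions differ", call. = FALSE)
  d <- abs(frame - reference)
  if (is.null(intensity_threshold))
    intensity_threshold <- max(otsu_threshold(d), 10 / 255)
  bw <- d > intensity_threshold
  if (!any(bw)) return(NULL)
  lab <- EBImage::bwlabel(bw * 1)
  lab <- as.integer(EBImage::imageData(lab))
  areas <- tabulate(lab)
  if (length(areas) == 0 || max(areas) < min_area_px) return(NULL)
  biggest <- which.max(areas)
  # labels come back in the same matrix layout they went in (rows = y)
  dims <- dim(bw)
  pix <- which(matrix(lab, dims[1], dims[2]) == biggest, arr.ind = TRUE)
  c(x = mean(pix[, 2]), y = mean(pix[, 1]))
}

#' Otsu's threshold of an image
#'
#' Maximises the between-class variance over a 256-bin histogram of values
#' in `[0, 1]`.
#'
#' @param x Numeric matrix/array with values in `[0, 1]`.
#' @return Threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(x) {
  counts <- tabulate(pmin(floor(as.vector(x) * 256) + 1L, 256L), 256L)
  p <- counts / sum(counts)
  mids <- (seq_len(256) - 0.5) / 256
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[256]
  bcv <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Track the moth across a frame sequence
#'
#' Applies [locate_moth()] to every frame and converts pixel centroids to
#' millimetres relative to the flower center, giving one trajectory record
#' per frame. Coordinates are image-plane mm (top-down camera, no
#' perspective correction); y increases down the image.
#'
#' @param frames A `frame_set` from [render_frames()]/[read_frames()], or a
#'   plain list of frame matrices.
#' @param calibration List with `mm_per_pixel`, `flower_center_px` and `fps`;
#'   taken from the frame set when omitted.
#' @param ... Passed on to [locate_moth()].
#' @return A data.frame of class `moth_trajectory`: `t`, `x_mm`, `y_mm`,
#'   `present`, with attribute `fps`.
#' @export
track <- function(frames, calibration = NULL, ...) {
  if (inherits(frames, "frame_set")) {
    if (is.null(calibration))
      calibration <- list(mm_per_pixel = frames$arena$mm_per_pixel,
                          flower_center_px = frames$arena$flower_center_px,
                          fps = 1 / diff(frames$t[1:2]))
    reference <- frames$reference
    tt <- frames$t
    frames <- frames$frames
  } else {
    if (is.null(calibration) || is.null(calibration$mm_per_pixel) ||
        is.null(calibration$flower_center_px))
      stop("calibration with mm_per_pixel and flower_center_px is required",
           call. = FALSE)
    reference <- calibration$reference
    if (is.null(reference))
      stop("calibration must designate a reference frame", call. = FALSE)
    tt <- (seq_along(frames) - 1) / calibration$fps
  }
  fps <- calibration$fps
  if (is.null(fps)) fps <- 5
  n <- length(frames)
  out <- data.frame(t = tt, x_mm = NA_real_, y_mm = NA_real_,
                    present = FALSE)
  fc <- calibration$flower_center_px
  for (k in seq_len(n)) {
    cen <- locate_moth(frames[[k]], reference, ...)
    if (!is.null(cen)) {
      out$x_mm[k] <- (cen[["x"]] - fc[1]) * calibration$mm_per_pixel
      out$y_mm[k] <- (cen[["y"]] - fc[2]) * calibration$mm_per_pixel
      out$present[k] <- TRUE
    }
  }
  attr(out, "fps") <- fps
  class(out) <- c("moth_trajectory", "data.frame")
  out
}

#' Segment a trajectory into flower visits
#'
#' A frame counts as in-visit when the moth is present and its centroid lies
#' within `radius_mm` of the flower center (the span of a hawkmoth body plus
#' extended proboscis). Maximal runs of in-visit frames become visit events;
#' out-of-visit gaps of at most `gap_frames` frames between runs are merged,
#' absorbing single-frame dropouts. Visit intervals are half-open
#' `[start, end)` in seconds and `duration = (n_frames_in_run) / fps`.
#'
#' @param traj A `moth_trajectory` (or data.frame with `t`, `x_mm`, `y_mm`,
#'   `present`).
#' @param radius_mm Presence radius, mm (default 125).
#' @param gap_frames Maximum merged gap, frames (default 1, i.e. 0.2 s at
#'   5 fps).
#' @param fps Frame rate; taken from the trajectory attribute when omitted.
#' @return A data.frame of class `visit_events`: `visit`, `start`, `end`,
#'   `duration`, `first_frame`, `last_frame`.
#' @export
segment_visits <- function(traj, radius_mm = 125, gap_frames = 1, fps = NULL) {
  stopifnot(nrow(traj) >= 1)
  if (is.null(fps)) fps <- attr(traj, "fps")
  if (is.null(fps)) fps <- if (nrow(traj) > 1) 1 / diff(traj$t[1:2]) else 5
  d <- sqrt(traj$x_mm^2 + traj$y_mm^2)
  inside <- !is.na(d) & traj$present & d <= radius_mm
  runs <- rle(inside)
  # merge short FALSE gaps flanked by TRUE runs
  if (length(runs$values) > 2) {
    for (i in 2:(length(runs$values) - 1)) {
      if (!runs$values[i] && runs$lengths[i] <= gap_frames &&
          runs$values[i - 1] && runs$values[i + 1])
        runs$values[i] <- TRUE
    }
  }
  merged <- rle(inverse.rle(runs))
  ends <- cumsum(merged$lengths)
  starts <- ends - merged$lengths + 1L
  vis <- which(merged$values)
  out <- data.frame(visit = seq_along(vis),
                    start = traj$t[starts[vis]],
                    end = traj$t[ends[vis]] + 1 / fps,
                    duration = (ends[vis] - starts[vis] + 1L) / fps,
                    first_frame = starts[vis] - 1L,
                    last_frame = ends[vis] - 1L)
  class(out) <- c("visit_events", "data.frame")
  attr(out, "fps") <- fps
  out
}
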