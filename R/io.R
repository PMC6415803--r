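#' Write a frame set as a PNG directory with JSON sidecar
#'
#' Lays out the on-disk capture format: `reference.png`, `frame_0000.png`,
#' `frame_0001.png`, ... plus `sidecar.json` recording the frame rate, image
#' scale, reference frame name and flower-center pixel.
#'
#' @param fs A `frame_set` from [render_frames()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(fs, dir) {
  stopifnot(inherits(fs, "frame_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(fs$reference, file.path(dir, "reference.png"))
  for (k in seq_along(fs$frames))
    png::writePNG(fs$frames[[k]],
                  file.path(dir, sprintf("frame_%04d.png", k - 1L)))
  sidecar <- list(
    fps = if (length(fs$t) > 1) 1 / diff(fs$t[1:2]) else 5,
    mm_per_pixel = fs$arena$mm_per_pixel,
    reference = "reference.png",
    flower_center_px = fs$arena$flower_center_px,
    n_frames = length(fs$frames),
    t0 = fs$t[1])
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a PNG frame directory written by [write_frames()]
#'
#' @param dir Directory holding `sidecar.json`, the reference frame and
#'   numbered frames.
#' @return A `frame_set` (without ground truth).
#' @export
read_frames <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path))
    stop(sprintf("no sidecar.json in '%s'", dir), call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  ref <- png::readPNG(file.path(dir, sc$reference))
  if (length(dim(ref)) == 3) ref <- ref[, , 1]
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img[, , 1] else img
  })
  t0 <- if (!is.null(sc$t0)) sc$t0 else 0
  arena <- arena_config(width_px = ncol(ref), height_px = nrow(ref),
                        mm_per_pixel = sc$mm_per_pixel,
                        flower_center_px = sc$flower_center_px)
  structure(list(reference = ref, frames = frames,
                 t = t0 + (seq_along(frames) - 1) / sc$fps,
                 truth_px = NULL, arena = arena),
            class = "frame_set")
}

#' Write a sensor bundle to a directory of plain-text files
#'
#' `accel.csv` (t, ax, ay, az; raw counts), `beam.csv` (t, state),
#' `meta.json` (sampling rates, calibration) and `truth.json` (the
#' generator's ground truth). Video frames are written separately with
#' [write_frames()] into `frames/`.
#'
#' @param bundle A `sensor_bundle`.
#' @param dir Output directory.
#' @param frames Optional `frame_set` to store under `frames/`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, frames = NULL) {
  stopifnot(inherits(bundle, "sensor_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$accel, file.path(dir, "accel.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$beam, file.path(dir, "beam.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fs = bundle$fs, fps = bundle$fps, calib = bundle$calib),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  tr <- bundle$truth
  jsonlite::write_json(
    list(visits = tr$visits, hit_times = tr$hit_times,
         hit_visit = tr$hit_visit, termination = tr$termination,
         seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(frames)) write_frames(frames, file.path(dir, "frames"))
  invisible(dir)
}

#' Write a fitness table (or any data.frame) as CSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
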