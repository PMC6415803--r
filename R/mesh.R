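#' Build a watertight surface-of-revolution mesh for a flower shape
#'
#' Constructs the printable solid for a flower morphology: the corolla
#' generating curve is sampled radially, given a wall of uniform thickness by
#' offsetting along the local surface normal, joined to a nectary bore tube of
#' inner radius `r0`, closed into a simple polygon in the (radius, height)
#' plane, and revolved about the z-axis. Because the closed generating polygon
#' is revolved as a whole, every edge of the triangulation is shared by
#' exactly two faces (torus topology), i.e. the mesh is watertight by
#' construction. Vertices are translated so the lowest point sits at z = 0.
#'
#' For `c = -Inf` the corolla degenerates to a flat annular disc of the given
#' wall thickness at the top of the flower, with the central nectary bore kept
#' open as a tube below it.
#'
#' @param shape A [flower_shape()].
#' @param n_angular Angular tessellation (>= 8; default 128, < 0.05 mm chord
#'   error at a 27.5 mm outer radius).
#' @param n_radial Radial tessellation of the corolla surface (>= 2;
#'   default 64).
#' @param wall_thickness Shell thickness in mm (default 1, as printed).
#' @param bore_depth Depth of the nectary tube below the corolla surface in
#'   mm (default 20).
#' @return An object of class `flower_mesh`: list with `vertices` (n x 3
#'   matrix, mm), `faces` (m x 3 integer matrix, 1-based, consistently
#'   oriented), `wall_thickness`, `source_shape`, and `z_offset` (the vertical
#'   translation applied so that min z = 0).
#' @examples
#' m <- build_mesh(flower_shape(0, 0.5, 20, 27), n_angular = 32, n_radial = 8)
#' mesh_is_watertight(m)
#' @export
build_mesh <- function(shape, n_angular = 128, n_radial = 64,
                       wall_thickness = 1, bore_depth = 20) {
  stopifnot(inherits(shape, "flower_shape"))
  if (n_angular < 8 || n_radial < 2)
    stop("tessellation too coarse: need n_angular >= 8, n_radial >= 2",
         call. = FALSE)
  if (wall_thickness <= 0 || bore_depth <= 0)
    stop("wall_thickness and bore_depth must be positive", call. = FALSE)
  if (wall_thickness >= 2 * shape$r0)
    stop("degenerate shape: wall_thickness >= nectary diameter", call. = FALSE)

  t <- wall_thickness
  r0 <- shape$r0
  poly <- if (is.infinite(shape$c)) {
    disc_polyline(shape, t, bore_depth, n_radial)
  } else {
    shell_polyline(shape, t, bore_depth, n_radial)
  }
  # drop consecutive (and wrap-around) duplicates so every revolved segment
  # has positive length
  keep <- c(TRUE, rowSums((poly[-1, , drop = FALSE] -
                           poly[-nrow(poly), , drop = FALSE])^2) > 1e-16)
  poly <- poly[keep, , drop = FALSE]
  if (sum((poly[1, ] - poly[nrow(poly), ])^2) < 1e-16)
    poly <- poly[-nrow(poly), , drop = FALSE]
  K <- nrow(poly)

  theta <- 2 * pi * (seq_len(n_angular) - 1L) / n_angular
  rho <- poly[, 1]
  zz <- poly[, 2]
  # vertex index of polyline point k at angle j: (j - 1) * K + k
  verts <- cbind(
    x = as.vector(outer(cos(theta), rho)),
    y = as.vector(outer(sin(theta), rho)),
    z = rep(zz, each = n_angular))
  # outer() above is angle-major per polyline point; rebuild index map
  # explicitly for clarity: vertex (k, j) at row (k - 1) * n_angular + j
  idx <- function(k, j) (k - 1L) * n_angular + ((j - 1L) %% n_angular) + 1L
  faces <- matrix(0L, nrow = 2L * K * n_angular, ncol = 3L)
  f <- 0L
  for (k in seq_len(K)) {
    k2 <- if (k == K) 1L else k + 1L
    j <- seq_len(n_angular)
    a <- idx(k, j); b <- idx(k2, j); cc <- idx(k2, j + 1L); d <- idx(k, j + 1L)
    faces[f + j, ] <- cbind(a, b, cc)
    faces[f + n_angular + j, ] <- cbind(a, cc, d)
    f <- f + 2L * n_angular
  }
  z_off <- -min(verts[, "z"])
  verts[, "z"] <- verts[, "z"] + z_off
  structure(list(vertices = verts, faces = faces,
                 wall_thickness = wall_thickness,
                 source_shape = shape, n_angular = n_angular,
                 n_radial = n_radial, z_offset = z_off),
            class = "flower_mesh")
}

# Closed (rho, z) generating polygon for a finite-curvature corolla shell:
# upper surface along the profile, lip cap, offset lower surface, junction to
# the bore outer wall, bore bottom annulus, bore inner wall back to the start.
shell_polyline <- function(shape, t, bore_depth, n_radial) {
  r0 <- shape$r0; R <- shape$R; L <- shape$L
  rr <- r0 + R * seq(0, 1, length.out = n_radial + 1L)
  zz <- corolla_profile(shape, rr)
  P <- cbind(rr, zz)
  # segment normals pointing into the material (below the upper surface)
  d <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  seg_n <- cbind(d[, 2], -d[, 1]) / len
  # vertex normals: average of adjacent segment normals
  vn <- rbind(seg_n[1, ],
              (seg_n[-1, , drop = FALSE] + seg_n[-nrow(seg_n), , drop = FALSE]) / 2,
              seg_n[nrow(seg_n), ])
  vn <- vn / sqrt(rowSums(vn^2))
  Q <- P + t * vn
  # keep the offset surface clear of the axis
  Q[, 1] <- pmax(Q[, 1], r0 / 2)
  rb <- r0 + t                       # bore outer radius
  zj <- min(Q[1, 2], 0)              # junction height to the bore outer wall
  rbind(
    P,                               # upper surface r0 -> r0+R
    Q[rev(seq_len(nrow(Q))), ],      # lip cap then offset surface back
    c(rb, zj),                       # junction onto the bore outer wall
    c(rb, -bore_depth),              # down the bore outer wall
    c(r0, -bore_depth))              # bottom annulus; closes via (r0, 0) = P[1]
}

# Flat-disc limit: annular disc of thickness t at z = L with an open central
# bore tube below it.
disc_polyline <- function(shape, t, bore_depth, n_radial) {
  r0 <- shape$r0; R <- shape$R; L <- shape$L
  rr <- r0 + R * seq(0, 1, length.out = n_radial + 1L)
  rb <- r0 + t
  rr_low <- rev(unique(c(rb, rr[rr > rb + 1e-12])))
  rbind(
    cbind(rr, L),                    # disc top surface
    cbind(rr_low, L - t),            # disc underside back to the bore wall
    c(rb, L - bore_depth),           # bore outer wall
    c(r0, L - bore_depth),           # bore bottom annulus
    c(r0, L - t))                    # up the inner wall; closes at (r0, L)
}

#' Check that a mesh is watertight
#'
#' A triangulation is watertight (2-manifold without boundary) when every
#' undirected edge is shared by exactly two faces.
#'
#' @param mesh A `flower_mesh` (or any list with `vertices` and `faces`).
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a mesh as binary STL
#'
#' Writes the standard 84-byte-header binary STL layout: one facet record per
#' triangle (normal + three vertices as little-endian float32, plus a 2-byte
#' attribute). STL is unit-less by convention; coordinates are in mm.
#'
#' @param mesh A `flower_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L)
    stop("cannot write an empty mesh", call. = FALSE)
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "corolla flower mesh (mm)"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  v <- mesh$vertices
  tri <- array(0, dim = c(nf, 3, 3))
  for (j in 1:3) tri[, j, ] <- v[mesh$faces[, j], , drop = FALSE]
  # facet normals from the right-hand rule
  u <- tri[, 2, ] - tri[, 1, ]
  w <- tri[, 3, ] - tri[, 1, ]
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nl <- sqrt(rowSums(nrm^2))
  nrm[nl > 0, ] <- nrm[nl > 0, ] / nl[nl > 0]
  rec <- t(cbind(nrm, tri[, 1, ], tri[, 2, ], tri[, 3, ]))
  for (i in seq_len(nf)) {
    writeBin(rec[, i], con, size = 4L, endian = "little")
    writeBin(as.integer(0), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' @param path Path to a binary STL file.
#' @return List with `triangles` (n x 3 x 3 array: facet, vertex, xyz),
#'   `normals` (n x 3) and `n_facets`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  tri <- array(NA_real_, dim = c(nf, 3, 3))
  nrm <- matrix(NA_real_, nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    nrm[i, ] <- rec[1:3]
    tri[i, , ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    invisible(readBin(con, "raw", n = 2L))
  }
  list(triangles = tri, normals = nrm, n_facets = nf)
}

#' @export
print.flower_mesh <- function(x, ...) {
  cat(sprintf(
    "<flower_mesh> %d vertices, %d faces, wall %g mm (c = %s, 2r0 = %g mm)\n",
    nrow(x$vertices), nrow(x$faces), x$wall_thickness,
    if (is.infinite(x$source_shape$c)) "-Inf" else format(x$source_shape$c),
    2 * x$source_shape$r0))
  invisible(x)
}
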