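#' Define a parametric flower shape
#'
#' A flower morphology is described by four parameters: the dimensionless
#' corolla curvature `c`, the nectary radius `r0`, the flower length `L`, and
#' the lateral corolla extent `R` (the full radius from the central axis is
#' `r0 + R`). The corolla's generating curve is
#' \deqn{z(r) = L \left(\frac{r - r_0}{R}\right)^{e^{c}},\qquad r_0 \le r \le r_0 + R.}
#' `c = 0` gives a straight-sided cone, `c = 1` a bowl, large negative `c` a
#' trumpet, and `c = -Inf` the flat-disc limit (the corolla is a flat annulus
#' at height `L`, since \eqn{e^{c} \to 0}).
#'
#' @param c Corolla curvature, a finite real or `-Inf` (flat-disc limit).
#' @param r0 Nectary radius in mm, > 0. The nectary diameter is `2 * r0`.
#' @param L Flower length in mm, > 0.
#' @param R Lateral corolla extent in mm, > 0.
#' @return An object of class `flower_shape`.
#' @examples
#' flower_shape(c = 0, r0 = 0.5, L = 20, R = 27)   # cone
#' flower_shape(c = -Inf, r0 = 2.5, L = 20, R = 25) # flat disc
#' @export
flower_shape <- function(c, r0, L, R) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c == Inf)
    stop("'c' must be a single finite real or -Inf", call. = FALSE)
  for (nm in c("r0", "L", "R")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  structure(list(c = as.numeric(c), r0 = as.numeric(r0),
                 L = as.numeric(L), R = as.numeric(R)),
            class = "flower_shape")
}

#' @export
print.flower_shape <- function(x, ...) {
  cat(sprintf("<flower_shape> c = %s, r0 = %g mm, L = %g mm, R = %g mm\n",
              if (is.infinite(x$c)) "-Inf (flat disc)" else format(x$c),
              x$r0, x$L, x$R))
  invisible(x)
}

#' Longitudinal corolla profile
#'
#' Evaluates the generating curve of a flower shape: the longitudinal height
#' `z` of the corolla surface at radial distance `r` from the central axis.
#' For finite curvature, `z = L * ((r - r0) / R)^(exp(c))`; for `c = -Inf`
#' the analytic flat-disc limit is used (`z = L` for `r > r0`, `z = 0` at
#' `r = r0`).
#'
#' @param shape A [flower_shape()].
#' @param r Radial distance(s) in mm; must lie in `[r0, r0 + R]`.
#' @return Numeric vector of heights `z` in mm, same length as `r`.
#' @examples
#' cone <- flower_shape(c = 0, r0 = 0.5, L = 20, R = 27)
#' corolla_profile(cone, 14)  # midpoint of a linear profile: L/2 = 10
#' @export
corolla_profile <- function(shape, r) {
  stopifnot(inherits(shape, "flower_shape"))
  if (!is.numeric(r) || anyNA(r))
    stop("'r' must be numeric without NA", call. = FALSE)
  tol <- 1e-9 * (shape$r0 + shape$R)
  if (any(r < shape$r0 - tol) || any(r > shape$r0 + shape$R + tol))
    stop(sprintf("radial distance outside the corolla domain [%g, %g] mm",
                 shape$r0, shape$r0 + shape$R), call. = FALSE)
  x <- pmin(pmax((r - shape$r0) / shape$R, 0), 1)
  if (is.infinite(shape$c)) {
    # flat-disc limit: exponent e^c -> 0, so x^0 = 1 everywhere except the
    # nectary rim itself, where the curve is anchored at z = 0
    z <- ifelse(x > 0, shape$L, 0)
  } else {
    z <- shape$L * x^exp(shape$c)
  }
  z
}

#' Sample a curvature-by-diameter morphospace grid
#'
#' Builds the set of flower shapes spanned by given corolla curvatures and
#' nectary diameters while keeping the flower length and the overall corolla
#' diameter `2 * (R + r0)` fixed, so each diameter choice trades nectary
#' radius against lateral extent: `r0 = d / 2`, `R = total_diameter / 2 - r0`.
#'
#' @param c_values Corolla curvatures (finite or `-Inf`).
#' @param diameter_values Nectary diameters `2 * r0` in mm.
#' @param L Flower length in mm (default 20).
#' @param total_diameter Overall corolla diameter `2 * (R + r0)` in mm
#'   (default 55).
#' @return An object of class `morph_grid`: list with `shapes` (ordered
#'   curvature-major), `c_values`, `diameter_values` and a `constraint_note`.
#' @examples
#' g <- sample_grid(c(-Inf, -4, -3, -2, -1, 0, 0.375, 1),
#'                  c(1, 1.75, 2.5, 3.25, 5, 7))
#' length(g$shapes)  # 48
#' @export
sample_grid <- function(c_values, diameter_values, L = 20, total_diameter = 55) {
  if (any(diameter_values >= total_diameter))
    stop("every nectary diameter must be smaller than 'total_diameter'",
         call. = FALSE)
  if (any(diameter_values <= 0))
    stop("nectary diameters must be positive", call. = FALSE)
  shapes <- vector("list", length(c_values) * length(diameter_values))
  k <- 0L
  for (cc in c_values) {
    for (d in diameter_values) {
      k <- k + 1L
      r0 <- d / 2
      shapes[[k]] <- flower_shape(c = cc, r0 = r0, L = L,
                                  R = total_diameter / 2 - r0)
    }
  }
  structure(list(
    shapes = shapes,
    c_values = as.numeric(c_values),
    diameter_values = as.numeric(diameter_values),
    constraint_note = sprintf(
      "L fixed at %g mm; overall diameter 2*(R + r0) fixed at %g mm", L,
      total_diameter)),
    class = "morph_grid")
}

#' @export
print.morph_grid <- function(x, ...) {
  cat(sprintf("<morph_grid> %d shapes: %d curvatures x %d diameters\n  %s\n",
              length(x$shapes), length(x$c_values), length(x$diameter_values),
              x$constraint_note))
  invisible(x)
}

#' Morphospace grid as a data frame
#'
#' @param x A `morph_grid`.
#' @param row.names,optional,... Passed through for S3 consistency; unused.
#' @return A data.frame with one row per shape (`c`, `diameter`, `r0`, `L`, `R`).
#' @export
as.data.frame.morph_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x$shapes, function(s)
    data.frame(c = s$c, diameter = 2 * s$r0, r0 = s$r0, L = s$L, R = s$R)))
}
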