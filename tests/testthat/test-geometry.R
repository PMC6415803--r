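paper_grid <- function()
  sample_grid(c(-Inf, -4, -3, -2, -1, 0, 0.375, 1),
              c(1, 1.75, 2.5, 3.25, 5, 7))

test_that("corolla profile reproduces the analytic generating curve", {
  cone <- flower_shape(c = 0, r0 = 0.5, L = 20, R = 27)
  expect_equal(corolla_profile(cone, 14), 10)   # linear profile, midpoint
  bowl <- flower_shape(c = 1, r0 = 0.5, L = 20, R = 27)
  expect_equal(corolla_profile(bowl, 14), 20 * 0.5^exp(1), tolerance = 1e-12)
  # vectorised evaluation agrees with pointwise
  rr <- seq(0.5, 27.5, length.out = 11)
  expect_equal(corolla_profile(cone, rr),
               vapply(rr, function(r) corolla_profile(cone, r), numeric(1)))
})

test_that("boundary conditions hold at machine precision over the full grid", {
  for (s in paper_grid()$shapes) {
    if (is.finite(s$c))
      expect_identical(corolla_profile(s, s$r0), 0)
    expect_equal(corolla_profile(s, s$r0 + s$R), s$L, tolerance = 1e-14)
  }
})

test_that("profile is monotone in r, strictly for finite curvature", {
  for (cc in c(-Inf, -4, -1, 0, 0.375, 1)) {
    s <- flower_shape(cc, 1.25, 20, 26.25)
    rr <- seq(s$r0, s$r0 + s$R, length.out = 200)
    z <- corolla_profile(s, rr)
    expect_true(all(diff(z) >= 0))
    if (is.finite(cc)) expect_true(all(diff(z) > 0))
  }
})

test_that("strongly negative curvature approaches the flat-disc limit", {
  s20 <- flower_shape(-20, 1.25, 20, 26.25)
  sInf <- flower_shape(-Inf, 1.25, 20, 26.25)
  rr <- seq(s20$r0 + 0.01, s20$r0 + s20$R, length.out = 500)
  expect_lt(max(abs(corolla_profile(s20, rr) - corolla_profile(sInf, rr))),
            0.01 * s20$L)
})

test_that("profile and shape constructors validate their domain", {
  s <- flower_shape(0, 0.5, 20, 27)
  expect_error(corolla_profile(s, 0.4), "domain")
  expect_error(corolla_profile(s, 28), "domain")
  expect_error(flower_shape(0, -1, 20, 27), "positive")
  expect_error(flower_shape(0, 0.5, 0, 27), "positive")
  expect_error(flower_shape(NA, 0.5, 20, 27), "finite")
})

test_that("morphospace grid is curvature-major under the fixed-diameter constraint", {
  g <- paper_grid()
  expect_length(g$shapes, 48)
  df <- as.data.frame(g)
  # curvature-major ordering: diameter cycles fastest
  expect_equal(df$diameter[1:6], c(1, 1.75, 2.5, 3.25, 5, 7))
  expect_equal(df$c[1:6], rep(-Inf, 6))
  # the overall radius constraint holds for every shape
  expect_true(all(abs(df$r0 + df$R - 27.5) < 1e-12))
  s <- g$shapes[[which(df$c == -3 & df$diameter == 2.5)]]
  expect_equal(s$r0, 1.25)
  expect_equal(s$R, 26.25)
  expect_length(sample_grid(0, 3)$shapes, 1)
  expect_error(sample_grid(0, 60, total_diameter = 55), "smaller")
})

test_that("meshes are watertight, symmetric and track the profile", {
  for (cc in c(-Inf, -3, 0, 1)) {
    m <- build_mesh(flower_shape(cc, 1.5, 20, 26), n_angular = 24,
                    n_radial = 8)
    expect_true(mesh_is_watertight(m))
    expect_equal(min(m$vertices[, 3]), 0)
    # rotation by one angular step maps the vertex set onto itself
    th <- 2 * pi / 24
    rot <- m$vertices %*% matrix(c(cos(th), sin(th), 0,
                                   -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    key <- function(v) sort(paste(round(v[, 1], 6), round(v[, 2], 6),
                                  round(v[, 3], 6)))
    expect_equal(key(rot), key(m$vertices), tolerance = 1e-6)
  }
  # outer surface of the cone at half height sits at r0 + R/2
  shape <- flower_shape(0, 1.5, 20, 26)
  m <- build_mesh(shape, n_angular = 16, n_radial = 32)
  target_z <- shape$L / 2 + m$z_offset
  rad <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  at_mid <- abs(m$vertices[, 3] - target_z) < 1e-9 &
    rad > shape$r0 + 1  # outer surface, not the bore wall
  expect_true(any(at_mid))
  expect_equal(unique(round(rad[at_mid], 9)), shape$r0 + shape$R / 2)
})

test_that("flat-disc mesh is an annulus of wall thickness with an open bore", {
  shape <- flower_shape(-Inf, 2.5, 20, 25)
  m <- build_mesh(shape, n_angular = 24, n_radial = 8)
  expect_true(mesh_is_watertight(m))
  z <- m$vertices[, 3]
  top <- max(z)
  rad <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  # the disc's two faces are 1 mm apart; the annulus spans r0 .. r0 + R
  disc <- rad > shape$r0 + m$wall_thickness + 1e-9
  expect_setequal(round(z[disc], 6), round(c(top, top - 1), 6))
  expect_equal(max(rad), shape$r0 + shape$R)
  expect_equal(min(rad), shape$r0)
})

test_that("mesh construction rejects degenerate inputs", {
  expect_error(build_mesh(flower_shape(0, 0.5, 20, 27)), "degenerate")
  expect_error(build_mesh(flower_shape(0, 2, 20, 25), n_angular = 4),
               "coarse")
})

test_that("binary STL round-trips through write and read", {
  m <- build_mesh(flower_shape(1, 1.5, 20, 26), n_angular = 16, n_radial = 6)
  path <- tempfile(fileext = ".stl")
  write_stl(m, path)
  r <- read_stl(path)
  expect_equal(r$n_facets, nrow(m$faces))
  for (i in c(1, 10, nrow(m$faces)))
    expect_equal(r$triangles[i, , ], unname(m$vertices[m$faces[i, ], ]),
                 tolerance = 1e-6)
  expect_error(write_stl(list(faces = matrix(0L, 0, 3)), tempfile()),
               "empty")
  expect_error(write_stl(m, file.path(tempdir(), "no_dir", "x.stl")),
               "cannot open")
})
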