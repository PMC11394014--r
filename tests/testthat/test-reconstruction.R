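test_that("the ramp filter kills DC, matches the DFT oracle and is linear", {
  const <- matrix(3, 8, 32)
  out <- ramlak_filter(const, pitch = 1)
  expect_lt(max(abs(out)), 1e-6 * 3)

  # impulse response equals the analytic ramp kernel up to discretization:
  # value 1/4 at the centre, -1/pi^2 at +-1, ~0 at even offsets
  m <- matrix(0, 4, 64); m[2, 33] <- 1
  f <- ramlak_filter(m, pitch = 1)
  expect_equal(f[2, 33], 0.25, tolerance = 1e-9)
  expect_equal(f[2, 32], -1 / pi^2, tolerance = 1e-3)
  expect_equal(f[2, 34], -1 / pi^2, tolerance = 1e-3)
  expect_lt(abs(f[2, 31]), 1e-3)

  # against the explicit DFT-matrix oracle, line by line
  set.seed(1)
  r <- matrix(rnorm(3 * 32), 3)
  fr <- ramlak_filter(r, pitch = 2)
  for (i in 1:3)
    expect_equal(fr[i, ], ramlak_line_oracle(r[i, ], pitch = 2),
                 tolerance = 1e-9)

  # linearity
  a <- matrix(rnorm(3 * 32), 3); b <- matrix(rnorm(3 * 32), 3)
  expect_lt(max(abs(ramlak_filter(a + b, 1) - ramlak_filter(a, 1) -
                      ramlak_filter(b, 1))), 1e-9)
})

test_that("single-angle unfiltered backprojection is the shifted projection", {
  g <- small_geometry(n_projections = 1L)
  set.seed(2)
  img <- matrix(rnorm(32 * 48), 32)
  ps <- structure(list(images = array(img, c(32, 48, 1)), angles_deg = 0,
                       geometry = g), class = "projection_set")
  vol <- backproject(ps, 10, filtered = FALSE)
  # angle 0: zero shift, slice equals the projection exactly
  expect_equal(vol$slices[, , 1], img)
})

test_that("unfiltered backprojection of all-ones projections is one in the interior", {
  g <- small_geometry(n_projections = 5L)
  ps <- structure(list(images = array(1, c(32, 48, 5)),
                       angles_deg = projection_angles(g), geometry = g),
                  class = "projection_set")
  vol <- backproject(ps, 20, filtered = FALSE)
  sl <- vol$slices[, , 1]
  # shifts at 20 mm are < 3 px; away from the shifted-in border it is 1
  expect_equal(sl[, 6:43], matrix(1, 32, 38), tolerance = 1e-12)
})

test_that("a point phantom focuses on its own plane and blurs off-focus", {
  g <- acquisition_geometry(n_projections = 15L, detector_shape = c(64L, 128L),
                            pixel_pitch = 0.5)
  ph <- list(volume = array(0, c(64, 128, 16)), voxel_size = 2)
  ph$volume[32, 64, 8] <- 1                     # point at z = 15 mm
  angs <- projection_angles(g)
  imgs <- array(0, c(64, 128, 15))
  for (i in 1:15) imgs[, , i] <- project(ph, g, angs[i])
  ps <- structure(list(images = imgs, angles_deg = angs, geometry = g),
                  class = "projection_set")
  heights <- seq(1, 31, by = 2)
  vol <- backproject(ps, heights, filtered = TRUE)
  focus <- in_focus_plane(vol, 15)
  expect_equal(attr(focus, "height_mm"), 15)
  pk <- which(focus == max(focus), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(32, 64))

  # sweep-axis FWHM strictly smaller in focus than >= 2 plane spacings away
  fw_in <- profile_fwhm(focus[32, ])
  for (off in c(-6, -4, 4, 6)) {
    k <- which(vol$heights_mm == 15 + off)
    expect_gt(profile_fwhm(vol$slices[32, , k]), fw_in)
  }
})

test_that("backprojection is the adjoint of the forward model", {
  g <- small_geometry(n_projections = 5L)
  set.seed(3)
  vox <- 4
  x <- list(volume = array(rnorm(32 * 48 * 6), c(32, 48, 6)),
            voxel_size = vox)
  y <- array(rnorm(32 * 48 * 5), c(32, 48, 5))
  angs <- projection_angles(g)
  lhs <- 0
  for (i in 1:5) lhs <- lhs + sum(project(x, g, angs[i]) * y[, , i])
  ps <- structure(list(images = y, angles_deg = angs, geometry = g),
                  class = "projection_set")
  bp <- backproject(ps, (1:6 - 0.5) * vox, filtered = FALSE)
  rhs <- sum(x$volume * bp$slices) * 5 * vox     # n_angles * voxel_size
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("FBP is linear in the projections", {
  g <- small_geometry(n_projections = 3L)
  set.seed(4)
  mk <- function(arr) structure(list(images = arr,
                                     angles_deg = projection_angles(g),
                                     geometry = g), class = "projection_set")
  a <- array(rnorm(32 * 48 * 3), c(32, 48, 3))
  b <- array(rnorm(32 * 48 * 3), c(32, 48, 3))
  va <- backproject(mk(a), c(10, 20))$slices
  vb <- backproject(mk(b), c(10, 20))$slices
  vab <- backproject(mk(a + b), c(10, 20))$slices
  expect_equal(vab, va + vb, tolerance = 1e-9)
})

test_that("in-focus plane selection takes the nearest height, lower on ties", {
  g <- small_geometry(n_projections = 1L)
  ps <- structure(list(images = array(1, c(32, 48, 1)), angles_deg = 0,
                       geometry = g), class = "projection_set")
  vol <- backproject(ps, c(5, 10, 15), filtered = FALSE)
  expect_equal(attr(in_focus_plane(vol, 10), "height_mm"), 10)
  expect_equal(attr(in_focus_plane(vol, 11), "height_mm"), 10)  # nearer
  expect_equal(attr(in_focus_plane(vol, 7.5), "height_mm"), 5)  # tie: lower
  v1 <- backproject(ps, 5, filtered = FALSE)
  expect_equal(attr(in_focus_plane(v1, 99), "height_mm"), 5)
})
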