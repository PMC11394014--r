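test_that("projection angles are evenly spaced and symmetric about zero", {
  g <- small_geometry(n_projections = 15L)
  a <- projection_angles(g)
  expect_length(a, 15L)
  expect_equal(a, -rev(a))
  expect_equal(diff(a), rep(15 / 14, 14))
  expect_equal(range(a), c(-7.5, 7.5))
  g1 <- small_geometry(n_projections = 1L)
  expect_equal(projection_angles(g1), 0)
})

test_that("phantoms are reproducible and respect requested object counts", {
  p1 <- make_phantom(c(32, 48, 8), "dense", n_masses = 2L, n_mcs = 2L,
                     seed = 7L)
  p2 <- make_phantom(c(32, 48, 8), "dense", n_masses = 2L, n_mcs = 2L,
                     seed = 7L)
  expect_identical(p1$volume, p2$volume)
  expect_identical(p1$label_map, p2$label_map)

  p0 <- make_phantom(c(32, 48, 8), "non_dense", n_masses = 0L, n_mcs = 0L,
                     seed = 1L)
  expect_false(any(p0$label_map == 3L))
  expect_false(any(p0$label_map == 4L))

  # connected-component oracle on the mass label
  expect_equal(count_components_3d(p1$label_map == 3L), 2L)
  expect_error(make_phantom(c(0, 4, 4)), "positive")
})

test_that("dense phantoms have a larger fibroglandular fraction", {
  pd <- make_phantom(c(32, 48, 8), "dense", 0L, 0L, seed = 3L)
  pn <- make_phantom(c(32, 48, 8), "non_dense", 0L, 0L, seed = 3L)
  frac <- function(p) sum(p$label_map == 2L) / sum(p$label_map != 0L)
  expect_gt(frac(pd), frac(pn))
  expect_true(all(pd$volume >= 0))
  expect_true(all(pd$volume[pd$label_map == 0L] == 0))
  expect_identical(dim(pd$volume), dim(pd$label_map))
})

test_that("forward projection matches the explicit ray-sum oracle", {
  g <- small_geometry()
  # all-zero phantom projects to zero
  ph0 <- list(volume = array(0, c(32, 48, 6)), voxel_size = 2)
  expect_equal(project(ph0, g, 0), matrix(0, 32, 48))

  # single unit voxel at the rotation-centre height, angle 0: one nonzero
  # pixel whose value is the path length through the voxel
  zc <- rotation_center_height(g)                  # 40 mm
  vox <- 2
  k <- round(zc / vox + 0.5)                       # plane centred at zc
  ph <- list(volume = array(0, c(32, 48, 32)), voxel_size = vox)
  ph$volume[16, 24, k] <- 1
  p <- project(ph, g, 0)
  expect_equal(sum(p != 0), 1L)
  expect_equal(p[16, 24], vox)

  # angle outside the arc errors
  expect_error(project(ph, g, 20), "arc")
})

test_that("mirrored phantoms project to mirrored images at the opposite angle", {
  g <- small_geometry()
  ph <- make_phantom(c(32, 48, 6), "dense", 1L, 1L, seed = 5L, voxel_size = 2)
  phm <- ph
  phm$volume <- ph$volume[, rev(seq_len(48)), , drop = FALSE]
  a <- g$arc_deg / 2
  expect_equal(project(phm, g, a), flip_horizontal(project(ph, g, -a)),
               tolerance = 1e-12)
})

test_that("noiseless projection is linear in the attenuation map", {
  g <- small_geometry()
  set.seed(2)
  v1 <- array(abs(rnorm(32 * 48 * 6)), c(32, 48, 6))
  v2 <- array(abs(rnorm(32 * 48 * 6)), c(32, 48, 6))
  ph <- function(v) list(volume = v, voxel_size = 2)
  lhs <- project(ph(2 * v1 + 3 * v2), g, 4)
  rhs <- 2 * project(ph(v1), g, 4) + 3 * project(ph(v2), g, 4)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
})

test_that("dose indices follow the deviation-index definition", {
  img <- matrix(5, 16, 16)
  di <- compute_dose_indices(img, EI_target = 5)
  expect_equal(di$EI, 5)
  expect_equal(di$DI, 0)
  di10 <- compute_dose_indices(img, EI_target = 0.5)
  expect_equal(di10$DI, 10)
  # DI identity holds to 1e-9 on arbitrary inputs
  set.seed(1)
  img2 <- matrix(runif(256, 1, 9), 16)
  d <- compute_dose_indices(img2, EI_target = 3, calibration = 2)
  expect_equal(d$DI, 10 * log10(d$EI / d$EI_target), tolerance = 1e-9)
  expect_error(compute_dose_indices(matrix(0, 4, 4), 1), "breast region")
})

test_that("simulated acquisitions are seeded, dose-scaled and label domains", {
  g <- small_geometry(n_projections = 3L, detector = c(64L, 128L),
                      pitch = 0.5)
  ph <- make_phantom(c(64, 128, 8), "dense", 1L, 2L, seed = 2L,
                     voxel_size = 2)
  a1 <- simulate_acquisition(ph, g, 500, seed = 1L)
  a2 <- simulate_acquisition(ph, g, 500, seed = 1L)
  expect_identical(a1$images, a2$images)

  # noise-disabled limit equals the noiseless projection per angle
  a0 <- simulate_acquisition(ph, g, 500, seed = 1L, noise = FALSE)
  for (i in 1:3)
    expect_equal(a0$images[, , i], project(ph, g, a0$angles_deg[i]))

  # 10:1 dose ratio gives ~10:1 exposure index (Poisson-averaged)
  hi <- simulate_acquisition(ph, g, 5000, seed = 2L)
  expect_equal(mean(hi$dose_indices$EI) / mean(a1$dose_indices$EI), 10,
               tolerance = 0.02)

  # low-dose set is the "object" domain with negative DI
  expect_identical(a1$dose_domain, "object")
  expect_identical(hi$dose_domain, "reference")
  expect_true(all(a1$dose_indices$DI < 0))
})

test_that("Poisson photon counts have variance close to their mean", {
  g <- small_geometry(n_projections = 1L, detector = c(128L, 128L),
                      pitch = 0.5)
  ph <- make_phantom(c(128, 128, 8), "dense", 0L, 0L, seed = 3L,
                     voxel_size = 2)
  L <- project(ph, g, 0)
  lam <- 1000 * exp(-L)
  set.seed(10)
  counts <- matrix(rpois(length(lam), lam), nrow(lam))
  sel <- lam > 100                     # pooled over > 1e4 pixels
  expect_gt(sum(sel), 1e4)
  expect_equal(var(counts[sel] - lam[sel]) / mean(lam[sel]), 1,
               tolerance = 0.05)
})
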