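test_that("MSCN coefficients vanish on constants and match the window oracle", {
  expect_equal(mscn(matrix(5, 32, 32)), matrix(0, 32, 32))

  # affine invariance up to the stabilising constant: rescale image by a,
  # rescale C by a, coefficients are unchanged
  set.seed(1)
  img <- blob_image(48, 48, seed = 1) * 100
  m1 <- mscn(img, C = 1)
  m2 <- mscn(5 * img + 11, C = 5)
  expect_equal(m1, m2, tolerance = 1e-9)

  # one interior pixel against a brute-force windowed loop
  k <- dbtgan:::gaussian_kernel(7)
  r0 <- 20; c0 <- 25
  win <- img[(r0 - 3):(r0 + 3), (c0 - 3):(c0 + 3)]
  mu <- sum(k * win)
  sg <- sqrt(max(sum(k * win^2) - mu^2, 0))
  expect_equal(m1[r0, c0], (img[r0, c0] - mu) / (sg + 1), tolerance = 1e-9)
  expect_error(mscn(matrix(0, 8, 8)), "32")
})

test_that("PIQE scores are bounded and rank noise-corrupted images higher", {
  base <- blob_image(128, 128, seed = 4)
  set.seed(4)
  noisy <- base + matrix(rnorm(128 * 128, sd = 0.15), 128)
  p_clean <- piqe(base)
  p_noisy <- piqe(noisy)
  for (p in list(p_clean, p_noisy)) {
    expect_gte(p$score, 0)
    expect_lte(p$score, 100)
    expect_true(all(p$block_class_map %in%
                      c("undistorted", "distorted_artifact",
                        "distorted_noise")))
  }
  expect_gt(p_noisy$score, p_clean$score)
  expect_error(piqe(matrix(0, 8, 8)), "block")
})

test_that("pure i.i.d. noise blocks are predominantly classified as noise", {
  set.seed(7)
  p <- piqe(matrix(rnorm(128 * 128), 128))
  active <- sum(p$block_class_map != "undistorted")
  expect_gt(active, 0)
  expect_gte(sum(p$block_class_map == "distorted_noise") / active, 0.5)
})

test_that("the co-occurrence matrix is normalised, symmetric and matches enumeration", {
  img <- matrix(c(1, 2, 1,
                  2, 3, 2,
                  1, 2, 1), 3, byrow = TRUE)
  Tm <- glcm(img, levels = 3L)
  expect_equal(sum(Tm), 1, tolerance = 1e-9)
  expect_true(all(Tm >= 0))
  expect_equal(unclass(Tm), t(unclass(Tm)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # exhaustive pair-enumeration oracle on the quantised image
  q <- matrix(c(1, 2, 1, 2, 3, 2, 1, 2, 1), 3, byrow = TRUE)
  expect_equal(unclass(Tm), glcm_oracle(q, 3L), ignore_attr = TRUE)

  # constant image: single diagonal entry equal to 1
  Tc <- glcm(matrix(7, 5, 5), levels = 8L)
  expect_equal(sum(Tc != 0), 1L)
  expect_equal(Tc[1, 1], 1)

  set.seed(2)
  rimg <- matrix(runif(400), 20)
  Tr <- glcm(rimg, 16L)
  expect_equal(sum(Tr), 1, tolerance = 1e-9)
  expect_equal(unclass(Tr), t(unclass(Tr)), ignore_attr = TRUE)
})

test_that("homogeneity and contrast follow their closed forms", {
  Tc <- glcm(matrix(7, 5, 5), levels = 8L)
  expect_equal(glcm_homogeneity(Tc), 1)
  expect_equal(glcm_contrast(Tc), 0)

  # all mass at |i - j| = 1 gives homogeneity 1/2; at |i - j| = 2, contrast 4
  T1 <- matrix(0, 4, 4); T1[1, 2] <- T1[2, 1] <- 0.5
  expect_equal(glcm_homogeneity(T1), 0.5)
  T2 <- matrix(0, 4, 4); T2[1, 3] <- T2[3, 1] <- 0.5
  expect_equal(glcm_contrast(T2), 4)

  # random normalised matrix against loop oracles
  set.seed(3)
  Tr <- matrix(runif(64), 8); Tr <- Tr / sum(Tr)
  h <- 0; cs <- 0
  for (i in 1:8) for (j in 1:8) {
    h <- h + Tr[i, j] / (1 + abs(i - j))
    cs <- cs + (i - j)^2 * Tr[i, j]
  }
  expect_equal(glcm_homogeneity(Tr), h, tolerance = 1e-12)
  expect_equal(glcm_contrast(Tr), cs, tolerance = 1e-12)
  expect_error(glcm_homogeneity(matrix(1, 3, 3)), "normalised")
})

test_that("homogeneity falls and contrast rises with noise amplitude", {
  base <- blob_image(128, 128, seed = 4)
  hs <- c(); cs <- c()
  for (sd_ in c(0.02, 0.08, 0.2)) {
    set.seed(9)
    f <- glcm_features(base + matrix(rnorm(128 * 128, sd = sd_), 128), 64L)
    hs <- c(hs, f$homogeneity); cs <- c(cs, f$contrast)
  }
  expect_true(all(diff(hs) < 0))
  expect_true(all(diff(cs) > 0))
})

test_that("profile extraction follows the window convention", {
  img <- matrix(seq_len(64 * 96), 64, 96)
  prof <- extract_profiles(img, c(10, 20), width = 30L, n_profiles = 24L)
  expect_identical(dim(prof), c(24L, 30L))
  # each profile runs along the sweep (column) axis
  expect_identical(prof[1, ], img[10, 20:49])
  expect_identical(prof[24, ], img[33, 20:49])

  # constant window: constant profiles
  pc <- extract_profiles(matrix(2, 64, 96), c(1, 1), 30L, 24L)
  expect_true(all(pc == 2))

  # transposed image with swapped axes yields identical profiles
  pt <- extract_profiles(t(img), c(20, 10), 30L, 24L, sweep_axis = 1L)
  expect_identical(pt, prof)
  expect_error(extract_profiles(img, c(60, 90), 30L, 24L), "bounds")
})

test_that("maximal adjacent variation matches the loop oracle", {
  expect_equal(max_adjacent_variation(rep(4, 10)), 0)
  expect_equal(max_adjacent_variation(c(0, 1, 3, 2)), 2)
  set.seed(5)
  p <- rnorm(40)
  oracle <- 0
  for (k in 1:39) oracle <- max(oracle, abs(p[k + 1] - p[k]))
  expect_equal(max_adjacent_variation(p), oracle)
  expect_error(max_adjacent_variation(1), "2")
})

test_that("pearson_r reproduces exact correlations and the textbook formula", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(6)
  a <- rnorm(25); b <- rnorm(25)
  n <- 25
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$r, num / den, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("the Gumbel probability plot recovers exact quantile lines", {
  # plotting positions for l = 29
  f29 <- gumbel_fit(seq_len(29) / 29)
  expect_equal(f29$Q[1], 0.5 / 29, tolerance = 1e-10)
  expect_equal(f29$l, 29L)

  # maxima exactly on a Gumbel quantile line: exact parameter recovery
  l <- 29
  u <- -log(-log((seq_len(l) - 0.5) / l))
  x <- 2 + 0.5 * u
  fit <- gumbel_fit(sample(x))
  expect_equal(fit$location, 2, tolerance = 1e-9)
  expect_equal(fit$scale, 0.5, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 0.01)
  expect_error(gumbel_fit(c(1, 2)), "3")
})

test_that("Monte-Carlo draws recover the Gumbel parameters", {
  set.seed(11)
  mus <- numeric(500); rs <- numeric(500)
  for (rep in 1:500) {
    x <- 0.05 - 0.01 * log(-log(runif(29)))
    f <- gumbel_fit(x)
    mus[rep] <- f$location; rs[rep] <- f$pearson_r
  }
  expect_lt(abs(mean(mus) - 0.05) / 0.05, 0.1)
  expect_gt(mean(rs), 0.9)
})

test_that("low-dose reconstructions show larger streak maxima than high-dose", {
  g <- small_geometry(n_projections = 5L, detector = c(64L, 128L),
                      pitch = 0.5)
  ph <- make_phantom(c(64, 128, 8), "dense", 1L, 1L, seed = 8L,
                     voxel_size = 2)
  lo <- simulate_acquisition(ph, g, 200, seed = 21L)
  hi <- simulate_acquisition(ph, g, 20000, seed = 22L)
  sl_lo <- in_focus_plane(backproject(lo, 8), 8)
  sl_hi <- in_focus_plane(backproject(hi, 8), 8)
  origin <- c(18, 60)
  f_lo <- gumbel_streak_statistic(sl_lo, origin)
  f_hi <- gumbel_streak_statistic(sl_hi, origin)
  expect_gt(f_lo$mean_max, f_hi$mean_max)
  expect_equal(f_lo$l, 29L)
})
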