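test_that("attention gate with zero maps scales by exactly one half", {
  set.seed(1)
  y <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  omega <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  params <- list(W_y = matrix(0, 3, 2), W_omega = matrix(0, 3, 2),
                 psi = matrix(0, 2, 1))
  r <- attention_gate(y, omega, params)
  expect_equal(r$beta, matrix(0.5, 8, 8))
  expect_equal(r$output, 0.5 * y)
})

test_that("attention coefficients are strictly inside (0, 1)", {
  set.seed(2)
  for (i in 1:5) {
    y <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    omega <- array(rnorm(8 * 8 * 4), c(8, 8, 4))   # coarser grid, resampled
    params <- list(W_y = matrix(rnorm(2 * 3), 2),
                   W_omega = matrix(rnorm(4 * 3), 4),
                   psi = matrix(rnorm(3), 3))
    r <- attention_gate(y, omega, params)
    expect_true(all(r$beta > 0 & r$beta < 1))
    # strict attenuation bound: |output| <= |y| elementwise
    expect_true(all(abs(r$output) <= abs(y)))
  }
})

test_that("scalar attention gate matches hand evaluation", {
  y <- matrix(c(0.5, -1, 2, 0), 2)
  omega <- matrix(c(1, 1, -3, 0.5), 2)
  r <- attention_gate(y, omega, list(W_y = 1, W_omega = 1, psi = 1))
  beta_hand <- 1 / (1 + exp(-pmax(y + omega, 0)))
  expect_equal(r$beta, beta_hand, tolerance = 1e-12)
  expect_equal(r$output[, , 1], y * beta_hand, tolerance = 1e-12)
})

test_that("SE block reweights channels through the bottleneck sigmoid", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  zero <- list(W1 = matrix(0, 4, 2), W2 = matrix(0, 2, 4))
  r0 <- se_block(x, zero)
  expect_equal(r0$weights, rep(0.5, 4))
  expect_equal(r0$output, 0.5 * x)

  # identical channels through channel-symmetric maps get identical weights
  xc <- array(rep(matrix(rnorm(36), 6), 4), c(6, 6, 4))
  rp <- se_block(xc, list(W1 = matrix(1, 4, 2), W2 = matrix(0.5, 2, 4)))
  expect_equal(max(rp$weights) - min(rp$weights), 0, tolerance = 1e-12)

  # 2-channel toy against closed-form evaluation
  x2 <- array(0, c(2, 2, 2))
  x2[, , 1] <- 1; x2[, , 2] <- -2
  W1 <- matrix(c(1, 0.3), 2, 1); W2 <- matrix(c(2, -1), 1, 2)
  r2 <- se_block(x2, list(W1 = W1, W2 = W2))
  h <- max(1 * 1 + (-2) * 0.3, 0)                 # squeeze = (1, -2)
  expect_equal(r2$weights, 1 / (1 + exp(-c(2, -1) * h)), tolerance = 1e-12)
  expect_true(all(r2$weights > 0 & r2$weights < 1))
})

test_that("generators keep the patch shape and expose the declared modules", {
  spec <- generator_spec("rSEAG", depth = 2L, base_channels = 4L,
                         se_reduction = 2L)
  g <- build_generator(spec, seed = 1L)
  x <- array(rnorm(128 * 128), c(128, 128, 1, 1))
  y <- g$forward(x)
  expect_identical(dim(y), c(128L, 128L, 1L, 1L))

  expect_identical(g$n_attention_gates, 2L)
  expect_identical(g$n_se_blocks, 1L)
  u <- build_generator(generator_spec("U-Net", depth = 2L,
                                      base_channels = 4L), seed = 1L)
  expect_identical(u$n_attention_gates, 0L)
  expect_identical(u$n_se_blocks, 0L)
  expect_identical(u$n_residual_blocks, 0L)

  r <- build_generator(generator_spec("ResUNet", depth = 2L,
                                      base_channels = 4L), seed = 1L)
  expect_identical(r$n_attention_gates, 0L)
  expect_gt(r$n_residual_blocks, 0L)

  # parameter-count ordering: rSEAG > same-depth ResUNet > 0
  expect_gt(count_params(g), count_params(r))
  expect_gt(count_params(r), 0)

  # deterministic initialization and forward pass
  g2 <- build_generator(spec, seed = 1L)
  expect_identical(g2$forward(x), y)
})

test_that("all generator kinds share the trainer I/O contract", {
  x <- array(rnorm(32 * 32), c(32, 32, 1, 2))
  for (kind in c("rSEAG", "ResUNet", "U-Net")) {
    net <- build_generator(generator_spec(kind, depth = 2L,
                                          base_channels = 4L,
                                          se_reduction = 2L), seed = 2L)
    y <- net$forward(x)
    expect_identical(dim(y), dim(x))
    gx <- net$backward(y)
    expect_identical(dim(gx), dim(x))
  }
})

test_that("generator backward pass matches finite differences", {
  spec <- generator_spec("rSEAG", depth = 2L, base_channels = 4L,
                         se_reduction = 2L)
  g <- build_generator(spec, seed = 3L)
  set.seed(4)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  y <- g$forward(x)
  gx <- g$backward(y)                       # gradient of sum(y^2)/2 w.r.t. x
  e <- 1e-5
  for (i in sample(length(x), 4)) {
    x1 <- x; x1[i] <- x1[i] + e
    x2 <- x; x2[i] <- x2[i] - e
    num <- (sum(g$forward(x1)^2) - sum(g$forward(x2)^2)) / (4 * e)
    expect_equal(gx[i], num, tolerance = 1e-4)
  }
  # parameter gradient on the first conv layer
  pl <- dbtgan:::collect_param_layers(g)[[1]]
  dbtgan:::zero_grads(g)
  g$backward(g$forward(x))
  an <- pl$grad$w[3]
  w0 <- pl$par$w[3]
  pl$par$w[3] <- w0 + e; f1 <- sum(g$forward(x)^2) / 2
  pl$par$w[3] <- w0 - e; f2 <- sum(g$forward(x)^2) / 2
  pl$par$w[3] <- w0
  expect_equal(an, (f1 - f2) / (2 * e), tolerance = 1e-4)
})

test_that("the PatchGAN discriminator emits a spatial score map", {
  spec <- discriminator_spec(base_channels = 8L, n_layers = 2L)
  d <- build_discriminator(spec, seed = 3L)
  x <- array(rnorm(128 * 128), c(128, 128, 1, 1))
  sc <- d$forward(x)
  expect_gt(dim(sc)[1], 1L)
  expect_gt(dim(sc)[2], 1L)

  # constant input: interior of the score map is spatially constant
  cst <- array(0.7, c(64, 64, 1, 1))
  m <- d$forward(cst)[, , 1, 1]
  interior <- m[4:(nrow(m) - 3), 4:(ncol(m) - 3)]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-10)

  d2 <- build_discriminator(spec, seed = 3L)
  expect_identical(d2$forward(x), sc)
})
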