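# Training losses.  Exported functions give the scalar values; internal
# *_with_grad variants also return the gradient with respect to their first
# argument, which is what the trainer backpropagates.

#' Mean squared error between two images
#' @param a,b Numeric arrays of identical shape.
#' @return Scalar mean of squared differences.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stopf("mse: shapes differ")
  mean((a - b)^2)
}

#' Cycle-consistency loss (mean absolute difference)
#' @param x Original batch.
#' @param x_cycled Batch after translating to the other domain and back.
#' @return Scalar L1 loss.
#' @export
cycle_consistency_loss <- function(x, x_cycled) {
  if (!identical(dim(x), dim(x_cycled)) || length(x) != length(x_cycled))
    stopf("cycle_consistency_loss: shapes differ")
  mean(abs(x - x_cycled))
}

cycle_loss_grad <- function(x_cycled, x) {
  list(loss = mean(abs(x - x_cycled)),
       grad = sign(x_cycled - x) / length(x))
}

#' Least-squares adversarial loss
#'
#' LSGAN objective on a PatchGAN score map: mean squared deviation of the
#' scores from the target label (1 for real, 0 for fake).
#'
#' @param scores Numeric array of discriminator scores.
#' @param is_real_target Logical; `TRUE` targets the "real" label 1.
#' @return Scalar loss.
#' @export
adversarial_loss <- function(scores, is_real_target) {
  if (any(!is.finite(scores))) stopf("adversarial_loss: non-finite scores")
  target <- if (isTRUE(is_real_target)) 1 else 0
  mean((scores - target)^2)
}

adversarial_loss_grad <- function(scores, is_real_target) {
  target <- if (isTRUE(is_real_target)) 1 else 0
  list(loss = mean((scores - target)^2),
       grad = 2 * (scores - target) / length(scores))
}

# Normalised Gaussian window used by SSIM (and by the MSCN transform).
gaussian_kernel <- function(size = 7L, sigma = size / 6) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# "Same"-size Gaussian filtering of a (H, W, 1, N) tensor via the conv kernel;
# the kernel is symmetric, so the operator is self-adjoint (used by the SSIM
# gradient).
gfilter <- function(x, kern) {
  x <- as_tensor(x)
  k <- length(kern[, 1])
  w <- array(kern, c(k, k, 1L, 1L))
  conv2d_fwd_cpp(x, dim(x), w, dim(w), 0, 1L, (k - 1L) %/% 2L)
}

ssim_with_grad <- function(a, b, data_range = NULL, window = 7L) {
  if (!identical(dim(a), dim(b))) stopf("ssim: shapes differ")
  if (is.null(data_range)) {
    data_range <- diff(range(c(a, b)))
    if (data_range == 0) data_range <- 1
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  kern <- gaussian_kernel(window)
  x <- as_tensor(a); y <- as_tensor(b)
  mux <- gfilter(x, kern); muy <- gfilter(y, kern)
  sxx <- gfilter(x * x, kern) - mux^2
  syy <- gfilter(y * y, kern) - muy^2
  sxy <- gfilter(x * y, kern) - mux * muy
  A1 <- 2 * mux * muy + C1; A2 <- 2 * sxy + C2
  B1 <- mux^2 + muy^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  n <- length(S)
  dS_dmux <- (2 * muy * A2) / (B1 * B2) - (2 * mux * A1 * A2) / (B1^2 * B2)
  dS_dsxx <- -(A1 * A2) / (B1 * B2^2)
  dS_dsxy <- (2 * A1) / (B1 * B2)
  Gmu <- dS_dmux - 2 * mux * dS_dsxx - muy * dS_dsxy
  grad_ssim <- (gfilter(Gmu, kern) + 2 * x * gfilter(dS_dsxx, kern) +
                  y * gfilter(dS_dsxy, kern)) / n
  list(ssim = mean(S), loss = 1 - mean(S), grad = -grad_ssim)
}

#' SSIM fidelity loss
#'
#' `1 - SSIM(a, b)` with the standard structural-similarity constants
#' (`C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L`) computed over
#' a 7x7 Gaussian window; zero for identical images, bounded by \[0, 2\], and
#' symmetric in its arguments.
#'
#' @param a,b Numeric matrices/arrays of identical shape.
#' @param data_range Dynamic range `L`; defaults to the joint range of the
#'   inputs (1 if both are constant).
#' @return Scalar loss.
#' @export
ssim_fidelity_loss <- function(a, b, data_range = NULL) {
  ssim_with_grad(a, b, data_range)$loss
}

#' Optimal training epoch from a validation-MSE curve
#'
#' Returns the 1-based index of the minimum of the per-epoch validation MSE;
#' ties resolve to the earliest epoch.
#'
#' @param mse_curve Numeric vector of per-epoch validation MSE values.
#' @return Integer epoch index.
#' @export
select_optimal_epoch <- function(mse_curve) {
  if (length(mse_curve) == 0L) stopf("empty MSE curve")
  if (any(!is.finite(mse_curve))) stopf("non-finite MSE curve")
  which.min(mse_curve)
}
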