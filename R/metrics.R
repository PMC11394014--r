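# No-reference quality instruments: MSCN/PIQE block distortion, GLCM texture
# features, and the Gumbel extreme-value statistic of streak artifacts.

pad_replicate <- function(m, k) {
  r <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  c_ <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[r, c_, drop = FALSE]
}

# Gaussian smoothing with edge-replication padding (so constant images stay
# exactly constant).
gsmooth <- function(m, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  p <- pad_replicate(m, k)
  x <- array(p, c(dim(p), 1L, 1L))
  w <- array(kern, c(dim(kern), 1L, 1L))
  y <- conv2d_fwd_cpp(x, dim(x), w, dim(w), 0, 1L, 0L)
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Mean-subtracted contrast-normalised (MSCN) coefficients
#'
#' `(I - mu) / (sigma + C)` with `mu` and `sigma` the local Gaussian-window
#' mean and standard deviation (7x7 window, edge-replicated borders). A
#' constant image maps to exactly zero; up to the stabilising constant `C`
#' the transform is invariant to global affine rescaling.
#'
#' @param image 2-D numeric matrix, at least 32 x 32.
#' @param window Gaussian window size (odd).
#' @param C Stabilising constant added to the local standard deviation.
#' @return Matrix of MSCN coefficients, same shape.
#' @export
mscn <- function(image, window = 7L, C = 1) {
  check_matrix(image, "image")
  if (any(dim(image) < 32L)) stopf("image must be at least 32 x 32")
  kern <- gaussian_kernel(window)
  mu <- gsmooth(image, kern)
  sigma <- sqrt(pmax(gsmooth(image^2, kern) - mu^2, 0))
  (image - mu) / (sigma + C)
}

#' PIQE-style no-reference block-distortion score
#'
#' The image is first min-max rescaled to the 8-bit range 0-255 (the scale
#' the MSCN stabilising constant `C = 1` assumes). The MSCN coefficient
#' image is tiled into 16x16 blocks; blocks whose
#' MSCN variance exceeds the spatial-activity threshold (0.1) are active, and
#' classifies each active block as `distorted_artifact` (some length-6
#' segment along a block edge is near-uniform, the blockiness signature) or
#' `distorted_noise` (block MSCN variance above the noise threshold).
#' The score is `100 * sum(distortion) / (n_distorted + 1)` with unit
#' distortion per distorted block — in \[0, 100\), lower is better.
#'
#' @param image 2-D numeric matrix, at least 16 x 16.
#' @param block_size Block side (default 16).
#' @param activity_threshold MSCN block-variance threshold for activity.
#' @param artifact_threshold Edge-segment standard-deviation threshold.
#' @param noise_threshold MSCN block-variance threshold for the noise class.
#' @return Object of class `"piqe_result"`: `score`, `block_class_map`
#'   (character matrix: `undistorted` / `distorted_artifact` /
#'   `distorted_noise`), `block_variance`, `mscn`.
#' @export
piqe <- function(image, block_size = 16L, activity_threshold = 0.1,
                 artifact_threshold = 0.1, noise_threshold = 0.5) {
  check_matrix(image, "image")
  if (any(dim(image) < block_size))
    stopf("image smaller than one %d x %d block", block_size, block_size)
  rng <- range(image)
  img8 <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) * 255
          else image * 0
  msc <- mscn(img8)
  nbr <- nrow(msc) %/% block_size
  nbc <- ncol(msc) %/% block_size
  classes <- matrix("undistorted", nbr, nbc)
  vmap <- matrix(0, nbr, nbc)
  seg_len <- 6L
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    blk <- msc[((i - 1L) * block_size + 1L):(i * block_size),
               ((j - 1L) * block_size + 1L):(j * block_size)]
    v <- mean(blk^2) - mean(blk)^2
    vmap[i, j] <- v
    if (v <= activity_threshold) next
    edges <- list(blk[1L, ], blk[block_size, ], blk[, 1L], blk[, block_size])
    artifact <- FALSE
    for (e in edges) {
      for (s in seq_len(block_size - seg_len + 1L)) {
        seg <- e[s:(s + seg_len - 1L)]
        if (sd(seg) < artifact_threshold) { artifact <- TRUE; break }
      }
      if (artifact) break
    }
    if (artifact) classes[i, j] <- "distorted_artifact"
    else if (v > noise_threshold) classes[i, j] <- "distorted_noise"
  }
  n_dist <- sum(classes != "undistorted")
  score <- 100 * n_dist / (n_dist + 1)
  structure(list(score = score, block_class_map = classes,
                 block_variance = vmap, mscn = msc,
                 block_size = block_size),
            class = "piqe_result")
}

#' @export
print.piqe_result <- function(x, ...) {
  tab <- table(factor(x$block_class_map,
                      levels = c("undistorted", "distorted_artifact",
                                 "distorted_noise")))
  cat(sprintf("PIQE score %.2f (lower is better); blocks: %s\n", x$score,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Grey-level co-occurrence matrix (8-neighbourhood, symmetric, normalised)
#'
#' Quantises the image to `levels` grey levels by linear min-max binning,
#' counts co-occurring level pairs over all 8 neighbour offsets, symmetrises
#' and normalises so the entries sum to one.
#'
#' @param image 2-D numeric matrix.
#' @param levels Number of grey levels (default 256).
#' @return `levels x levels` matrix of class `"glcm_matrix"`.
#' @export
glcm <- function(image, levels = 256L) {
  check_matrix(image, "image")
  if (length(image) == 0L) stopf("empty image")
  levels <- as.integer(levels)
  if (levels < 2L) stopf("'levels' must be >= 2")
  rng <- range(image)
  q <- if (rng[2] > rng[1])
    pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  else matrix(1L, nrow(image), ncol(image))
  storage.mode(q) <- "integer"
  dr <- c(0L, 0L, 1L, -1L, 1L, 1L, -1L, -1L)
  dc <- c(1L, -1L, 0L, 0L, 1L, -1L, 1L, -1L)
  counts <- glcm_counts_cpp(q, levels, dr, dc)
  counts <- (counts + t(counts)) / 2
  Tm <- counts / sum(counts)
  class(Tm) <- c("glcm_matrix", class(Tm))
  attr(Tm, "levels") <- levels
  Tm
}

check_glcm <- function(Tm) {
  if (!is.matrix(Tm) || nrow(Tm) != ncol(Tm))
    stopf("'T' must be a square co-occurrence matrix")
  if (any(Tm < 0) || abs(sum(Tm) - 1) > 1e-6)
    stopf("'T' must be normalised (non-negative, summing to 1)")
  invisible(Tm)
}

#' GLCM homogeneity
#'
#' `sum_ij T(i,j) / (1 + |i - j|)`: closeness of the co-occurrence mass to
#' the diagonal; 1 for a constant image, smaller under noise.
#'
#' @param T Normalised co-occurrence matrix from [glcm()].
#' @return Scalar in (0, 1].
#' @export
glcm_homogeneity <- function(T) {
  check_glcm(T)
  n <- nrow(T)
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  sum(T / (1 + idx))
}

#' GLCM contrast
#'
#' `sum_ij (i - j)^2 T(i,j)`: mean squared grey-level difference between
#' neighbours; 0 for a constant image, growing with pixel-to-pixel variation.
#'
#' @param T Normalised co-occurrence matrix from [glcm()].
#' @return Non-negative scalar.
#' @export
glcm_contrast <- function(T) {
  check_glcm(T)
  n <- nrow(T)
  idx <- outer(seq_len(n), seq_len(n), "-")
  sum(idx^2 * T)
}

#' GLCM texture features of an image
#'
#' Convenience wrapper returning the matrix together with homogeneity and
#' contrast.
#'
#' @inheritParams glcm
#' @return List with `T`, `homogeneity`, `contrast`, `levels`.
#' @export
glcm_features <- function(image, levels = 256L) {
  Tm <- glcm(image, levels)
  list(T = Tm, homogeneity = glcm_homogeneity(Tm),
       contrast = glcm_contrast(Tm), levels = levels)
}

#' Parallel pixel-value profiles in a rectangular window
#'
#' Places a window at `origin` (top-left, 1-based) and extracts parallel
#' profiles running along the X-ray sweep direction at 1-pixel intervals:
#' `n_profiles` lines of `width` samples each, one per pixel of the
#' cross-sweep extent.
#'
#' @param image 2-D numeric matrix.
#' @param origin Integer pair: top-left (row, col) of the window.
#' @param width Samples per profile, along the sweep axis (default 30).
#' @param n_profiles Number of parallel profiles (window extent across the
#'   sweep; default 24).
#' @param sweep_axis Sweep direction (1 = rows, 2 = cols).
#' @return `n_profiles x width` matrix, one profile per row.
#' @export
extract_profiles <- function(image, origin, width = 30L, n_profiles = 24L,
                             sweep_axis = 2L) {
  check_matrix(image, "image")
  origin <- as.integer(origin)
  width <- as.integer(width); n_profiles <- as.integer(n_profiles)
  if (length(origin) != 2L || any(origin < 1L))
    stopf("'origin' must be a positive (row, col) pair")
  if (width < 2L || n_profiles < 1L) stopf("degenerate window")
  if (sweep_axis == 2L) {
    r1 <- origin[1] + n_profiles - 1L; c1 <- origin[2] + width - 1L
    if (r1 > nrow(image) || c1 > ncol(image)) stopf("window out of bounds")
    image[origin[1]:r1, origin[2]:c1, drop = FALSE]
  } else {
    r1 <- origin[1] + width - 1L; c1 <- origin[2] + n_profiles - 1L
    if (r1 > nrow(image) || c1 > ncol(image)) stopf("window out of bounds")
    t(image[origin[1]:r1, origin[2]:c1, drop = FALSE])
  }
}

#' Maximal adjacent variation of a profile
#'
#' Largest absolute difference between adjacent samples.
#'
#' @param profile Numeric vector of length >= 2.
#' @return Scalar maximum adjacent difference.
#' @export
max_adjacent_variation <- function(profile) {
  if (length(profile) < 2L) stopf("profile must have at least 2 samples")
  max(abs(diff(profile)))
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("lengths differ")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Gumbel fit of profile maxima by the symmetry-rank probability plot
#'
#' Sorts the maxima ascending, assigns plotting positions
#' `Q = (rank - 0.5) / l`, maps them to the reduced variate
#' `u = -log(-log(Q))`, and fits the least-squares line
#' `x = location + scale * u`. Linearity of the plot (Pearson r of sorted
#' maxima against `u`) indicates Gumbel-distributed maxima; the fit also
#' reports `mean_max` with its standard error `sd / sqrt(l)`.
#'
#' @param maxima Numeric vector of per-profile maximal adjacent variations,
#'   length `l >= 3`.
#' @return Object of class `"gumbel_fit"`: `location`, `scale`,
#'   `pearson_r`, `p_value`, `Q`, `reduced_variate`, `sorted_maxima`,
#'   `mean_max`, `se_max`, `l`.
#' @export
gumbel_fit <- function(maxima) {
  if (length(maxima) < 3L) stopf("need at least 3 maxima")
  if (any(!is.finite(maxima))) stopf("non-finite maxima")
  l <- length(maxima)
  xs <- sort(maxima)
  Q <- (seq_len(l) - 0.5) / l
  u <- -log(-log(Q))
  fit <- stats::lm.fit(cbind(1, u), xs)
  r <- if (sd(xs) == 0) NA_real_ else cor(xs, u)
  p <- if (is.na(r) || abs(r) >= 1) 0 else {
    t <- r * sqrt((l - 2) / (1 - r^2))
    2 * pt(-abs(t), l - 2)
  }
  structure(list(location = unname(fit$coefficients[1]),
                 scale = unname(fit$coefficients[2]),
                 pearson_r = r, p_value = p,
                 Q = Q, reduced_variate = u, sorted_maxima = xs,
                 mean_max = mean(maxima), se_max = sd(maxima) / sqrt(l),
                 l = l),
            class = "gumbel_fit")
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf(
    "Gumbel fit (l = %d): location %.4g, scale %.4g, r = %.3f (p = %.3g)\n  mean max adjacent variation %.4g +/- %.4g\n",
    x$l, x$location, x$scale, x$pearson_r, x$p_value, x$mean_max, x$se_max))
  invisible(x)
}

#' Gumbel streak-artifact statistic of a reconstructed slice
#'
#' Full pipeline on one in-focus plane: extract parallel profiles in a
#' rectangular window oriented along the sweep direction, take each
#' profile's maximal adjacent variation, and fit the Gumbel probability
#' plot. The default window yields `l = 29` maxima.
#'
#' @inheritParams extract_profiles
#' @param n_profiles Number of profiles (sampling size `l`); default 29.
#' @return A [gumbel_fit()] object with the profile matrix attached as
#'   attribute `"profiles"`.
#' @export
gumbel_streak_statistic <- function(image, origin, width = 30L,
                                    n_profiles = 29L, sweep_axis = 2L) {
  prof <- extract_profiles(image, origin, width, n_profiles, sweep_axis)
  maxima <- apply(prof, 1L, max_adjacent_variation)
  fit <- gumbel_fit(maxima)
  attr(fit, "profiles") <- prof
  fit
}
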