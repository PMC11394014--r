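#' Two-stage image normalization
#'
#' Standardises an image to zero mean and unit spread, then affinely maps the
#' result to a fixed range: first `I_temp = (I - mean(I)) / sigma` with the
#' population standard deviation, then
#' `I_norm = 1 + (I_temp - min) / (max - min)`. The printed form of the
#' second stage (`mode = "as_printed"`, the default) lands exactly on the
#' range \[1, 2\]; `mode = "zero_one"` drops the unit offset and lands on
#' \[0, 1\].
#'
#' @param image 2-D numeric matrix with at least two distinct values.
#' @param mode `"as_printed"` (range \[1, 2\]) or `"zero_one"` (range \[0, 1\]).
#' @return Object of class `"normalized_image"`: list with `data`,
#'   `source_mean`, `source_sd` (population), `mode`.
#' @export
normalize_image <- function(image, mode = c("as_printed", "zero_one")) {
  check_matrix(image, "image")
  mode <- match.arg(mode)
  mu <- mean(image)
  sigma <- sqrt(mean((image - mu)^2))      # population SD
  if (sigma == 0) stopf("constant image: normalization is degenerate")
  temp <- (image - mu) / sigma
  rng <- range(temp)
  if (rng[2] == rng[1]) stopf("degenerate dynamic range")
  data <- (temp - rng[1]) / (rng[2] - rng[1])
  if (mode == "as_printed") data <- data + 1.0
  structure(list(data = data, source_mean = mu, source_sd = sigma,
                 mode = mode),
            class = "normalized_image")
}

#' Crop a projection to the analysis matrix
#'
#' Extracts a `target`-shaped window, by default anchored at the chest-wall
#' edge (column 1, the flat face of the compressed breast) and centred across
#' rows — mirroring the clinical practice of cropping a 2560 x 4096 panel
#' readout to a 1024 x 2048 analysis matrix.
#'
#' @param image 2-D numeric matrix.
#' @param target Integer pair `(rows, cols)`, each `<=` the image dimension.
#' @param anchor `"chest_wall"`, `"center"` or `"top_left"`.
#' @return The cropped matrix of dimension `target`.
#' @export
crop_projection <- function(image, target,
                            anchor = c("chest_wall", "center", "top_left")) {
  check_matrix(image, "image")
  anchor <- match.arg(anchor)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stopf("'target' must be two positive integers")
  d <- dim(image)
  if (any(target > d))
    stopf("crop target (%d x %d) exceeds image (%d x %d)",
          target[1], target[2], d[1], d[2])
  r0 <- switch(anchor,
               chest_wall = ,
               center = (d[1] - target[1]) %/% 2L + 1L,
               top_left = 1L)
  c0 <- switch(anchor,
               chest_wall = ,
               top_left = 1L,
               center = (d[2] - target[2]) %/% 2L + 1L)
  image[r0:(r0 + target[1] - 1L), c0:(c0 + target[2] - 1L), drop = FALSE]
}

#' Seeded random patch extraction with horizontal-flip augmentation
#'
#' Samples `n_patches` fully-interior square windows with uniform-random
#' origins (R's Mersenne-Twister stream via `sample.int`, so origins are
#' identical across runs and platforms for a fixed seed) and independently
#' mirrors each patch left-right with probability `flip_prob`.
#'
#' @param image 2-D numeric matrix.
#' @param n_patches Number of patches to draw (>= 1).
#' @param patch_size Side of the square patch in pixels.
#' @param flip_prob Probability of a horizontal flip in \[0, 1\].
#' @param seed Integer seed.
#' @param source_id Optional identifier recorded in the batch.
#' @return Object of class `"patch_batch"`: `patches` (patch_size x
#'   patch_size x n_patches array), `origins` (n x 2 matrix of top-left row,
#'   col), `flipped` (logical), `source_id`, `seed`, `patch_size`.
#' @export
extract_patches <- function(image, n_patches = 128L, patch_size = 128L,
                            flip_prob = 0.5, seed = 1L, source_id = "") {
  check_matrix(image, "image")
  n_patches <- as.integer(n_patches); patch_size <- as.integer(patch_size)
  if (n_patches < 1L) stopf("'n_patches' must be >= 1")
  d <- dim(image)
  if (patch_size < 1L || any(patch_size > d))
    stopf("patch size %d exceeds image (%d x %d)", patch_size, d[1], d[2])
  if (!is.numeric(flip_prob) || flip_prob < 0 || flip_prob > 1)
    stopf("'flip_prob' must be in [0, 1]")
  patches <- array(0, c(patch_size, patch_size, n_patches))
  origins <- matrix(0L, n_patches, 2L,
                    dimnames = list(NULL, c("row", "col")))
  flipped <- logical(n_patches)
  with_seed(seed, {
    origins[, 1L] <- sample.int(d[1] - patch_size + 1L, n_patches,
                                replace = TRUE)
    origins[, 2L] <- sample.int(d[2] - patch_size + 1L, n_patches,
                                replace = TRUE)
    flipped[] <- runif(n_patches) < flip_prob
  })
  for (i in seq_len(n_patches)) {
    p <- image[origins[i, 1L]:(origins[i, 1L] + patch_size - 1L),
               origins[i, 2L]:(origins[i, 2L] + patch_size - 1L)]
    if (flipped[i]) p <- flip_horizontal(p)
    patches[, , i] <- p
  }
  structure(list(patches = patches, origins = origins, flipped = flipped,
                 source_id = source_id, seed = as.integer(seed),
                 patch_size = patch_size),
            class = "patch_batch")
}

#' Mirror an image left-right
#'
#' Horizontal flip (column reversal); applying it twice restores the input
#' exactly.
#' @param image 2-D numeric matrix.
#' @return The mirrored matrix.
#' @export
flip_horizontal <- function(image) {
  image[, rev(seq_len(ncol(image))), drop = FALSE]
}

#' @export
print.patch_batch <- function(x, ...) {
  cat(sprintf("Patch batch: %d patches of %d x %d (%d flipped), seed %d\n",
              dim(x$patches)[3], x$patch_size, x$patch_size,
              sum(x$flipped), x$seed))
  invisible(x)
}
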