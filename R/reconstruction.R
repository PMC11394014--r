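#' Ramachandran-Lakshminarayanan (ramp) filtering of a projection
#'
#' Filters every detector line along the sweep axis with the ideal ramp
#' `|f|` in the frequency domain (zero response at DC, maximum at Nyquist,
#' even-symmetric), padding each line to at least twice its length by edge
#' replication to avoid circular wraparound (so a constant line filters to
#' zero exactly, and padding stays linear in the input). An optional Hann
#' apodization is available but off by default (the bare ramp is the
#' reference kernel).
#'
#' @param projection 2-D numeric matrix.
#' @param pitch Detector pixel pitch in mm (scales the frequency axis).
#' @param axis Axis along which lines run (1 = rows, 2 = cols); this is the
#'   sweep direction.
#' @param window `"none"` (bare ramp) or `"hann"`.
#' @return Filtered matrix of the same shape.
#' @export
ramlak_filter <- function(projection, pitch = 1, axis = 2L,
                          window = c("none", "hann")) {
  check_matrix(projection, "projection")
  check_scalar(pitch, "pitch", positive = TRUE)
  window <- match.arg(window)
  flip <- axis == 1L
  m <- if (flip) projection else t(projection)   # lines as columns
  n <- nrow(m)
  N <- 2^ceiling(log2(2L * n))
  pl <- (N - n) %/% 2L
  pr <- N - n - pl
  padded <- rbind(m[rep(1L, pl), , drop = FALSE], m,
                  m[rep(n, pr), , drop = FALSE])
  freqs <- c(seq(0, N / 2), seq(-N / 2 + 1, -1)) / (N * pitch)
  H <- abs(freqs)
  if (window == "hann")
    H <- H * 0.5 * (1 + cos(pi * freqs / max(abs(freqs))))
  Fm <- stats::mvfft(padded) * H
  out <- Re(stats::mvfft(Fm, inverse = TRUE)) / N
  out <- out[pl + seq_len(n), , drop = FALSE]
  if (flip) out else t(out)
}

#' Shift-and-add (filtered) backprojection
#'
#' Reconstructs planes at the requested heights above the detector: each
#' projection is laterally shifted along the sweep axis by minus the
#' parallax of that plane (sub-pixel, linear interpolation — the exact
#' adjoint of the forward model's shift) and the shifted projections are
#' averaged. With `filtered = TRUE` every projection is first ramp-filtered
#' with [ramlak_filter()]. Averaging preserves constants (all-ones
#' projections reconstruct to ones away from the shifted-in border); the
#' exact adjoint of [project()] is the unfiltered backprojection times
#' `n_projections * voxel_size`.
#'
#' @param projections A `"projection_set"` from [simulate_acquisition()] (or
#'   a compatible list with `images`, `angles_deg`, `geometry`).
#' @param plane_heights Numeric vector of reconstruction heights in mm.
#' @param filtered Apply the ramp filter first (default `TRUE`).
#' @param window Apodization passed to [ramlak_filter()].
#' @return Object of class `"recon_volume"`: `slices` (rows x cols x
#'   n_planes), `heights_mm` (ascending), `geometry`, `filtered`.
#' @export
backproject <- function(projections, plane_heights, filtered = TRUE,
                        window = "none") {
  geom <- projections$geometry
  stopifnot(inherits(geom, "acquisition_geometry"))
  imgs <- projections$images
  angles <- projections$angles_deg
  if (length(dim(imgs)) != 3L || dim(imgs)[3] != length(angles))
    stopf("projection stack inconsistent with angle list")
  if (!all(dim(imgs)[1:2] == geom$detector_shape))
    stopf("projection shape inconsistent with detector geometry")
  if (length(plane_heights) < 1L) stopf("no plane heights requested")
  ord <- order(plane_heights)
  heights <- plane_heights[ord]
  d <- dim(imgs)
  filt <- array(0, d)
  for (i in seq_len(d[3]))
    filt[, , i] <- if (filtered)
      ramlak_filter(imgs[, , i], geom$pixel_pitch, geom$sweep_axis, window)
    else imgs[, , i]
  slices <- array(0, c(d[1], d[2], length(heights)))
  for (k in seq_along(heights)) {
    acc <- matrix(0, d[1], d[2])
    for (i in seq_len(d[3])) {
      s <- plane_shift_px(geom, angles[i], heights[k])
      acc <- acc + shift_image(filt[, , i], -s, geom$sweep_axis)
    }
    slices[, , k] <- acc / d[3]
  }
  structure(list(slices = slices, heights_mm = heights, geometry = geom,
                 filtered = filtered),
            class = "recon_volume")
}

#' Extract the in-focus plane of a reconstruction
#'
#' Returns the reconstructed slice whose height is nearest the target; an
#' exact tie between two planes resolves to the lower one.
#'
#' @param volume A [backproject()] result.
#' @param target_height Height of the structure of interest in mm.
#' @return 2-D matrix (the slice), with attribute `"height_mm"`.
#' @export
in_focus_plane <- function(volume, target_height) {
  stopifnot(inherits(volume, "recon_volume"))
  if (length(volume$heights_mm) == 0L) stopf("empty reconstruction volume")
  check_scalar(target_height, "target_height")
  idx <- which.min(abs(volume$heights_mm - target_height))  # first = lower
  out <- volume$slices[, , idx]
  attr(out, "height_mm") <- volume$heights_mm[idx]
  out
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("Reconstruction volume: %d planes (%g..%g mm), %s backprojection\n",
              length(x$heights_mm), min(x$heights_mm), max(x$heights_mm),
              if (x$filtered) "filtered" else "unfiltered"))
  invisible(x)
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear-interpolated FWHM around the global maximum; used to compare the
#' sharpness of a point structure between in-focus and off-focus planes.
#'
#' @param values Numeric profile.
#' @return FWHM in samples (`Inf` if the profile never falls to half maximum).
#' @export
profile_fwhm <- function(values) {
  if (length(values) < 3L) stopf("profile too short")
  i0 <- which.max(values)
  half <- values[i0] / 2
  left <- NA_real_
  for (i in seq(i0, 2L)) if (values[i - 1L] < half && values[i] >= half) {
    left <- (i - 1L) + (half - values[i - 1L]) / (values[i] - values[i - 1L])
    break
  }
  right <- NA_real_
  for (i in seq(i0, length(values) - 1L))
    if (values[i] >= half && values[i + 1L] < half) {
      right <- i + (values[i] - half) / (values[i] - values[i + 1L])
      break
    }
  if (is.na(left) || is.na(right)) return(Inf)
  right - left
}
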