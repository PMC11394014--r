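# Projection-set persistence: multi-page 32-bit float TIFF plus a JSON
# sidecar carrying angles, geometry, dose indices and the seed.  Pixel data
# are rescaled to [0,1] per page for the TIFF container and the per-page
# (min, max) recorded in the sidecar, so the round trip is exact to 32-bit
# float precision.

#' Write a projection set to TIFF + JSON
#'
#' @param ps A `"projection_set"`.
#' @param path Output path without extension; writes `<path>.tif` and
#'   `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_projection_set <- function(ps, path) {
  stopifnot(inherits(ps, "projection_set"))
  d <- dim(ps$images)
  pages <- vector("list", d[3])
  ranges <- matrix(0, d[3], 2L)
  for (i in seq_len(d[3])) {
    img <- ps$images[, , i]
    rng <- range(img)
    ranges[i, ] <- rng
    pages[[i]] <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
                  else img * 0
  }
  tif <- paste0(path, ".tif"); jsn <- paste0(path, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  g <- ps$geometry
  meta <- list(
    angles_deg = ps$angles_deg,
    dose_domain = ps$dose_domain,
    dose_indices = ps$dose_indices,
    dose_level = ps$dose_level,
    seed = ps$seed,
    noise = ps$noise,
    page_min = ranges[, 1], page_max = ranges[, 2],
    geometry = unclass(g))
  jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, jsn))
}

#' Read a projection set written by [write_projection_set()]
#'
#' @param path Path without extension.
#' @return A `"projection_set"`.
#' @export
read_projection_set <- function(path) {
  tif <- paste0(path, ".tif"); jsn <- paste0(path, ".json")
  if (!file.exists(tif) || !file.exists(jsn))
    stopf("missing projection files at '%s'", path)
  pages <- tiff::readTIFF(tif, all = TRUE)
  meta <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  g <- meta$geometry
  geometry <- acquisition_geometry(
    n_projections = g$n_projections, arc_deg = g$arc_deg,
    detector_shape = g$detector_shape, pixel_pitch = g$pixel_pitch,
    source_to_detector = g$source_to_detector,
    source_to_rotation_center = g$source_to_rotation_center,
    sweep_axis = g$sweep_axis)
  n <- length(pages)
  d <- dim(pages[[1]])
  images <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    lo <- meta$page_min[i]; hi <- meta$page_max[i]
    images[, , i] <- if (hi > lo) pages[[i]] * (hi - lo) + lo else pages[[i]]
  }
  structure(list(images = images, angles_deg = meta$angles_deg,
                 geometry = geometry, dose_domain = meta$dose_domain,
                 dose_indices = as.data.frame(meta$dose_indices),
                 dose_level = meta$dose_level, seed = meta$seed,
                 noise = meta$noise),
            class = "projection_set")
}

#' Write a reconstruction volume to TIFF + JSON
#' @param volume A `"recon_volume"`.
#' @param path Output path without extension.
#' @return Invisibly, the file paths.
#' @export
write_recon_volume <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  d <- dim(volume$slices)
  pages <- vector("list", d[3])
  ranges <- matrix(0, d[3], 2L)
  for (i in seq_len(d[3])) {
    img <- volume$slices[, , i]
    rng <- range(img)
    ranges[i, ] <- rng
    pages[[i]] <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
                  else img * 0
  }
  tif <- paste0(path, ".tif"); jsn <- paste0(path, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  jsonlite::write_json(list(heights_mm = volume$heights_mm,
                            filtered = volume$filtered,
                            page_min = ranges[, 1], page_max = ranges[, 2],
                            geometry = unclass(volume$geometry)),
                       jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, jsn))
}
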