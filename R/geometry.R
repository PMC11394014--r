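#' Acquisition geometry for a limited-angle tomosynthesis sweep
#'
#' Describes the linear-sweep acquisition: a small number of projections taken
#' over a narrow arc (default 15 projections over 15 degrees, symmetric about
#' 0), a flat detector, and the source/rotation-centre distances that fix the
#' per-plane parallax used by both the forward model and the shift-and-add
#' backprojection.
#'
#' @param n_projections Number of projections in one sweep (>= 1).
#' @param arc_deg Total angular range of the sweep in degrees (> 0); angles
#'   are evenly spaced over `[-arc_deg/2, +arc_deg/2]` inclusive.
#' @param detector_shape Integer pair `(rows, cols)` of the detector. The
#'   default `c(256, 512)` is a desk-scale stand-in for a clinical
#'   2560 x 4096 panel; the full size is supported.
#' @param pixel_pitch Detector pixel pitch in mm.
#' @param source_to_detector Source-to-detector distance in mm.
#' @param source_to_rotation_center Source-to-rotation-centre distance in mm;
#'   the rotation centre sits `source_to_detector - source_to_rotation_center`
#'   mm above the detector and projects with zero parallax.
#' @param sweep_axis Image axis along which the tube travels (1 = rows,
#'   2 = cols). All parallax shifts and the ramp filter act along this axis.
#'
#' @return An object of class `"acquisition_geometry"`.
#' @export
acquisition_geometry <- function(n_projections = 15L,
                                 arc_deg = 15,
                                 detector_shape = c(256L, 512L),
                                 pixel_pitch = 0.14,
                                 source_to_detector = 700,
                                 source_to_rotation_center = 660,
                                 sweep_axis = 2L) {
  n_projections <- as.integer(n_projections)
  if (is.na(n_projections) || n_projections < 1L)
    stopf("'n_projections' must be >= 1")
  check_scalar(arc_deg, "arc_deg", positive = TRUE)
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2L || any(detector_shape < 1L))
    stopf("'detector_shape' must be two positive integers (rows, cols)")
  check_scalar(pixel_pitch, "pixel_pitch", positive = TRUE)
  check_scalar(source_to_detector, "source_to_detector", positive = TRUE)
  check_scalar(source_to_rotation_center, "source_to_rotation_center",
               positive = TRUE)
  if (source_to_rotation_center >= source_to_detector)
    stopf("rotation centre must lie above the detector")
  sweep_axis <- as.integer(sweep_axis)
  if (!sweep_axis %in% c(1L, 2L)) stopf("'sweep_axis' must be 1 or 2")
  structure(list(
    n_projections = n_projections,
    arc_deg = arc_deg,
    detector_shape = detector_shape,
    pixel_pitch = pixel_pitch,
    source_to_detector = source_to_detector,
    source_to_rotation_center = source_to_rotation_center,
    sweep_axis = sweep_axis
  ), class = "acquisition_geometry")
}

#' Projection angles of a sweep
#'
#' Evenly spaced angles over `[-arc_deg/2, +arc_deg/2]`, inclusive and
#' symmetric about zero; a single-projection sweep sits at 0 degrees.
#'
#' @param geometry An [acquisition_geometry()].
#' @return Numeric vector of angles in degrees.
#' @export
projection_angles <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  n <- geometry$n_projections
  if (n == 1L) return(0)
  seq(-geometry$arc_deg / 2, geometry$arc_deg / 2, length.out = n)
}

#' Height of the rotation centre above the detector (mm)
#' @param geometry An [acquisition_geometry()].
#' @return Scalar height in mm.
#' @export
rotation_center_height <- function(geometry) {
  geometry$source_to_detector - geometry$source_to_rotation_center
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "Tomosynthesis geometry: %d projections over %g deg, detector %d x %d @ %g mm,\n  rotation centre %g mm above detector, sweep along axis %d\n",
    x$n_projections, x$arc_deg, x$detector_shape[1], x$detector_shape[2],
    x$pixel_pitch, rotation_center_height(x), x$sweep_axis))
  invisible(x)
}

# Sub-pixel shift of a matrix along one axis, zero-filled, linear
# interpolation.  shift_image(x, d)[i] == x[i - d]; its exact adjoint is
# shift_image(., -d), which the backprojector relies on.
shift_image <- function(img, delta, axis = 2L) {
  m <- floor(delta)
  f <- delta - m
  out <- (1 - f) * shift_int(img, m, axis)
  if (f != 0) out <- out + f * shift_int(img, m + 1, axis)
  out
}

shift_int <- function(img, m, axis) {
  if (m == 0) return(img)
  n <- dim(img)[axis]
  out <- array(0, dim(img))
  if (abs(m) >= n) return(out)
  if (axis == 2L) {
    if (m > 0) out[, (m + 1):n] <- img[, 1:(n - m), drop = FALSE]
    else out[, 1:(n + m)] <- img[, (1 - m):n, drop = FALSE]
  } else {
    if (m > 0) out[(m + 1):n, ] <- img[1:(n - m), , drop = FALSE]
    else out[1:(n + m), ] <- img[(1 - m):n, , drop = FALSE]
  }
  out
}

# Lateral parallax (in detector pixels) of a plane at height z_mm for a tube
# angle theta: planes at the rotation-centre height have zero shift.
plane_shift_px <- function(geometry, angle_deg, z_mm) {
  (z_mm - rotation_center_height(geometry)) *
    tan(angle_deg * pi / 180) / geometry$pixel_pitch
}
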