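# Tissue label codes and nominal linear attenuation (per mm, ~20 keV scale).
PHANTOM_LABELS <- c(air = 0L, adipose = 1L, fibroglandular = 2L,
                    mass = 3L, microcalcification = 4L)
PHANTOM_MU <- c(air = 0, adipose = 0.046, fibroglandular = 0.080,
                mass = 0.085, microcalcification = 0.60)

#' Synthetic compressed-breast phantom
#'
#' Builds a voxelised digital phantom used in place of clinical projections:
#' a half-ellipsoidal breast pressed against the chest-wall edge of the
#' detector, an adipose background with fibroglandular inclusions (more for
#' the dense type), optional soft-contrast mass lesions and small
#' high-attenuation microcalcifications. The in-plane voxel grid is
#' identified one-to-one with the detector pixel grid; `voxel_size` is the
#' slab thickness (mm) in the height direction and the path-length weight of
#' the forward projector.
#'
#' @param shape Integer triple `(rows, cols, planes)` of the voxel grid.
#' @param breast_type `"dense"` or `"non_dense"`; dense phantoms get a higher
#'   fibroglandular volume fraction.
#' @param n_masses Number of mass lesions (>= 0), placed disjointly.
#' @param n_mcs Number of microcalcifications (>= 0).
#' @param seed Integer seed; phantoms are bit-reproducible per seed.
#' @param voxel_size Slab thickness in mm.
#'
#' @return An object of class `"digital_phantom"` with elements `volume`
#'   (attenuation per mm), `label_map` (integer tissue codes, see
#'   `PHANTOM_LABELS`), `voxel_size`, `breast_type` and `seed`.
#' @export
make_phantom <- function(shape = c(256L, 512L, 24L),
                         breast_type = c("dense", "non_dense"),
                         n_masses = 1L, n_mcs = 3L, seed = 1L,
                         voxel_size = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stopf("'shape' must be three positive integers")
  breast_type <- match.arg(breast_type)
  n_masses <- as.integer(n_masses); n_mcs <- as.integer(n_mcs)
  if (n_masses < 0L || n_mcs < 0L) stopf("object counts must be >= 0")
  check_scalar(voxel_size, "voxel_size", positive = TRUE)

  nr <- shape[1]; nc <- shape[2]; nz <- shape[3]
  label <- array(PHANTOM_LABELS[["air"]], dim = shape)

  # Breast half-ellipsoid: flat face on the chest-wall edge (col 1).
  cr <- (nr + 1) / 2; ar <- 0.45 * nr
  ac <- 0.80 * nc
  cz <- (nz + 1) / 2; az <- 0.48 * nz
  er <- ((seq_len(nr) - cr) / ar)^2
  ec <- ((seq_len(nc) - 1) / ac)^2
  ez <- ((seq_len(nz) - cz) / az)^2
  breast <- outer(outer(er, ec, "+"), ez, "+") <= 1
  label[breast] <- PHANTOM_LABELS[["adipose"]]

  inside_ellipsoid <- function(center, axes) {
    u <- ((seq_len(nr) - center[1]) / axes[1])^2
    v <- ((seq_len(nc) - center[2]) / axes[2])^2
    w <- ((seq_len(nz) - center[3]) / axes[3])^2
    outer(outer(u, v, "+"), w, "+") <= 1
  }
  # Rejection-sample a centre lying inside the breast, shrunk by `margin`
  # voxels so the inclusion stays fully interior.
  sample_center <- function(margin) {
    for (i in 1:2000) {
      p <- c(runif(1, 1, nr), runif(1, 1, nc), runif(1, 1, nz))
      s <- ((p[1] - cr) / max(ar - margin, 1))^2 +
           ((p[2] - 1) / max(ac - margin, 1))^2 +
           ((p[3] - cz) / max(az - margin, 1))^2
      if (s <= 1 && p[2] > margin + 1) return(p)
    }
    stopf("could not place an inclusion inside the breast; shape too small")
  }

  with_seed(seed, {
    # Fibroglandular blobs until the target volume fraction is reached.
    target_frac <- if (breast_type == "dense") 0.40 else 0.12
    n_breast <- sum(breast)
    guard <- 0L
    while (sum(label == PHANTOM_LABELS[["fibroglandular"]]) / n_breast <
             target_frac && guard < 200L) {
      guard <- guard + 1L
      axes <- c(runif(1, 0.04, 0.12) * nr, runif(1, 0.04, 0.12) * nc,
                runif(1, 0.10, 0.30) * nz)
      blob <- inside_ellipsoid(sample_center(2), axes) & breast
      label[blob & label != PHANTOM_LABELS[["mass"]]] <-
        PHANTOM_LABELS[["fibroglandular"]]
    }
    # Disjoint mass lesions: enforce pairwise separation so each mass is one
    # connected component.
    if (n_masses > 0L) {
      centers <- list(); radii <- numeric(0)
      while (length(centers) < n_masses) {
        r <- runif(1, 0.030, 0.050) * min(nr, nc)
        p <- sample_center(r + 2)
        ok <- TRUE
        for (j in seq_along(centers))
          if (sqrt(sum((p - centers[[j]])^2)) < r + radii[j] + 4) ok <- FALSE
        if (ok) { centers[[length(centers) + 1L]] <- p; radii <- c(radii, r) }
      }
      for (j in seq_len(n_masses)) {
        m <- inside_ellipsoid(centers[[j]],
                              c(radii[j], radii[j], 0.6 * radii[j])) & breast
        label[m] <- PHANTOM_LABELS[["mass"]]
      }
    }
    # Microcalcifications: single high-attenuation voxels off the masses.
    if (n_mcs > 0L) {
      placed <- 0L
      while (placed < n_mcs) {
        p <- round(sample_center(3))
        if (label[p[1], p[2], p[3]] %in%
            PHANTOM_LABELS[c("adipose", "fibroglandular")]) {
          label[p[1], p[2], p[3]] <- PHANTOM_LABELS[["microcalcification"]]
          placed <- placed + 1L
        }
      }
    }
  })

  volume <- array(PHANTOM_MU[match(label, PHANTOM_LABELS)], dim = shape)
  structure(list(volume = volume, label_map = label,
                 voxel_size = voxel_size, breast_type = breast_type,
                 seed = as.integer(seed)),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$volume)
  tab <- table(factor(x$label_map, levels = PHANTOM_LABELS,
                      labels = names(PHANTOM_LABELS)))
  cat(sprintf("Digital breast phantom %d x %d x %d (%s), voxel %g mm\n",
              d[1], d[2], d[3], x$breast_type, x$voxel_size))
  print(tab)
  invisible(x)
}

#' Noiseless forward projection at one tube angle
#'
#' Shear (shifted line-sum) forward model for a narrow-arc sweep: every
#' phantom plane is laterally shifted along the sweep axis by its
#' height-dependent parallax and the shifted planes are summed with a
#' path-length weight of one voxel. This makes shift-and-add backprojection
#' the exact adjoint of the forward model.
#'
#' @param phantom A [make_phantom()] result (or compatible list).
#' @param geometry An [acquisition_geometry()]; its `detector_shape` must
#'   match the phantom's in-plane dimensions.
#' @param angle_deg Tube angle in degrees, `|angle_deg| <= arc_deg / 2`.
#' @return A detector-shaped matrix of attenuation line integrals.
#' @export
project <- function(phantom, geometry, angle_deg) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  check_scalar(angle_deg, "angle_deg")
  if (abs(angle_deg) > geometry$arc_deg / 2 + 1e-9)
    stopf("angle %g deg outside the acquisition arc [%g, %g]",
          angle_deg, -geometry$arc_deg / 2, geometry$arc_deg / 2)
  vol <- phantom$volume
  d <- dim(vol)
  if (!all(d[1:2] == geometry$detector_shape))
    stopf("phantom in-plane shape (%d x %d) must match the detector (%d x %d)",
          d[1], d[2], geometry$detector_shape[1], geometry$detector_shape[2])
  out <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) {
    z <- (k - 0.5) * phantom$voxel_size
    s <- plane_shift_px(geometry, angle_deg, z)
    out <- out + shift_image(vol[, , k], s, geometry$sweep_axis)
  }
  out * phantom$voxel_size
}

#' Detector dose indices of a projection
#'
#' Exposure index `EI` is a calibration constant times the mean detector
#' signal over the breast region; deviation index
#' `DI = 10 * log10(EI / EI_target)` so that under-exposed (low-dose)
#' acquisitions get negative DI. The breast region defaults to pixels whose
#' signal exceeds 1\% of the image maximum.
#'
#' @param projection 2-D numeric matrix of detector signal.
#' @param EI_target Calibration target exposure index (> 0).
#' @param calibration Multiplicative calibration constant (> 0).
#' @param mask Optional logical matrix selecting the breast region.
#' @return Object of class `"dose_indices"`: list with `EI`, `EI_target`, `DI`.
#' @export
compute_dose_indices <- function(projection, EI_target, calibration = 1,
                                 mask = NULL) {
  check_matrix(projection, "projection")
  check_scalar(EI_target, "EI_target", positive = TRUE)
  check_scalar(calibration, "calibration", positive = TRUE)
  if (is.null(mask)) mask <- projection > 0.01 * max(projection)
  if (!any(mask)) stopf("empty breast region: no pixels above threshold")
  EI <- calibration * mean(projection[mask])
  if (EI <= 0) stopf("non-positive exposure index")
  structure(list(EI = EI, EI_target = EI_target,
                 DI = 10 * log10(EI / EI_target)),
            class = "dose_indices")
}

#' Simulate a full noisy tomosynthesis acquisition
#'
#' For each sweep angle the noiseless line-integral projection is converted
#' to expected photon counts by Beer-Lambert attenuation of `dose_level`
#' photons per detector pixel, Poisson-sampled, and log-converted back to a
#' line-integral image. Per-projection exposure/deviation indices are stamped
#' from the mean photon count over the breast region, and the set is labelled
#' `"reference"` or `"object"` by comparing the mean EI with `ei_split`.
#'
#' @param phantom A [make_phantom()] result.
#' @param geometry An [acquisition_geometry()].
#' @param dose_level Incident photons per pixel (> 0).
#' @param seed Integer seed for the Poisson draw.
#' @param noise If `FALSE`, skip Poisson sampling (infinite-dose limit); the
#'   returned images equal the noiseless [project()] output per angle.
#' @param EI_target Exposure-index calibration target.
#' @param ei_calibration Calibration constant mapping mean counts to EI.
#' @param ei_split EI threshold separating the dose domains; defaults to
#'   `EI_target * 10^(-0.5)` (a deviation index of -5).
#' @return An object of class `"projection_set"`: `images` (rows x cols x
#'   n_projections array), `angles_deg`, `geometry`, `dose_domain`,
#'   `dose_indices` (data frame), `dose_level`, `seed`.
#' @export
simulate_acquisition <- function(phantom, geometry, dose_level, seed = 1L,
                                 noise = TRUE, EI_target = 1000,
                                 ei_calibration = 1, ei_split = NULL) {
  check_scalar(dose_level, "dose_level", positive = TRUE)
  check_scalar(EI_target, "EI_target", positive = TRUE)
  if (is.null(ei_split)) ei_split <- EI_target * 10^(-0.5)
  angles <- projection_angles(geometry)
  d <- geometry$detector_shape
  images <- array(0, c(d[1], d[2], length(angles)))
  di <- vector("list", length(angles))
  with_seed(seed, {
    for (i in seq_along(angles)) {
      L <- project(phantom, geometry, angles[i])
      if (noise) {
        counts <- matrix(rpois(length(L), dose_level * exp(-L)), d[1], d[2])
        counts <- pmax(counts, 0.5)       # guard the log at zero counts
        images[, , i] <- log(dose_level / counts)
      } else {
        counts <- dose_level * exp(-L)
        images[, , i] <- L
      }
      mask <- L > 0.01 * max(L)
      di[[i]] <- compute_dose_indices(counts, EI_target, ei_calibration, mask)
    }
  })
  dose_indices <- data.frame(
    angle_deg = angles,
    EI = vapply(di, `[[`, numeric(1), "EI"),
    EI_target = EI_target,
    DI = vapply(di, `[[`, numeric(1), "DI"))
  dose_domain <- if (mean(dose_indices$EI) >= ei_split) "reference" else "object"
  structure(list(images = images, angles_deg = angles, geometry = geometry,
                 dose_domain = dose_domain, dose_indices = dose_indices,
                 dose_level = dose_level, seed = as.integer(seed),
                 noise = noise),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "Projection set: %d projections of %d x %d (%s domain), mean EI %.1f, mean DI %+.2f\n",
    d[3], d[1], d[2], x$dose_domain, mean(x$dose_indices$EI),
    mean(x$dose_indices$DI)))
  invisible(x)
}
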