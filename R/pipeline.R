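# Pipeline orchestration: a single config with materialized defaults drives
# simulate -> train -> translate -> reconstruct -> evaluate, each stage a
# plain function writing files plus a manifest for reproducibility.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "dbtgan_run",
    geometry = list(n_projections = 15L, arc_deg = 15,
                    detector_shape = c(256L, 512L), pixel_pitch = 0.14,
                    source_to_detector = 700, source_to_rotation_center = 660,
                    sweep_axis = 2L),
    phantom = list(shape = c(256L, 512L, 24L), voxel_size = 2,
                   n_masses = 1L, n_mcs = 3L),
    dataset = list(n_train_cases = 45L, n_test_cases = 4L,
                   dense_fraction = 0.5),
    dose = list(reference_level = 8000, object_level = 800,
                EI_target = 1000, ei_calibration = 1),
    patching = list(patches_per_image = 128L, patch_size = 128L,
                    flip_prob = 0.5),
    network = list(kind = "rSEAG", depth = 4L, base_channels = 64L,
                   se_reduction = 16L, disc_base_channels = 64L,
                   disc_layers = 2L),
    trainer = list(n_epochs = 3L, minibatch = 16L, learning_rate = 1e-4,
                   beta1 = 0.5, beta2 = 0.999, lambda_adv = 1,
                   lambda_cycle = 10, lambda_fidelity = 5,
                   pool_capacity = 50L, val_fraction = 0.1, data_range = 1),
    reconstruction = list(plane_spacing_mm = 1, filtered = TRUE,
                          window = "none"),
    metrics = list(glcm_levels = 256L, gumbel_width = 30L,
                   gumbel_profiles = 29L, gumbel_origin = NULL))
}

#' Build a pipeline configuration with materialized defaults
#'
#' Merges user overrides (a nested list, or a YAML file path) into the full
#' default configuration, so the saved config snapshot of every run contains
#' every effective value — no hidden defaults.
#'
#' @param x `NULL` (all defaults), a nested list of overrides, or the path
#'   to a YAML file of overrides.
#' @return Nested list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(x = NULL) {
  cfg <- default_config()
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (!is.null(x)) {
    if (!is.list(x)) stopf("config overrides must be a list or YAML path")
    merge_rec <- function(a, b) {
      for (nm in names(b))
        a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
          merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
      a
    }
    cfg <- merge_rec(cfg, x)
  }
  structure(cfg, class = "pipeline_config")
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  acquisition_geometry(g$n_projections, g$arc_deg, g$detector_shape,
                       g$pixel_pitch, g$source_to_detector,
                       g$source_to_rotation_center, g$sweep_axis)
}

save_config_snapshot <- function(cfg, dir) {
  yaml::write_yaml(unclass(cfg), file.path(dir, "config_snapshot.yaml"))
}

#' Dataset bookkeeping implied by a configuration
#'
#' The arithmetic of the training set: cases times projections per sweep
#' gives the projections per dose domain, times patches per image gives the
#' patch samples per domain, divided by the minibatch gives the iterations
#' per epoch (e.g. 45 cases x 15 projections = 675; 675 x 128 = 86,400;
#' 86,400 / 16 = 5,400).
#'
#' @param cfg A [pipeline_config()].
#' @return List with `projections_per_domain`, `test_projections`,
#'   `samples_per_domain`, `iterations_per_epoch`.
#' @export
dataset_bookkeeping <- function(cfg = pipeline_config()) {
  n_proj <- cfg$dataset$n_train_cases * cfg$geometry$n_projections
  n_test <- cfg$dataset$n_test_cases * cfg$geometry$n_projections
  n_samples <- n_proj * cfg$patching$patches_per_image
  list(projections_per_domain = as.integer(n_proj),
       test_projections = as.integer(n_test),
       samples_per_domain = as.integer(n_samples),
       iterations_per_epoch = iterations_per_epoch(n_samples,
                                                   cfg$trainer$minibatch))
}

#' Simulate the reference- and object-domain projection datasets
#'
#' Generates `n_cases` phantoms (alternating dense / non-dense, with and
#' without masses) and simulates one reference-dose and one object-dose
#' acquisition per case, writing TIFF+JSON pairs under
#' `<output_dir>/projections/` and logging per-projection EI/DI.
#'
#' @param cfg A [pipeline_config()].
#' @param n_cases Number of cases to simulate (defaults to the configured
#'   training cases; lower it for desk-scale smoke runs).
#' @return Data frame manifest (one row per written projection set).
#' @export
run_simulate <- function(cfg = pipeline_config(), n_cases = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(n_cases)) n_cases <- cfg$dataset$n_train_cases
  geom <- config_geometry(cfg)
  dir <- file.path(cfg$output_dir, "projections")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_config_snapshot(cfg, cfg$output_dir)
  manifest <- data.frame()
  for (case in seq_len(n_cases)) {
    btype <- if ((case %% 2L) == 1L) "dense" else "non_dense"
    nmass <- case %% 2L
    ph <- make_phantom(cfg$phantom$shape, btype, n_masses = nmass,
                       n_mcs = cfg$phantom$n_mcs,
                       seed = cfg$seed + 1000L + case,
                       voxel_size = cfg$phantom$voxel_size)
    for (domain in c("reference", "object")) {
      lvl <- if (domain == "reference") cfg$dose$reference_level
             else cfg$dose$object_level
      ps <- simulate_acquisition(ph, geom, lvl,
                                 seed = cfg$seed + 2000L + 2L * case +
                                   (domain == "object"),
                                 EI_target = cfg$dose$EI_target,
                                 ei_calibration = cfg$dose$ei_calibration)
      path <- file.path(dir, sprintf("case%03d_%s", case, domain))
      write_projection_set(ps, path)
      manifest <- rbind(manifest, data.frame(
        case = case, domain = domain, breast_type = btype, n_masses = nmass,
        path = path, mean_EI = mean(ps$dose_indices$EI),
        mean_DI = mean(ps$dose_indices$DI)))
    }
  }
  utils::write.csv(manifest, file.path(cfg$output_dir, "simulate_manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Train the cycleGAN from simulated projection sets
#'
#' Extracts seeded patch pools from the listed reference/object projection
#' sets and runs [train_cyclegan()] with the configured network and trainer
#' settings; loss curves are written to CSV.
#'
#' @param cfg A [pipeline_config()].
#' @param manifest Manifest from [run_simulate()] (or compatible data frame).
#' @return The `"cyclegan_fit"`.
#' @export
run_train <- function(cfg, manifest) {
  pools <- list(reference = list(), object = list())
  for (i in seq_len(nrow(manifest))) {
    ps <- read_projection_set(manifest$path[i])
    dom <- manifest$domain[i]
    for (k in seq_len(dim(ps$images)[3])) {
      img <- normalize_image(ps$images[, , k], "zero_one")$data
      pb <- extract_patches(img, cfg$patching$patches_per_image,
                            cfg$patching$patch_size, cfg$patching$flip_prob,
                            seed = cfg$seed + 3000L + 100L * i + k)
      pools[[dom]][[length(pools[[dom]]) + 1L]] <- pb$patches
    }
  }
  bind3 <- function(lst) {
    d <- dim(lst[[1]])
    array(unlist(lst), c(d[1], d[2], sum(vapply(lst, function(a) dim(a)[3],
                                                numeric(1)))))
  }
  fit <- train_cyclegan(
    bind3(pools$reference), bind3(pools$object),
    generator_spec(cfg$network$kind, cfg$network$depth,
                   cfg$network$base_channels,
                   se_reduction = cfg$network$se_reduction),
    discriminator_spec(cfg$network$disc_base_channels,
                       cfg$network$disc_layers),
    n_epochs = cfg$trainer$n_epochs,
    lambda_adv = cfg$trainer$lambda_adv,
    lambda_cycle = cfg$trainer$lambda_cycle,
    lambda_fidelity = cfg$trainer$lambda_fidelity,
    learning_rate = cfg$trainer$learning_rate, beta1 = cfg$trainer$beta1,
    beta2 = cfg$trainer$beta2, minibatch = cfg$trainer$minibatch,
    seed = cfg$seed, val_fraction = cfg$trainer$val_fraction,
    data_range = cfg$trainer$data_range,
    pool_capacity = cfg$trainer$pool_capacity)
  utils::write.csv(fit$history, file.path(cfg$output_dir, "loss_curves.csv"),
                   row.names = FALSE)
  fit
}

# Periodic (raised-cosine) window used for seamless tile blending.
cosine_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)

#' Translate a full projection with a trained generator by blended tiling
#'
#' Processes a full-size image through a patch-trained generator: overlapping
#' tiles are translated independently and blended back with a 2-D cosine
#' window, preserving the image shape. On constant input the blend is exact
#' for any stride.
#'
#' @param net A generator (`"dbt_network"`).
#' @param image 2-D numeric matrix, at least tile-sized.
#' @param tile Tile side (must suit the generator depth; default 128).
#' @param stride Tile stride (< tile for overlap; default `tile / 2`).
#' @return Translated matrix, same shape as the input.
#' @export
translate_image <- function(net, image, tile = 128L, stride = tile %/% 2L) {
  check_matrix(image, "image")
  d <- dim(image)
  if (any(d < tile)) stopf("image smaller than one %d tile", tile)
  starts <- function(n) {
    s <- seq(1L, n - tile + 1L, by = stride)
    if (s[length(s)] != n - tile + 1L) s <- c(s, n - tile + 1L)
    s
  }
  w2 <- outer(cosine_window(tile), cosine_window(tile))
  acc <- matrix(0, d[1], d[2]); wacc <- matrix(0, d[1], d[2])
  for (r in starts(d[1])) for (c in starts(d[2])) {
    rows <- r:(r + tile - 1L); cols <- c:(c + tile - 1L)
    out <- network_apply(net, image[rows, cols])
    acc[rows, cols] <- acc[rows, cols] + w2 * out
    wacc[rows, cols] <- wacc[rows, cols] + w2
  }
  acc / wacc
}

#' Translate every projection of a set
#'
#' @param net A generator network.
#' @param ps A `"projection_set"`.
#' @param tile,stride Tiling parameters of [translate_image()].
#' @param normalize Normalize each projection to \[0, 1\] before translation
#'   (matching the training input scale) and keep that scale in the output.
#' @return A `"projection_set"` of translated projections.
#' @export
translate_projection_set <- function(net, ps, tile = 128L,
                                     stride = tile %/% 2L, normalize = TRUE) {
  stopifnot(inherits(ps, "projection_set"))
  out <- ps
  for (i in seq_len(dim(ps$images)[3])) {
    img <- ps$images[, , i]
    if (normalize) img <- normalize_image(img, "zero_one")$data
    out$images[, , i] <- translate_image(net, img, tile, stride)
  }
  out
}

#' Reconstruct a projection set per the configuration
#'
#' @param cfg A [pipeline_config()].
#' @param ps A `"projection_set"`.
#' @param plane_heights Optional explicit heights; defaults to the full
#'   phantom height range at the configured spacing.
#' @return A `"recon_volume"`.
#' @export
run_reconstruct <- function(cfg, ps, plane_heights = NULL) {
  if (is.null(plane_heights)) {
    zmax <- cfg$phantom$shape[3] * cfg$phantom$voxel_size
    plane_heights <- seq(cfg$reconstruction$plane_spacing_mm / 2, zmax,
                         by = cfg$reconstruction$plane_spacing_mm)
  }
  backproject(ps, plane_heights, cfg$reconstruction$filtered,
              cfg$reconstruction$window)
}

#' Quality report of one in-focus plane
#'
#' Computes the three evaluation instruments on a slice: PIQE block
#' distortion, GLCM homogeneity/contrast, and the Gumbel streak-artifact
#' statistic in a window at the breast periphery.
#'
#' @param image 2-D slice (an [in_focus_plane()] result).
#' @param cfg A [pipeline_config()] supplying metric settings.
#' @param label Identifier recorded in the report.
#' @return Object of class `"quality_report"`: `piqe`, `glcm`, `gumbel`,
#'   and a one-row `summary` data frame.
#' @export
quality_report <- function(image, cfg = pipeline_config(), label = "") {
  pq <- piqe(image)
  gf <- glcm_features(image, cfg$metrics$glcm_levels)
  origin <- cfg$metrics$gumbel_origin
  if (is.null(origin)) {
    # Default window at the breast periphery: centre row, two-thirds across
    # the sweep direction.
    origin <- c(max(1L, nrow(image) %/% 2L - cfg$metrics$gumbel_profiles %/% 2L),
                max(1L, round(ncol(image) * 2 / 3)))
  }
  gb <- gumbel_streak_statistic(image, origin, cfg$metrics$gumbel_width,
                                cfg$metrics$gumbel_profiles,
                                cfg$geometry$sweep_axis)
  summary <- data.frame(
    label = label, piqe = pq$score, homogeneity = gf$homogeneity,
    contrast = gf$contrast, gumbel_mean_max = gb$mean_max,
    gumbel_se = gb$se_max, gumbel_location = gb$location,
    gumbel_scale = gb$scale, gumbel_r = gb$pearson_r,
    gumbel_p = gb$p_value)
  structure(list(piqe = pq, glcm = gf, gumbel = gb, summary = summary),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  print(x$summary, digits = 4)
  invisible(x)
}

#' Evaluate reconstructions and write the report files
#'
#' One report row per supplied slice; writes CSV and JSON under the run's
#' output directory.
#'
#' @param cfg A [pipeline_config()].
#' @param slices Named list of 2-D slices (names label the methods).
#' @return Data frame of report rows.
#' @export
run_evaluate <- function(cfg, slices) {
  if (!length(slices)) stopf("no slices to evaluate")
  rows <- lapply(names(slices), function(nm)
    quality_report(slices[[nm]], cfg, nm)$summary)
  rep <- do.call(rbind, rows)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep, file.path(cfg$output_dir, "quality_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, file.path(cfg$output_dir, "quality_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rep
}
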