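# Run configuration and on-disk formats. A run directory holds:
#   config.yaml        the full, re-runnable configuration
#   stack.tif          multi-page 32-bit float TIFF of calibrated views
#   stack_meta.csv     per-page metadata (angle, exposure, camera, units,
#                      binning, scale)
#   ground_truth.json  exact simulated source positions/powers and medium
# Units are explicit in every file; simulation outputs are bit-reproducible
# from config + seed.

#' Assemble a run configuration
#'
#' Nested-list configuration covering scene, gantry, CCD, exposure, noise,
#' reconstruction parameters and seed. Unspecified fields get the package
#' defaults. The object round-trips through YAML without loss.
#'
#' @param scene List: `phantom` (diameter/height/voxel_size, or `NULL` for a
#'   bare source in air), `medium` (registry name or explicit coefficients),
#'   `sources` (list of position/power/wavelength lists).
#' @param gantry List: n_cameras, n_views, angular_step, radius, n_pixels.
#' @param ccd List overriding [ccd_parameters()] defaults.
#' @param exposure Exposure per view (s), scalar or vector.
#' @param noise Apply the CCD noise chain.
#' @param recon List: sigma_mm, max_iter, tol, grid_n, grid_voxel,
#'   views_subset.
#' @param seed Integer seed.
#' @param preset Optional preset name this config was derived from.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(scene, gantry = list(), ccd = list(), exposure = 60,
                       noise = FALSE, recon = list(), seed = 1L,
                       preset = NULL) {
  g_def <- list(n_cameras = 4L, n_views = 20L, angular_step = 18,
                radius = 116.5, n_pixels = 512L)
  gantry <- utils::modifyList(g_def, gantry)
  c_def <- list(quantum_efficiency = 0.85, full_well = 350000,
                read_noise = 5, dark_current = 0.1, adc_bits = 16L,
                binning = 4L, prnu_sd = 0.01, bias_dn = 100L)
  ccd <- utils::modifyList(c_def, ccd)
  r_def <- list(sigma_mm = 1.5, max_iter = 200L, tol = 1e-4,
                grid_n = 64L, grid_voxel = 0.5, views_subset = "all",
                max_sources = 3L, fit_rel_tol = 0.04, fit_improve = 0.75)
  recon <- utils::modifyList(r_def, recon)
  stopifnot(!is.null(scene$sources), length(scene$sources) >= 1)
  cfg <- list(scene = scene, gantry = gantry, ccd = ccd,
              exposure = exposure, noise = isTRUE(noise), recon = recon,
              seed = as.integer(seed), preset = preset)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a run configuration
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(scene = raw$scene, gantry = raw$gantry, ccd = raw$ccd,
             exposure = raw$exposure, noise = raw$noise, recon = raw$recon,
             seed = raw$seed, preset = raw$preset)
}

config_medium <- function(scene) {
  m <- scene$medium
  if (is.character(m)) return(medium_registry(m))
  optical_medium(m$mu_a, m$mu_s_prime, m$refractive_index %||% 1.0,
                 name = m$name %||% "custom",
                 turbid = m$turbid %||% (m$mu_s_prime > 0))
}

#' Build the scene described by a run configuration
#'
#' @param cfg A `run_config`.
#' @return A [scene_model()].
#' @export
config_scene <- function(cfg) {
  medium <- config_medium(cfg$scene)
  sources <- lapply(cfg$scene$sources, function(s) {
    point_source(unlist(s$position), s$power, s$wavelength %||% 560)
  })
  ph <- cfg$scene$phantom
  if (!is.null(ph)) {
    phantom <- build_cylinder_phantom(ph$diameter, ph$height,
                                      ph$voxel_size %||% 0.5)
    scene_model(sources, medium, mesh = phantom$mesh, grid = phantom$grid,
                mask = phantom$mask)
  } else {
    scene_model(sources, medium)
  }
}

#' Build the gantry described by a run configuration
#'
#' @param cfg A `run_config`.
#' @return List of `camera_pose`s.
#' @export
config_gantry <- function(cfg) {
  g <- cfg$gantry
  tmpl <- camera_pose(radius = g$radius, n_pixels = g$n_pixels)
  build_gantry(gantry_config(g$n_cameras, g$n_views, g$angular_step),
               camera_template = tmpl, radius = g$radius)
}

#' CCD parameters described by a run configuration
#'
#' @param cfg A `run_config`.
#' @return A [ccd_parameters()].
#' @export
config_ccd <- function(cfg) {
  c <- cfg$ccd
  ccd_parameters(quantum_efficiency = c$quantum_efficiency,
                 full_well = c$full_well, read_noise = c$read_noise,
                 dark_current = c$dark_current, adc_bits = c$adc_bits,
                 binning = c$binning, prnu_sd = c$prnu_sd,
                 bias_dn = c$bias_dn)
}

#' Reconstruction grid and config from a run configuration
#'
#' @param cfg A `run_config`.
#' @return List with `config` ([recon_config()]) and `grid`.
#' @export
config_recon <- function(cfg) {
  r <- cfg$recon
  list(config = recon_config(sigma_mm = r$sigma_mm, max_iter = r$max_iter,
                             tol = r$tol,
                             views_subset = r$views_subset %||% "all",
                             max_sources = r$max_sources %||% 3L,
                             fit_rel_tol = r$fit_rel_tol %||% 0.04,
                             fit_improve = r$fit_improve %||% 0.75),
       grid = recon_grid(r$grid_n, r$grid_voxel))
}

#' Write a view set as a run directory
#'
#' Calibrated views go to a multi-page 32-bit float TIFF (per-page scale in
#' the sidecar CSV); ground truth and the config are archived beside it.
#'
#' @param views A `view_set`.
#' @param dir Output directory (created).
#' @param cfg The `run_config` that produced the views.
#' @return `dir`, invisibly.
#' @export
write_view_set <- function(views, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(views$images)
  pages <- vector("list", n)
  meta <- data.frame(page = seq_len(n), angle_deg = NA_real_,
                     exposure_s = NA_real_, camera_id = NA_integer_,
                     binning = NA_integer_, units = NA_character_,
                     scale = NA_real_)
  for (i in seq_len(n)) {
    im <- views$images[[i]]
    scl <- max(im$data, 1e-300)
    pages[[i]] <- im$data / scl
    meta$angle_deg[i] <- im$view_angle
    meta$exposure_s[i] <- im$exposure_time
    meta$camera_id[i] <- im$camera_id
    meta$binning[i] <- im$binning
    meta$units[i] <- im$units
    meta$scale[i] <- scl
  }
  tiff::writeTIFF(pages, file.path(dir, "stack.tif"),
                  bits.per.sample = 32L, compression = "none")
  utils::write.csv(meta, file.path(dir, "stack_meta.csv"),
                   row.names = FALSE)
  gt <- list(
    sources = lapply(views$ground_truth, function(s) {
      list(position_mm = s$position, power_photons_s = s$power,
           wavelength_nm = s$wavelength)
    }),
    medium = views$scene$medium[c("name", "mu_a", "mu_s_prime",
                                  "refractive_index", "turbid")],
    seed = views$seed, noise = views$noise)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cfg)) write_run_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load an acquisition run directory
#'
#' Rebuilds the `view_set` (calibrated images, camera poses, scene) from the
#' archived config and TIFF stack.
#'
#' @param dir Run directory written by [write_view_set()].
#' @return A `view_set`.
#' @export
load_acquisition <- function(dir) {
  cfg <- read_run_config(file.path(dir, "config.yaml"))
  meta <- utils::read.csv(file.path(dir, "stack_meta.csv"))
  pages <- tiff::readTIFF(file.path(dir, "stack.tif"), all = TRUE)
  scene <- config_scene(cfg)
  gantry <- config_gantry(cfg)
  ccd <- config_ccd(cfg)
  angles <- vapply(gantry, `[[`, 0, "view_angle")
  images <- vector("list", nrow(meta))
  cams <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    data <- pages[[m$page]] * m$scale
    images[[i]] <- detector_image(data, m$units, m$exposure_s, m$angle_deg,
                                  m$camera_id, m$binning)
    cams[[i]] <- gantry[[which.min(abs(angles - m$angle_deg))]]
  }
  structure(list(images = images, cameras = cams, calmaps = NULL,
                 scene = scene, ccd = ccd, exposure = meta$exposure_s,
                 seed = cfg$seed, noise = cfg$noise,
                 ground_truth = scene$sources),
            class = "view_set")
}

#' Write a reconstructed volume as NIfTI
#'
#' Grid spacing goes into the pixel dimensions; the affine places the volume
#' with its world origin.
#'
#' @param volume A `source_estimate` or `fluence_field`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  v <- as_volume(volume)
  img <- RNifti::asNifti(v$vol)
  RNifti::pixdim(img) <- rep(v$grid$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a peak table as CSV
#'
#' @param peaks A `peak_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' Write an angular capture profile as CSV
#'
#' @param profile Data frame from [angular_capture_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

# Timestamped, level-tagged log line to console and optionally a file.
log_msg <- function(level, ..., file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
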