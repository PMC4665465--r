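# Radiometric chain: render_view produces expected photo-electrons per pixel;
# apply_ccd_noise digitizes them (shot noise -> full-well clip -> on-chip
# binning -> read noise -> ADC); flat_field_calibrate inverts the whole chain
# back to absolute radiance. Internal radiance unit is photons/s/mm^2/sr.

PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C <- 2.99792458e8      # m/s

#' Photon energy at a wavelength
#'
#' @param wavelength_nm Wavelength in nm.
#' @return Energy per photon in J.
#' @export
photon_energy <- function(wavelength_nm) {
  PLANCK_H * LIGHT_C / (wavelength_nm * 1e-9)
}

#' CCD detector parameters
#'
#' Defaults describe a back-illuminated cooled scientific CCD: 512 x 512
#' native pixels of 24 um, quantum efficiency 0.85 at 560 nm, 350,000 e- full
#' well, 2.6 uV/e- sensitivity, 5 e- RMS read noise, <0.1 e-/pixel/s dark
#' current at -50 C, 16-bit digitization, software-selectable on-chip binning.
#'
#' @param quantum_efficiency Fraction of photons converted to electrons.
#' @param full_well Pixel full-well capacity, electrons.
#' @param sensitivity_uV_per_e Output amplifier sensitivity (uV/e-), metadata.
#' @param read_noise Read noise, electrons RMS per (binned) readout.
#' @param dark_current Dark current, e-/pixel/s.
#' @param adc_bits ADC bit depth.
#' @param binning On-chip binning factor, one of 1, 2, 4, 8.
#' @param prnu_sd Pixel response non-uniformity (relative SD of per-pixel
#'   gain), simulated deterministically per camera head.
#' @param bias_dn Digitizer bias offset in counts.
#' @return An object of class `ccd_parameters`.
#' @export
ccd_parameters <- function(quantum_efficiency = 0.85, full_well = 350000,
                           sensitivity_uV_per_e = 2.6, read_noise = 5,
                           dark_current = 0.1, adc_bits = 16L,
                           binning = 1L, prnu_sd = 0.01, bias_dn = 100L) {
  stopifnot(quantum_efficiency > 0, quantum_efficiency <= 1,
            binning %in% c(1, 2, 4, 8), full_well > 0, read_noise >= 0,
            dark_current >= 0, adc_bits >= 1)
  structure(list(quantum_efficiency = quantum_efficiency,
                 full_well = full_well,
                 sensitivity_uV_per_e = sensitivity_uV_per_e,
                 read_noise = read_noise, dark_current = dark_current,
                 adc_bits = as.integer(adc_bits), binning = as.integer(binning),
                 prnu_sd = prnu_sd, bias_dn = bias_dn,
                 adc_gain = full_well / (2^adc_bits - 1)),
            class = "ccd_parameters")
}

#' Detector image container
#'
#' @param data Numeric matrix indexed `[u, v]`.
#' @param units One of `"electrons"`, `"counts"`, `"photons_s_mm2_sr"`,
#'   `"photons_s_cm2_sr"`, `"W_cm2_sr"`.
#' @param exposure_time Exposure in seconds.
#' @param view_angle Gantry view angle, degrees.
#' @param camera_id Physical camera head id.
#' @param binning Binning factor the pixel grid corresponds to.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(data, units, exposure_time, view_angle = 0,
                           camera_id = 1L, binning = 1L) {
  stopifnot(is.matrix(data))
  structure(list(data = data, units = units, exposure_time = exposure_time,
                 view_angle = view_angle, camera_id = as.integer(camera_id),
                 binning = as.integer(binning)),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf(
    "<detector_image> %dx%d px (bin %d), %s, %g s, view %g deg, camera %d\n",
    nrow(x$data), ncol(x$data), x$binning, x$units, x$exposure_time,
    x$view_angle, x$camera_id))
  invisible(x)
}

#' Scene model: phantom, medium and sources
#'
#' @param sources List of [point_source()] objects (a single source may be
#'   passed bare).
#' @param medium An [optical_medium()].
#' @param mesh Optional `surface_mesh` (required for turbid media).
#' @param grid Optional `voxel_grid` describing the phantom volume.
#' @param mask Optional inside-mask array matching `grid`.
#' @return An object of class `scene_model`.
#' @export
scene_model <- function(sources, medium, mesh = NULL, grid = NULL,
                        mask = NULL) {
  if (inherits(sources, "point_source")) sources <- list(sources)
  stopifnot(all(vapply(sources, inherits, TRUE, "point_source")),
            inherits(medium, "optical_medium"))
  if (medium$turbid) {
    if (is.null(mesh)) stop("a turbid scene needs a surface mesh")
    pos <- do.call(rbind, lapply(sources, `[[`, "position"))
    if (!all(inside_mesh(mesh, pos, margin = 1e-9))) {
      stop("all sources must lie strictly inside the mesh in a turbid medium")
    }
  }
  structure(list(sources = sources, medium = medium, mesh = mesh,
                 grid = grid, mask = mask),
            class = "scene_model")
}

# Per-pixel response of a camera head: deterministic pixel response
# non-uniformity field, seeded by the camera id (independent of the user RNG
# stream).
ccd_response_field <- function(ccd, camera, binning = 1L) {
  g <- camera_pixel_geometry(camera, binning)
  if (ccd$prnu_sd <= 0) return(matrix(1, g$n, g$n))
  native <- camera$n_pixels
  prnu <- local_seed(1000L + camera$camera_id, {
    matrix(1 + ccd$prnu_sd * stats::rnorm(native * native), native, native)
  })
  if (binning > 1) {
    prnu <- bin_matrix(prnu, binning) / binning^2
  }
  prnu
}

# Sum b x b blocks of a matrix.
bin_matrix <- function(m, b) {
  n1 <- nrow(m) %/% b
  n2 <- ncol(m) %/% b
  m <- m[seq_len(n1 * b), seq_len(n2 * b), drop = FALSE]
  dim(m) <- c(b, n1, b * n2)
  m <- colSums(m)
  dim(m) <- c(n1, b, n2)
  m <- aperm(m, c(1, 3, 2))
  rowSums(m, dims = 2)
}

# Evaluate RNG-dependent code under a fixed seed without disturbing the
# caller's RNG stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Geometric etendue of each detector pixel
#'
#' Product `A_pixel * A_lens / d_image^2 * cos^4(alpha)` (mm^2 sr): the
#' conversion from scene radiance at the pixel's footprint to power collected
#' by that pixel, including the off-axis cos^4 falloff (lens vignetting).
#'
#' @param camera A `camera_pose`.
#' @param binning Binning factor.
#' @return Matrix indexed `[u, v]`.
#' @export
pixel_etendue <- function(camera, binning = 1L) {
  pr <- camera_pixel_rays(camera, binning)
  a_pix <- pr$pitch^2
  matrix(a_pix * camera$aperture_area / camera$image_distance^2 *
           pr$cos_alpha^4, pr$n, pr$n)
}

#' Render one noiseless view
#'
#' Expected photo-electrons per pixel for one camera pose. Turbid media are
#' rendered by ray-casting each pixel to the phantom surface and evaluating
#' the diffusion fluence of all sources there, converted to Lambertian
#' radiance by [boundary_exitance()]; a transparent (air) scene is rendered
#' by direct inverse-square projection of each bare source, spread over the
#' image of a small emitting disc (1 mm fiber tip by default).
#'
#' @param scene A [scene_model()].
#' @param camera A `camera_pose` (outside the mesh).
#' @param exposure Exposure time, seconds.
#' @param ccd A [ccd_parameters()].
#' @param binning Binning factor of the rendered pixel grid (the noiseless
#'   equivalent of on-chip binning).
#' @param source_extent_mm Physical diameter of the bare source used for the
#'   air-mode splat.
#' @return A `detector_image` in units `"electrons"` (expected values).
#' @export
render_view <- function(scene, camera, exposure, ccd = ccd_parameters(),
                        binning = 1L, source_extent_mm = 1) {
  g <- camera_pixel_geometry(camera, binning)
  img <- matrix(0, g$n, g$n)
  medium <- scene$medium
  if (medium$turbid) {
    if (isTRUE(inside_mesh(scene$mesh, camera$position))) {
      stop("camera must be outside the mesh")
    }
    pr <- camera_pixel_rays(camera, binning)
    orig <- matrix(camera$position, nrow(pr$dir), 3, byrow = TRUE)
    hit <- ray_cylinder(orig, pr$dir, scene$mesh$primitive)
    idx <- which(hit$hit)
    if (length(idx)) {
      pts <- hit$point[idx, , drop = FALSE]
      phi <- numeric(length(idx))
      for (s in scene$sources) {
        phi <- phi + point_source_fluence(s, pts, medium)
      }
      L <- boundary_exitance(phi, medium = medium)
      a_pix <- pr$pitch^2
      det <- L * a_pix * camera$aperture_area / camera$image_distance^2 *
        pr$cos_alpha[idx]^4
      img[idx] <- det
    }
  } else {
    for (s in scene$sources) {
      p <- matrix(s$position, 1, 3)
      prj <- project_to_pixels(camera, p, binning)
      if (!prj$in_fov) next
      power_det <- s$power * camera$aperture_area / (4 * pi * prj$dist^2)
      cosa <- prj$depth / prj$dist
      power_det <- power_det * cosa^4
      # splat over the image of the emitting disc
      mag <- camera$image_distance / prj$depth
      r_px <- max(source_extent_mm / 2 * mag / g$pitch, 1e-6)
      lo_u <- max(1L, floor(prj$u - r_px - 1)); hi_u <- min(g$n, ceiling(prj$u + r_px + 1))
      lo_v <- max(1L, floor(prj$v - r_px - 1)); hi_v <- min(g$n, ceiling(prj$v + r_px + 1))
      us <- lo_u:hi_u; vs <- lo_v:hi_v
      du <- outer(us - prj$u, rep(1, length(vs)))
      dv <- outer(rep(1, length(us)), vs - prj$v)
      w <- pmax(pmin(r_px + 0.5 - sqrt(du^2 + dv^2), 1), 0)
      if (sum(w) <= 0) {
        w[which.min(du^2 + dv^2)] <- 1
      }
      img[us, vs] <- img[us, vs] + power_det * w / sum(w)
    }
  }
  img <- img * ccd$quantum_efficiency * exposure *
    ccd_response_field(ccd, camera, binning)
  detector_image(img, "electrons", exposure, camera$view_angle,
                 camera$camera_id, as.integer(binning))
}

#' Apply the CCD noise chain and digitize
#'
#' Expects an image of expected photo-electrons at native (unbinned)
#' resolution. Applies, in physical order: Poisson shot noise on signal plus
#' dark current, full-well clipping per native pixel, on-chip binning
#' (electron sum, one readout per bin), Gaussian read noise per readout, and
#' ADC quantization with bias offset and 16-bit clipping.
#'
#' @param image A `detector_image` in `"electrons"` with `binning == 1`.
#' @param ccd A [ccd_parameters()]; its `binning` controls on-chip binning.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A `detector_image` of integer ADC counts (units `"counts"`).
#' @export
apply_ccd_noise <- function(image, ccd, seed = 1L) {
  stopifnot(inherits(image, "detector_image"), image$units == "electrons")
  if (image$binning != 1L) {
    stop("apply_ccd_noise expects a native-resolution (binning 1) image")
  }
  e <- image$data
  lam <- e + ccd$dark_current * image$exposure_time
  out <- local_seed(seed, {
    shot <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    shot <- pmin(shot, ccd$full_well)
    b <- ccd$binning
    binned <- if (b > 1) bin_matrix(shot, b) else shot
    binned <- binned + ccd$read_noise *
      matrix(stats::rnorm(length(binned)), nrow(binned), ncol(binned))
    # binned readout digitizes the summed wells: the ADC gain scales with
    # the bin capacity so full scale matches b^2 full wells
    gain <- ccd$adc_gain * b^2
    dn <- round(binned / gain) + ccd$bias_dn
    matrix(pmin(pmax(dn, 0), 2^ccd$adc_bits - 1), nrow(binned), ncol(binned))
  })
  detector_image(out, "counts", image$exposure_time, image$view_angle,
                 image$camera_id, as.integer(image$binning * ccd$binning))
}

#' Expected ADC counts of an expected-electron image
#'
#' Noise-free digitization (the many-frame average of [apply_ccd_noise()]):
#' on-chip binning, ADC gain matched to the binned well capacity, bias
#' offset; no shot/read noise and no rounding.
#'
#' @param image A `detector_image` in `"electrons"` at native resolution.
#' @param ccd A [ccd_parameters()].
#' @return A `detector_image` in `"counts"` (fractional expected values).
#' @export
expected_counts <- function(image, ccd) {
  stopifnot(image$units == "electrons", image$binning == 1L)
  b <- ccd$binning
  e <- if (b > 1) bin_matrix(image$data, b) else image$data
  dn <- e / (ccd$adc_gain * b^2) + ccd$bias_dn
  detector_image(dn, "counts", image$exposure_time, image$view_angle,
                 image$camera_id, as.integer(b))
}

#' Flat-field radiometric calibration
#'
#' Builds a per-pixel gain map from images of a uniform source of known
#' radiance: `gain = reference_radiance / mean(signal rate)`. Corrects lens
#' vignetting, pixel response non-uniformity and the overall transmission/QE
#' of the chain in one step. Pixels with non-positive mean rate are flagged
#' dead and excluded (gain `NA`).
#'
#' @param flat_images List of `detector_image`s (counts or electrons) of the
#'   flat-field source.
#' @param reference_radiance Known radiance of the source in W/cm^2/sr
#'   (default 3.0e-7).
#' @param wavelength Wavelength (nm) used to express the gain in photon units.
#' @param ccd The `ccd_parameters` (for the bias offset of counts images).
#' @return An object of class `calibration_map`: per-pixel gain converting
#'   signal/s to photons/s/mm^2/sr, plus the dead-pixel index set.
#' @export
flat_field_calibrate <- function(flat_images,
                                 reference_radiance = 3.0e-7,
                                 wavelength = 560,
                                 ccd = ccd_parameters()) {
  if (inherits(flat_images, "detector_image")) flat_images <- list(flat_images)
  stopifnot(length(flat_images) >= 1)
  rate <- NULL
  for (im in flat_images) {
    sig <- im$data
    if (im$units == "counts") sig <- sig - ccd$bias_dn
    else if (im$units != "electrons") stop("flats must be counts or electrons")
    r <- sig / im$exposure_time
    rate <- if (is.null(rate)) r else rate + r
  }
  rate <- rate / length(flat_images)
  dead <- which(rate <= 0)
  ref_photons_mm2 <- reference_radiance * 0.01 / photon_energy(wavelength)
  gain <- ref_photons_mm2 / rate
  gain[dead] <- NA_real_
  structure(list(gain = gain, dead_pixels = dead,
                 reference_radiance = reference_radiance,
                 wavelength = wavelength,
                 units = "photons_s_mm2_sr"),
            class = "calibration_map")
}

#' Apply a calibration map to a detector image
#'
#' Converts raw counts (or expected electrons) to absolute radiance
#' (photons/s/mm^2/sr). Dead pixels and negative post-bias excursions are
#' set to zero; calibrated images are non-negative.
#'
#' @param image A `detector_image` in `"counts"` or `"electrons"`.
#' @param calmap A `calibration_map` matching the image geometry.
#' @param ccd The `ccd_parameters` (bias offset).
#' @return A calibrated `detector_image` in `"photons_s_mm2_sr"`.
#' @export
calibrate_image <- function(image, calmap, ccd = ccd_parameters()) {
  sig <- image$data
  if (image$units == "counts") sig <- sig - ccd$bias_dn
  else if (image$units != "electrons") stop("image already calibrated")
  stopifnot(all(dim(sig) == dim(calmap$gain)))
  out <- sig / image$exposure_time * calmap$gain
  out[!is.finite(out)] <- 0
  out[out < 0] <- 0
  detector_image(out, "photons_s_mm2_sr", image$exposure_time,
                 image$view_angle, image$camera_id, image$binning)
}

#' Convert a calibrated image between radiance unit systems
#'
#' Converts using the photon energy `hc / lambda` and the cm^2/mm^2 area
#' factor. Round trips are exact to machine precision.
#'
#' @param image A calibrated `detector_image`.
#' @param wavelength Wavelength (nm).
#' @param to Target units: `"photons_s_mm2_sr"`, `"photons_s_cm2_sr"` or
#'   `"W_cm2_sr"`.
#' @return The converted `detector_image`.
#' @export
radiance_units <- function(image, wavelength = 560,
                           to = c("photons_s_cm2_sr", "W_cm2_sr",
                                  "photons_s_mm2_sr")) {
  to <- match.arg(to)
  from <- image$units
  valid <- c("photons_s_mm2_sr", "photons_s_cm2_sr", "W_cm2_sr")
  if (!from %in% valid) stop("unknown units flag: ", from)
  e_ph <- photon_energy(wavelength)
  # normalize to photons/s/mm^2/sr
  x <- switch(from,
    photons_s_mm2_sr = image$data,
    photons_s_cm2_sr = image$data / 100,
    W_cm2_sr = image$data * 0.01 / e_ph)
  out <- switch(to,
    photons_s_mm2_sr = x,
    photons_s_cm2_sr = x * 100,
    W_cm2_sr = x * 100 * e_ph)
  im <- image
  im$data <- out
  im$units <- to
  im
}

#' Simulate a complete calibrated multi-view acquisition
#'
#' Renders every gantry view, optionally applies the CCD noise chain, and
#' calibrates each frame back to absolute radiance with a flat-field gain map
#' built per camera head through the same chain. Ground truth (the source
#' list) travels with the result.
#'
#' @param scene A [scene_model()].
#' @param gantry List of camera poses from [build_gantry()].
#' @param ccd A [ccd_parameters()].
#' @param exposure Exposure time per view (s); scalar or vector of length
#'   `length(gantry)`.
#' @param seed Integer seed for the noise chain.
#' @param noise Apply the CCD noise chain? If `FALSE`, expected-value images
#'   are calibrated directly (rendered at the binned resolution).
#' @return An object of class `view_set`: list of calibrated
#'   `detector_image`s, the camera poses, calibration maps, scene reference
#'   and ground truth.
#' @export
simulate_acquisition <- function(scene, gantry, ccd = ccd_parameters(),
                                 exposure = 60, seed = 1L, noise = TRUE) {
  nv <- length(gantry)
  exposure <- rep_len(exposure, nv)
  wl <- scene$sources[[1]]$wavelength
  cam_ids <- unique(vapply(gantry, `[[`, 0L, "camera_id"))
  calmaps <- list()
  for (cid in cam_ids) {
    cam <- gantry[[which(vapply(gantry, `[[`, 0L, "camera_id") == cid)[1]]]
    calmaps[[as.character(cid)]] <- if (noise) {
      # noisy acquisitions are digitized, so the gain map must invert the
      # counts chain: use the (many-frame average) digitized flat
      flat <- render_flat_view(cam, ccd, wavelength = wl, binning = 1L)
      flat_field_calibrate(expected_counts(flat, ccd), wavelength = wl,
                           ccd = ccd)
    } else {
      simulate_flat_calibration(cam, ccd, wavelength = wl,
                                binning = ccd$binning)
    }
  }
  images <- vector("list", nv)
  for (i in seq_len(nv)) {
    cam <- gantry[[i]]
    calmap <- calmaps[[as.character(cam$camera_id)]]
    if (noise) {
      raw <- render_view(scene, cam, exposure[i], ccd, binning = 1L)
      noisy <- apply_ccd_noise(raw, ccd, seed = seed + i)
      images[[i]] <- calibrate_image(noisy, calmap, ccd)
    } else {
      raw <- render_view(scene, cam, exposure[i], ccd, binning = ccd$binning)
      images[[i]] <- calibrate_image(raw, calmap, ccd)
    }
  }
  structure(list(images = images, cameras = gantry, calmaps = calmaps,
                 scene = scene, ccd = ccd, exposure = exposure,
                 seed = seed, noise = noise,
                 ground_truth = scene$sources),
            class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf("<view_set> %d calibrated views, %s medium, %d source(s)%s\n",
              length(x$images), x$scene$medium$name,
              length(x$ground_truth),
              if (x$noise) ", with CCD noise" else ", noiseless"))
  invisible(x)
}

#' Flat-field calibration map simulated for one camera head
#'
#' Renders the flat-field source (uniform known radiance filling the field)
#' through the camera's radiometric chain and calibrates against it.
#'
#' @param camera A `camera_pose`.
#' @param ccd A `ccd_parameters`.
#' @param reference_radiance Flat source radiance, W/cm^2/sr.
#' @param wavelength Wavelength (nm).
#' @param binning Binning of the map.
#' @param exposure Flat exposure (s).
#' @return A `calibration_map`.
#' @export
simulate_flat_calibration <- function(camera, ccd,
                                      reference_radiance = 3.0e-7,
                                      wavelength = 560, binning = 1L,
                                      exposure = 60) {
  flat <- render_flat_view(camera, ccd, reference_radiance, wavelength,
                           binning, exposure)
  flat_field_calibrate(list(flat), reference_radiance, wavelength, ccd)
}

#' Render the flat-field source
#'
#' Expected electrons per pixel from a uniform Lambertian source of known
#' radiance filling the field of view.
#'
#' @inheritParams simulate_flat_calibration
#' @return A `detector_image` in `"electrons"`.
#' @export
render_flat_view <- function(camera, ccd, reference_radiance = 3.0e-7,
                             wavelength = 560, binning = 1L, exposure = 60) {
  l_photons <- reference_radiance * 0.01 / photon_energy(wavelength)
  e <- l_photons * pixel_etendue(camera, binning) *
    ccd$quantum_efficiency * exposure *
    ccd_response_field(ccd, camera, binning)
  detector_image(e, "electrons", exposure, camera$view_angle,
                 camera$camera_id, as.integer(binning))
}

#' Angular capture profile of a view set
#'
#' Total light captured per view: the calibrated radiance of every pixel
#' multiplied by its geometric etendue and summed, giving detected photons/s
#' at the lens for each gantry angle.
#'
#' @param views A `view_set`.
#' @return Data frame with columns `angle_deg`, `total_light`, `units`.
#' @export
angular_capture_profile <- function(views) {
  stopifnot(length(views$images) >= 1)
  n <- length(views$images)
  ang <- numeric(n)
  tot <- numeric(n)
  for (i in seq_len(n)) {
    im <- views$images[[i]]
    stopifnot(im$units == "photons_s_mm2_sr")
    eta <- pixel_etendue(views$cameras[[i]], im$binning)
    ang[i] <- im$view_angle
    tot[i] <- sum(im$data * eta)
  }
  o <- order(ang)
  data.frame(angle_deg = ang[o], total_light = tot[o],
             units = "photons_s")
}

#' Detected photon rate per pixel of a calibrated image
#'
#' Radiance times per-pixel etendue: photons/s collected by the lens for each
#' pixel. This is the quantity the reconstruction backprojects.
#'
#' @param image A calibrated `detector_image`.
#' @param camera The matching `camera_pose`.
#' @return Matrix of photons/s.
#' @export
detected_rate <- function(image, camera) {
  stopifnot(image$units == "photons_s_mm2_sr")
  image$data * pixel_etendue(camera, image$binning)
}
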