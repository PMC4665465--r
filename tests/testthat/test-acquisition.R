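# Forward rendering, CCD noise chain, flat-field calibration, units.

test_that("air rendering follows the inverse-square law", {
  src <- point_source(c(0, 0, 0), 1e10)
  sc <- scene_model(src, medium_registry("air"))
  ccd <- ccd_parameters(prnu_sd = 0)
  t1 <- sum(render_view(sc, camera_pose(0, radius = 100), 1, ccd,
                        binning = 4)$data)
  t2 <- sum(render_view(sc, camera_pose(0, radius = 200), 1, ccd,
                        binning = 4)$data)
  expect_equal(t1 / t2, 4, tolerance = 1e-9)
  # detected power equals S * A_lens / (4 pi d^2) * QE for an on-axis source
  cam <- camera_pose(0, radius = 100)
  expected <- 1e10 * cam$aperture_area / (4 * pi * 100^2) * 0.85
  expect_equal(t1, expected, tolerance = 1e-9)
})

test_that("a centered source renders identically in all 20 views", {
  v <- cached_sim("centered_source")
  tot <- vapply(v$images, function(im) sum(im$data), 0)
  expect_equal(max(tot) / min(tot) - 1, 0, tolerance = 1e-6)
  # pixel-level identity across opposed views (symmetry)
  expect_equal(sum(abs(v$images[[1]]$data - v$images[[11]]$data)) /
                 sum(v$images[[1]]$data), 0, tolerance = 1e-6)
})

test_that("noiseless pipeline is linear in source power", {
  ph <- build_cylinder_phantom(30, 40, 1)
  med <- lipid()
  gantry <- build_gantry(gantry_config(4, 4, 90))
  ccd <- ccd_parameters(binning = 4)
  mk <- function(pw) {
    sc <- scene_model(point_source(c(5, 0, 0), pw), med, mesh = ph$mesh)
    simulate_acquisition(sc, gantry, ccd, exposure = 60, noise = FALSE)
  }
  v1 <- mk(1e9)
  v3 <- mk(3.7e9)
  for (i in seq_along(v1$images)) {
    expect_equal(v3$images[[i]]$data, 3.7 * v1$images[[i]]$data,
                 tolerance = 1e-10)
  }
})

test_that("sources outside the mesh are rejected in turbid mode", {
  ph <- build_cylinder_phantom(30, 40, 1)
  expect_error(scene_model(point_source(c(20, 0, 0), 1e9), lipid(),
                           mesh = ph$mesh), "inside")
  # inside is fine
  expect_s3_class(scene_model(point_source(c(14, 0, 0), 1e9), lipid(),
                              mesh = ph$mesh), "scene_model")
})

test_that("CCD noise chain is reproducible and has the stated read noise", {
  ccd <- ccd_parameters(prnu_sd = 0)
  img <- detector_image(matrix(0, 96, 96), "electrons", exposure_time = 0)
  n1 <- apply_ccd_noise(img, ccd, seed = 5)
  n2 <- apply_ccd_noise(img, ccd, seed = 5)
  expect_identical(n1$data, n2$data)
  n3 <- apply_ccd_noise(img, ccd, seed = 6)
  expect_false(identical(n1$data, n3$data))
  # zero signal, zero exposure: mean ~ bias, SD ~ 5 e- in count equivalents
  e <- (n1$data - ccd$bias_dn) * ccd$adc_gain
  expect_equal(mean(n1$data), ccd$bias_dn, tolerance = 0.01)
  # quantization adds adc_gain/sqrt(12) in quadrature to the 5 e- read noise
  expect_equal(stats::sd(e), sqrt(25 + ccd$adc_gain^2 / 12), tolerance = 0.1)
})

test_that("on-chip binning sums electrons with one read per bin", {
  # brute-force oracle: replicate the chain with explicit block sums
  ccd <- ccd_parameters(binning = 4, prnu_sd = 0)
  lam <- matrix(1000, 32, 32)
  img <- detector_image(lam, "electrons", exposure_time = 1)
  got <- apply_ccd_noise(img, ccd, seed = 9)
  lam_d <- lam + ccd$dark_current * 1
  oracle <- local({
    set.seed(9)
    shot <- matrix(stats::rpois(length(lam_d), lam_d), 32, 32)
    shot <- pmin(shot, ccd$full_well)
    binned <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      binned[i, j] <- sum(shot[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)])
    }
    binned <- binned + ccd$read_noise * matrix(stats::rnorm(64), 8, 8)
    dn <- round(binned / (ccd$adc_gain * 16)) + ccd$bias_dn
    pmin(pmax(dn, 0), 2^16 - 1)
  })
  expect_identical(dim(got$data), c(8L, 8L))
  expect_equal(got$data, oracle)
  # 16x mean signal per output pixel (in electron equivalents)
  e <- (got$data - ccd$bias_dn) * ccd$adc_gain * 16
  expect_equal(mean(e), 16 * 1000, tolerance = 0.01)
})

test_that("flat-field calibration recovers the reference radiance", {
  cam <- camera_pose(0)
  ccd <- ccd_parameters(binning = 4, prnu_sd = 0.02)
  calm <- simulate_flat_calibration(cam, ccd, binning = 4)
  flat <- render_flat_view(cam, ccd, binning = 4)
  # the flat itself is vignetted and non-uniform...
  expect_gt(diff(range(flat$data)) / mean(flat$data), 0.01)
  # ...but calibrates to the uniform reference radiance
  cal <- radiance_units(calibrate_image(flat, calm, ccd), 560, "W_cm2_sr")
  expect_equal(max(abs(cal$data - 3.0e-7)) / 3.0e-7, 0, tolerance = 1e-9)
  # ideal camera (no vignetting beyond geometry, no PRNU): gain map constant
  # up to the cos^4 field geometry it corrects
  expect_true(all(is.finite(calm$gain)))
  expect_length(calm$dead_pixels, 0)
})

test_that("calibration round-trips and flags dead pixels", {
  cam <- camera_pose(0)
  ccd <- ccd_parameters(binning = 4, prnu_sd = 0.01)
  calm <- simulate_flat_calibration(cam, ccd, binning = 4)
  set.seed(3)
  raw <- detector_image(matrix(stats::runif(128^2, 10, 100), 128, 128),
                        "electrons", 60, 0, 1, 4L)
  cal <- calibrate_image(raw, calm, ccd)
  back <- cal$data / calm$gain * raw$exposure_time
  expect_equal(back, raw$data, tolerance = 1e-12)
  # dead pixel: zero flat signal
  flat <- render_flat_view(cam, ccd, binning = 4)
  flat$data[5, 7] <- 0
  calm2 <- flat_field_calibrate(flat, ccd = ccd)
  expect_equal(calm2$dead_pixels, 5 + 128 * 6)
  cal2 <- calibrate_image(raw, calm2, ccd)
  expect_equal(cal2$data[5, 7], 0)   # excluded, not NA
})

test_that("radiance unit conversions use the photon energy", {
  im <- detector_image(matrix(1, 2, 2), "W_cm2_sr", 1)
  ph <- radiance_units(im, 560, "photons_s_cm2_sr")
  expect_equal(ph$data[1], 2.82e18, tolerance = 1e-3)
  # round trip identity
  back <- radiance_units(ph, 560, "W_cm2_sr")
  expect_equal(back$data, im$data, tolerance = 1e-12)
  # doubling the wavelength doubles the photon rate at fixed W
  ph2 <- radiance_units(im, 1120, "photons_s_cm2_sr")
  expect_equal(ph2$data[1] / ph$data[1], 2, tolerance = 1e-12)
  # mm^2 <-> cm^2
  mm <- radiance_units(ph, 560, "photons_s_mm2_sr")
  expect_equal(mm$data * 100, ph$data, tolerance = 1e-12)
  bad <- im
  bad$units <- "furlongs"
  expect_error(radiance_units(bad, 560, "W_cm2_sr"), "unknown units")
})

test_that("calibrated images are exposure-invariant", {
  ph <- build_cylinder_phantom(30, 40, 1)
  sc <- scene_model(point_source(c(5, 0, 0), 1e10), lipid(), mesh = ph$mesh)
  gantry <- build_gantry(gantry_config(2, 2, 180))
  ccd <- ccd_parameters(binning = 4)
  v60 <- simulate_acquisition(sc, gantry, ccd, exposure = 60, noise = FALSE)
  v300 <- simulate_acquisition(sc, gantry, ccd, exposure = 300, noise = FALSE)
  for (i in seq_along(v60$images)) {
    expect_equal(v300$images[[i]]$data, v60$images[[i]]$data,
                 tolerance = 1e-10)
  }
})

test_that("simulated acquisitions are bit-reproducible under a fixed seed", {
  cfg <- fixture_spec("intralipid_single_offaxis", noise = TRUE, seed = 21)
  cfg$gantry$n_views <- 4L
  cfg$gantry$angular_step <- 90
  v1 <- simulate_run(cfg)
  v2 <- simulate_run(cfg)
  for (i in seq_along(v1$images)) {
    expect_identical(v1$images[[i]]$data, v2$images[[i]]$data)
  }
})

test_that("zero exposure yields pure-noise frames with valid calibration", {
  cfg <- fixture_spec("intralipid_single_offaxis", noise = TRUE)
  cfg$gantry$n_views <- 4L
  cfg$gantry$angular_step <- 90
  cfg$exposure <- 1e-6
  v <- simulate_run(cfg)
  for (im in v$images) {
    expect_true(all(is.finite(im$data)))
    expect_true(all(im$data >= 0))
  }
})

test_that("angular capture profiles reproduce the phantom asymmetry", {
  va <- cached_sim("air_single_offaxis")
  vl <- cached_sim("intralipid_single_offaxis")
  pa <- angular_capture_profile(va)
  pl <- angular_capture_profile(vl)
  expect_equal(pa$angle_deg, seq(0, 342, by = 18))
  # air: small modulation from distance change only
  expect_lt(max(pa$total_light) / min(pa$total_light), 1.6)
  # Intralipid: nearest view over farthest view is large
  expect_gt(max(pl$total_light) / min(pl$total_light), 3)
  # scattering boosts the proximal signal relative to air
  expect_gt(max(pl$total_light / pa$total_light), 1.5)
})

test_that("diffusion profile shape agrees with Monte-Carlo transport", {
  vl <- cached_sim("intralipid_single_offaxis")
  prof <- angular_capture_profile(vl)
  med <- vl$scene$medium
  mc <- mc_angular_profile(c(10, 0, 0), 40000, med, vl$cameras, seed = 7)
  # proximal span (within 54 degrees of the source azimuth) carries most of
  # the light and is where the diffusion approximation is quantitative
  ang <- prof$angle_deg
  prox <- ang <= 54 | ang >= 306
  d_n <- prof$total_light[prox] / sum(prof$total_light[prox])
  m_n <- mc[prox] / sum(mc[prox])
  expect_lt(max(abs(d_n / m_n - 1)), 0.10)
  # overall profile structure agrees (monotone decay into the shadow)
  expect_gt(stats::cor(log(prof$total_light), log(mc)), 0.98)
  # both show the near/far asymmetry
  expect_gt(mc[1] / mc[11], 5)
})

test_that("air-mode photon budget closes over a virtual sphere", {
  # quadrature oracle: integrate the detected flux density over directions
  src <- point_source(c(0, 0, 0), 1e10)
  sc <- scene_model(src, medium_registry("air"))
  ccd <- ccd_parameters(prnu_sd = 0, quantum_efficiency = 1)
  d <- 150
  cam <- camera_pose(0, radius = d)
  tot <- sum(render_view(sc, cam, 1, ccd, binning = 4)$data)
  flux_density <- tot / cam$aperture_area      # photons/s/mm^2 at the lens
  expect_equal(flux_density * 4 * pi * d^2, 1e10, tolerance = 0.01)
})
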