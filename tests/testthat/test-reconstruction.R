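# Deblurring kernel, EM update, Green's convolution, backprojection and the
# point-source localization step.

test_that("deblurring kernel is normalized, separable and degenerates to a delta", {
  g <- recon_grid(16, 0.5)
  for (sig in c(0.3, 0.8, 1.5, 3)) {
    k <- make_kernel(sig, g)
    expect_equal(sum(k$array), 1, tolerance = 1e-12)
    expect_true(all(k$array >= 0))
    expect_equal(k$radius, ceiling(3 * sig / 0.5))
  }
  expect_warning(k0 <- make_kernel(0.05, g), "identity")
  expect_equal(max(k0$array), 1, tolerance = 1e-6)
  x <- array(stats::runif(16^3), dim = c(16, 16, 16))
  expect_equal(convolve_kernel(x, k0), x, tolerance = 1e-6)
})

test_that("kernel central weight matches direct Gaussian quadrature", {
  g <- recon_grid(16, 0.5)
  k <- make_kernel(1, g)
  # oracle: voxel-integrated Gaussian, renormalized over the same support
  r <- k$radius
  cells <- vapply((-r):r, function(i) {
    stats::integrate(function(x) stats::dnorm(x, sd = 1),
                     (i - 0.5) * 0.5, (i + 0.5) * 0.5)$value
  }, 0)
  cells <- cells / sum(cells)
  expect_equal(k$taps[r + 1], cells[r + 1], tolerance = 0.02)
})

test_that("EM iteration has the Richardson-Lucy fixed point and conserves flux", {
  # support kept 2 kernel radii from the boundary so the blur is unclipped
  g <- recon_grid(13, 0.5)
  k <- make_kernel(0.5, g)    # radius 3 voxels
  set.seed(4)
  phi <- array(0, dim = c(13, 13, 13))
  phi[6:8, 6:8, 6:8] <- stats::runif(27, 0.5, 2)
  d <- convolve_kernel(phi, k)
  phi1 <- em_iterate(phi, d, k)
  expect_equal(phi1, phi, tolerance = 1e-10)
  # conservation from a uniform start
  u <- array(1, dim = c(13, 13, 13))
  u1 <- em_iterate(u, d, k)
  expect_equal(sum(u1), sum(d), tolerance = 1e-12)
  expect_true(all(u1 >= 0))
  # unnormalized kernel is rejected
  kb <- k
  kb$array <- kb$array * 2
  expect_error(em_iterate(phi, d, kb), "normalized")
})

test_that("em_iterate matches a brute-force small-array oracle", {
  g <- recon_grid(9, 1)
  k <- make_kernel(0.8, g)
  set.seed(8)
  phi <- array(stats::runif(9^3, 0.1, 1), dim = c(9, 9, 9))
  d <- array(0, dim = c(9, 9, 9))
  d[3:7, 3:7, 3:7] <- stats::runif(125, 0, 2)
  got <- em_iterate(phi, d, k)
  want <- brute_rl_iterate(phi, d, k$array)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("RL deblurring sharpens a blurred two-point phantom monotonically", {
  g <- recon_grid(33, 0.5)
  k <- make_kernel(1.0, g)
  truth <- array(0, dim = c(33, 33, 33))
  truth[11, 17, 17] <- 1
  truth[23, 17, 17] <- 1
  d <- convolve_kernel(truth, k)
  phi <- d
  contrast <- function(x) {
    pk <- (x[11, 17, 17] + x[23, 17, 17]) / 2
    pk / x[17, 17, 17]
  }
  cs <- numeric(50)
  for (i in 1:50) {
    phi <- em_iterate(phi, d, k)
    cs[i] <- contrast(phi)
    expect_true(all(phi >= 0))
  }
  expect_true(all(diff(cs) > -1e-9))
  expect_gt(cs[50], cs[1])
  # total stays at the data total throughout
  expect_equal(sum(phi), sum(d), tolerance = 1e-9)
})

test_that("Green's convolution reproduces the sampled Green's function", {
  g <- recon_grid(32, 1)
  med <- lipid()
  src <- array(0, dim = c(32, 32, 32))
  src[16, 16, 16] <- 2.5e9
  phi <- greens_convolve(src, g, med)
  p0 <- index_to_world(g, matrix(c(16L, 16L, 16L), 1))
  for (off in list(c(3, 0, 0), c(0, 5, 0), c(4, 4, 2), c(-6, 1, -3))) {
    idx <- matrix(c(16L, 16L, 16L) + off, 1)
    r <- sqrt(sum((off * 1)^2))
    want <- 2.5e9 * exp(-med$mu_eff * r) / (4 * pi * med$D * r)
    expect_equal(phi[idx], want, tolerance = 1e-9)
  }
  # superposition
  src2 <- array(0, dim = c(32, 32, 32))
  src2[10, 16, 16] <- 1e9
  expect_equal(greens_convolve(src + src2, g, med),
               phi + greens_convolve(src2, g, med), tolerance = 1e-9)
})

test_that("initial fluence peaks at the source and applies data weights", {
  v <- cached_sim("intralipid_single_offaxis")
  grid <- recon_grid()
  est <- mblt:::rasterize_sources(
    data.frame(x_mm = 10, y_mm = 0, z_mm = 0, power_photons_s = 1.4e10),
    grid)
  phi0 <- initial_fluence(est, v$scene$medium, v$scene$mesh, v)
  pkidx <- arrayInd(which.max(phi0$volume), grid$shape)
  pk <- index_to_world(grid, pkidx)
  expect_lt(sqrt(sum((pk - c(10, 0, 0))^2)), 0.5)
  # single unit-power voxel without views: Green's function on the grid
  est1 <- structure(list(volume = array(0, grid$shape), grid = grid),
                    class = "source_estimate")
  est1$volume[32, 32, 32] <- 1
  f1 <- initial_fluence(est1, v$scene$medium)
  expect_equal(f1$volume,
               greens_convolve(est1$volume, grid, v$scene$medium),
               tolerance = 1e-12)
  # superposition of two single-voxel estimates
  est2 <- est1
  est2$volume[20, 32, 32] <- 2
  f2 <- initial_fluence(est2, v$scene$medium)
  d1 <- est2$volume * 0; d1[32, 32, 32] <- 1
  d2 <- est2$volume * 0; d2[20, 32, 32] <- 2
  e1 <- structure(list(volume = d1, grid = grid), class = "source_estimate")
  e2 <- structure(list(volume = d2, grid = grid), class = "source_estimate")
  expect_equal(f2$volume,
               initial_fluence(e1, v$scene$medium)$volume +
                 initial_fluence(e2, v$scene$medium)$volume,
               tolerance = 1e-10)
  # degenerate all-zero estimate warns and returns zero field
  ez <- structure(list(volume = array(0, grid$shape), grid = grid),
                  class = "source_estimate")
  expect_warning(fz <- initial_fluence(ez, v$scene$medium), "zero")
  expect_true(all(fz$volume == 0))
})

test_that("backprojection smear peaks at a centered source", {
  v <- cached_sim("centered_source")
  g11 <- recon_grid(11, 3)
  bp <- backproject_initial(v, v$scene$mesh, g11, v$scene$medium)
  expect_equal(as.integer(arrayInd(which.max(bp$volume), dim(bp$volume))),
               c(6L, 6L, 6L))
  expect_true(all(bp$volume >= 0))
})

test_that("backprojection of a single bright pixel is a sight-line ridge", {
  cam1 <- camera_pose(0, radius = 116.5)
  cam2 <- camera_pose(90, radius = 116.5)
  g <- recon_grid(21, 1)
  blank <- matrix(0, 128, 128)
  bright <- blank
  bright[64, 64] <- 1e6   # on the optical axis of camera 1
  mk <- function(m, cam) detector_image(m, "photons_s_mm2_sr", 60,
                                        cam$view_angle, cam$camera_id, 4L)
  views <- structure(list(
    images = list(mk(bright, cam1), mk(blank, cam2)),
    cameras = list(cam1, cam2)), class = "view_set")
  bp <- backproject_initial(views, NULL, g, medium_registry("air"))
  # the x-axis line (sight line of the bright pixel) carries the ridge
  on_axis <- bp$volume[, 11, 11]
  off_axis <- bp$volume[, 4, 11]
  expect_gt(min(on_axis), max(off_axis) * 10)
  # all-zero views give an all-zero estimate
  views0 <- views
  views0$images <- list(mk(blank, cam1), mk(blank, cam2))
  bp0 <- backproject_initial(views0, NULL, g, medium_registry("air"))
  expect_true(all(bp0$volume == 0))
})

test_that("point-source localization recovers single and double sources", {
  v1 <- cached_sim("intralipid_single_offaxis")
  grid <- recon_grid()
  f1 <- fit_point_sources(v1, grid, v1$scene$medium, v1$scene$mesh)
  expect_equal(nrow(f1), 1)
  expect_lt(sqrt(sum((c(f1$x_mm, f1$y_mm, f1$z_mm) - c(10, 0, 0))^2)), 0.25)
  expect_equal(f1$power_photons_s, 1.4e10, tolerance = 0.02)
  expect_lt(attr(f1, "rel_residual"), 0.01)

  v2 <- cached_sim("intralipid_two_source")
  f2 <- fit_point_sources(v2, grid, v2$scene$medium, v2$scene$mesh)
  expect_equal(nrow(f2), 2)
  xs <- sort(f2$x_mm)
  expect_equal(xs, c(-5, 5), tolerance = 0.05)
  expect_equal(f2$power_photons_s, c(7e9, 7e9), tolerance = 0.05)
})

test_that("views subsets select the advertised frames", {
  v <- cached_sim("intralipid_single_offaxis")
  odd <- mblt:::resolve_views_subset(v, "odd")
  expect_length(odd$images, 10)
  expect_equal(vapply(odd$cameras, `[[`, 0, "view_angle"),
               seq(0, 342, by = 36))
  even <- mblt:::resolve_views_subset(v, "even")
  expect_equal(vapply(even$cameras, `[[`, 0, "view_angle"),
               seq(18, 342, by = 36))
  idx <- mblt:::resolve_views_subset(v, c(1L, 5L))
  expect_length(idx$images, 2)
  expect_error(mblt:::resolve_views_subset(v, "half"), "unknown")
})

test_that("pure-noise input is flagged low SNR, not an exception", {
  cfg <- fixture_spec("intralipid_single_offaxis", noise = TRUE)
  cfg$exposure <- 1e-6                     # essentially no signal
  cfg$gantry$n_views <- 4L
  cfg$gantry$angular_step <- 90
  cfg$recon$max_iter <- 3L
  v <- simulate_run(cfg)
  res <- reconstruct_run(cfg, v)
  expect_s3_class(res, "recon_result")
  expect_true(res$low_snr)
})
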