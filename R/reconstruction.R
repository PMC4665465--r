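# Three-step volumetric reconstruction:
#   1. backprojection of the calibrated views (boundary internal-reflection
#      factor divided out) into the voxel grid, followed by source
#      localization: greedy extraction of point-source candidates from the
#      Green's-function-normalized correlation of the backprojected surface
#      data, refined by nonlinear least squares with measured/predicted
#      intensity-ratio weighting,
#   2. initial photon fluence: the source estimate convolved with the
#      diffusion Green's function, globally rescaled so that its
#      re-projection matches the measured per-view totals,
#   3. iterative Richardson-Lucy / EM deblurring with a Gaussian kernel in
#      the volume domain, followed by a data-consistency power calibration
#      of the final map.
# Surface measurements of the diffuse fluence cannot distinguish a deep
# source from an equivalent shallower shell (the BLT inverse problem is
# degenerate), so the localization step fits an explicit point-source model
# -- the regime the instrument targets -- instead of an unconstrained
# voxel inversion.

#' Reconstruction configuration
#'
#' @param sigma_mm Gaussian deblurring kernel width (mm).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative change per iteration.
#' @param correct_boundary Divide out the boundary internal-reflection factor
#'   before backprojection (turbid media).
#' @param views_subset `"all"`, `"even"`, `"odd"`, or integer view indices.
#' @param max_sources Maximum number of point-source components extracted by
#'   the localization step.
#' @param fit_rel_tol Weighted relative residual below which no further
#'   source components are added.
#' @param fit_improve A new component is kept only if it shrinks the
#'   relative residual below this fraction of the previous one.
#' @param log_data_residual Also log, per EM iteration, the relative
#'   residual between the measured surface data and the re-projection of the
#'   current iterate (costs one extra convolution per iteration).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(sigma_mm = 1.5, max_iter = 200, tol = 1e-4,
                         correct_boundary = TRUE, views_subset = "all",
                         max_sources = 3L, fit_rel_tol = 0.04,
                         fit_improve = 0.75, log_data_residual = FALSE) {
  stopifnot(sigma_mm > 0, max_iter >= 1, tol >= 0, max_sources >= 1)
  structure(list(sigma_mm = sigma_mm, max_iter = as.integer(max_iter),
                 tol = tol, correct_boundary = correct_boundary,
                 views_subset = views_subset,
                 max_sources = as.integer(max_sources),
                 fit_rel_tol = fit_rel_tol, fit_improve = fit_improve,
                 log_data_residual = isTRUE(log_data_residual)),
            class = "recon_config")
}

#' Default reconstruction grid for a phantom
#'
#' Cube of `n^3` voxels centered on the gantry axis, cropped to the phantom
#' footprint.
#'
#' @param n Voxels per side.
#' @param voxel_size Voxel edge (mm).
#' @return A `voxel_grid`.
#' @export
recon_grid <- function(n = 64, voxel_size = 0.5) {
  voxel_grid(c(n, n, n), voxel_size, origin = -c(n, n, n) * voxel_size / 2)
}

#' Gaussian deblurring kernel
#'
#' Discretized isotropic 3-D Gaussian, truncated at 3 sigma per axis and
#' normalized to unit sum. Separable: the 3-D kernel is the outer product of
#' identical 1-D tap vectors, which is how convolutions are evaluated.
#'
#' @param sigma_mm Kernel width sigma (mm), > 0.
#' @param grid The `voxel_grid` the kernel will act on (fixes the tap
#'   spacing).
#' @return An object of class `deblur_kernel` with elements `taps` (1-D),
#'   `array` (3-D, sums to 1), `radius` (voxels), `sigma_mm`, `voxel_size`.
#' @export
make_kernel <- function(sigma_mm, grid) {
  stopifnot(sigma_mm > 0)
  h <- grid$voxel_size
  if (sigma_mm < 0.25 * h) {
    warning("sigma below 0.25 voxel: kernel degenerates to identity")
  }
  radius <- max(0L, as.integer(ceiling(3 * sigma_mm / h)))
  off <- (-radius):radius
  taps <- exp(-(off * h)^2 / (2 * sigma_mm^2))
  taps <- taps / sum(taps)
  arr <- outer(outer(taps, taps), taps)
  dim(arr) <- c(length(taps), length(taps), length(taps))
  structure(list(taps = taps, array = arr, radius = radius,
                 sigma_mm = sigma_mm, voxel_size = h,
                 bands = new.env(parent = emptyenv())),
            class = "deblur_kernel")
}

# Symmetric banded Toeplitz convolution matrix for one axis (zero-padded
# boundary); cached per axis length inside the kernel object.
.kernel_band <- function(kernel, n) {
  key <- as.character(n)
  m <- kernel$bands[[key]]
  if (!is.null(m)) return(m)
  r <- kernel$radius
  m <- matrix(0, n, n)
  for (k in (-r):r) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    m[cbind(i[ok], j[ok])] <- kernel$taps[k + r + 1]
  }
  kernel$bands[[key]] <- m
  m
}

#' Separable 3-D convolution with a deblurring kernel
#'
#' Zero-padded (values beyond the grid are zero) separable convolution. The
#' kernel is symmetric, so this operator is self-adjoint, which makes the EM
#' update exactly flux-preserving for interior-supported data.
#'
#' @param x 3-D array.
#' @param kernel A `deblur_kernel`.
#' @return Convolved array of the same shape.
#' @export
convolve_kernel <- function(x, kernel) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (kernel$radius == 0L) return(x)
  m1 <- .kernel_band(kernel, d[1])
  dim(x) <- c(d[1], d[2] * d[3])
  x <- m1 %*% x
  dim(x) <- d
  x <- aperm(x, c(2, 1, 3))
  m2 <- .kernel_band(kernel, d[2])
  dim(x) <- c(d[2], d[1] * d[3])
  x <- m2 %*% x
  dim(x) <- c(d[2], d[1], d[3])
  x <- aperm(x, c(3, 2, 1))   # now (z, x, y)
  m3 <- .kernel_band(kernel, d[3])
  dim(x) <- c(d[3], d[1] * d[2])
  x <- m3 %*% x
  dim(x) <- c(d[3], d[1], d[2])
  aperm(x, c(2, 3, 1))
}

# --- diffusion Green's-function convolution on the grid (FFT-based) --------

.greens_fft_cache <- new.env(parent = emptyenv())

.greens_fft <- function(grid, medium, power = 1) {
  key <- paste(c(grid$shape, grid$voxel_size, medium$mu_eff, medium$D, power),
               collapse = "_")
  got <- .greens_fft_cache[[key]]
  if (!is.null(got)) return(got)
  n <- grid$shape
  p <- 2L * n
  h <- grid$voxel_size
  offs <- lapply(1:3, function(a) {
    k <- c(0:(p[a] %/% 2 - 1), -(p[a] - p[a] %/% 2):-1)
    k * h
  })
  r2 <- outer(outer(offs[[1]]^2, offs[[2]]^2, "+"), offs[[3]]^2, "+")
  r <- sqrt(r2)
  r[r < h / 2] <- h / 2   # regularize the 1/r singularity at zero offset
  kern <- (exp(-medium$mu_eff * r) / (4 * pi * medium$D * r))^power
  res <- list(fftk = stats::fft(kern), p = p)
  .greens_fft_cache[[key]] <- res
  res
}

.greens_conv_raw <- function(x, grid, medium, power = 1) {
  gk <- .greens_fft(grid, medium, power)
  p <- gk$p
  xp <- array(0, dim = p)
  n <- grid$shape
  xp[1:n[1], 1:n[2], 1:n[3]] <- x
  y <- Re(stats::fft(stats::fft(xp) * gk$fftk, inverse = TRUE)) / prod(p)
  y[1:n[1], 1:n[2], 1:n[3]]
}

#' Convolve a per-voxel source map with the diffusion Green's function
#'
#' \eqn{\phi_j = \sum_i s_i \exp(-\mu_{eff} r_{ij}) / (4 \pi D r_{ij})},
#' evaluated by zero-padded FFT convolution on the grid (the self-distance is
#' regularized at half a voxel).
#'
#' @param source 3-D array of per-voxel source powers (photons/s).
#' @param grid The `voxel_grid`.
#' @param medium Turbid `optical_medium`.
#' @return 3-D fluence array (photons/s/mm^2).
#' @export
greens_convolve <- function(source, grid, medium) {
  stopifnot(all(dim(source) == grid$shape), medium$turbid)
  .greens_conv_raw(source, grid, medium, power = 1)
}

# Trilinear interpolation of a grid volume at world points; NA outside.
interp_volume <- function(vol, grid, pts) {
  h <- grid$voxel_size
  # continuous voxel coordinate: center of voxel i at i - 0.5
  f <- sweep(pts, 2, grid$origin) / h + 0.5
  n <- grid$shape
  i0 <- floor(f)
  w <- f - i0
  out <- rep(NA_real_, nrow(pts))
  ok <- i0[, 1] >= 1 & i0[, 1] < n[1] &
        i0[, 2] >= 1 & i0[, 2] < n[2] &
        i0[, 3] >= 1 & i0[, 3] < n[3]
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  wk <- w[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) wk[, 1] else 1 - wk[, 1]) *
          (if (dy) wk[, 2] else 1 - wk[, 2]) *
          (if (dz) wk[, 3] else 1 - wk[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    acc <- acc + wt * vol[idx]
  }
  out[ok] <- acc
  out
}

# Backproject the calibrated surface data into the boundary voxels of the
# grid: every pixel's surface-fluence estimate (radiance divided by the
# boundary-exitance factor) is accumulated in the voxel containing its
# surface hit point. Returns the splatted data, hit counts, and per-voxel
# mean hit positions.
surface_splat <- function(views, grid, medium, mesh,
                          correct_boundary = TRUE) {
  c_b <- if (correct_boundary) boundary_exitance(1, medium = medium) else 1
  n <- grid$shape
  y <- array(0, n)
  q <- array(0, n)
  sx <- array(0, n); sy <- array(0, n); sz <- array(0, n)
  for (i in seq_along(views$images)) {
    im <- views$images[[i]]
    if (im$units != "photons_s_mm2_sr") {
      stop("surface splat needs calibrated views (photons_s_mm2_sr)")
    }
    cam <- views$cameras[[i]]
    pr <- camera_pixel_rays(cam, im$binning)
    orig <- matrix(cam$position, nrow(pr$dir), 3, byrow = TRUE)
    hit <- ray_cylinder(orig, pr$dir, mesh$primitive)
    idx <- which(hit$hit)
    if (!length(idx)) next
    yv <- im$data[idx] / c_b
    P <- hit$point[idx, , drop = FALSE]
    vi <- world_to_index(grid, P)
    ok <- vi[, 1] >= 1 & vi[, 1] <= n[1] &
          vi[, 2] >= 1 & vi[, 2] <= n[2] &
          vi[, 3] >= 1 & vi[, 3] <= n[3]
    if (!any(ok)) next
    lin <- vi[ok, 1] + n[1] * (vi[ok, 2] - 1L) + n[1] * n[2] * (vi[ok, 3] - 1L)
    add <- function(arr, val) {
      t <- tapply(val, lin, sum)
      ii <- as.integer(names(t))
      arr[ii] <- arr[ii] + t
      arr
    }
    y <- add(y, yv[ok])
    q <- add(q, rep(1, sum(ok)))
    sx <- add(sx, P[ok, 1]); sy <- add(sy, P[ok, 2]); sz <- add(sz, P[ok, 3])
  }
  w <- which(q > 0)
  list(lin = w, y = y[w], q = q[w],
       X = cbind(sx[w], sy[w], sz[w]) / q[w],
       yvol = y, qvol = q)
}

#' Localize point sources in a calibrated turbid acquisition
#'
#' Step-1 source localization: the calibrated surface data are backprojected
#' onto the phantom surface, point-source candidates are extracted greedily
#' from the Green's-function-normalized correlation field (for a single
#' source the correlation maximum coincides with the true source voxel), and
#' all candidate positions are refined jointly by nonlinear least squares
#' against the surface data, with amplitudes profiled out linearly.
#' Components are added while the weighted relative residual exceeds
#' `rel_tol` and each addition improves it by the required factor; this
#' model-order rule is what makes a degenerate deep pair collapse to its
#' equivalent single source.
#'
#' @param views A `view_set` of calibrated images (turbid scene).
#' @param grid Reconstruction `voxel_grid`.
#' @param medium Turbid `optical_medium`.
#' @param mesh Phantom `surface_mesh` with a cylinder primitive.
#' @param max_sources Maximum components.
#' @param rel_tol Stop when the relative residual falls below this.
#' @param improve Required residual shrink factor per added component.
#' @return Data frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `power_photons_s`; attribute `rel_residual`.
#' @export
fit_point_sources <- function(views, grid, medium, mesh, max_sources = 3L,
                              rel_tol = 0.04, improve = 0.75) {
  sp <- surface_splat(views, grid, medium, mesh)
  if (!length(sp$lin) || sum(sp$y) <= 0) {
    out <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), power_photons_s = numeric(0))
    attr(out, "rel_residual") <- 1
    return(out)
  }
  prim <- mesh$primitive
  den2 <- .greens_conv_raw(sp$qvol, grid, medium, power = 2)
  ctr <- grid_centers(grid)
  interior <- inside_mesh(mesh, ctr, margin = 1.5)
  gfun <- function(r) exp(-medium$mu_eff * r) / (4 * pi * medium$D * r)
  corr_argmax <- function(uvol) {
    num <- greens_convolve(uvol, grid, medium)
    cf <- num / sqrt(pmax(den2, 1e-300))
    cf[!interior] <- -Inf
    index_to_world(grid, arrayInd(which.max(cf), grid$shape))
  }
  wts <- 1 / sp$q
  profile_fit <- function(P) {
    k <- nrow(P)
    A <- vapply(seq_len(k), function(j) {
      r <- sqrt(rowSums(sweep(sp$X, 2, P[j, ])^2))
      sp$q * gfun(pmax(r, grid$voxel_size / 2))
    }, numeric(length(sp$y)))
    A <- matrix(A, ncol = k)
    M <- crossprod(A, A * wts)
    b <- crossprod(A, sp$y * wts)
    a <- tryCatch(as.numeric(solve(M, b)), error = function(e) rep(0, k))
    a <- pmax(a, 0)
    res <- sp$y - as.numeric(A %*% a)
    list(ss = sum(res^2 * wts), a = a, res = res)
  }
  # soft barrier keeping candidate positions inside the phantom
  penalized <- function(theta) {
    P <- matrix(theta, ncol = 3)
    o <- profile_fit(P)$ss
    rr <- sqrt((P[, 1] - prim$center[1])^2 + (P[, 2] - prim$center[2])^2)
    over_r <- pmax(rr - (prim$radius - 1), 0)
    over_z <- pmax(abs(P[, 3] - prim$center[3]) - (prim$height / 2 - 1), 0)
    o * (1 + sum(over_r^2) + sum(over_z^2))
  }
  ss0 <- sum(sp$y^2 * wts)
  fitted <- NULL
  relres <- 1
  ures <- sp$yvol
  for (k in seq_len(max_sources)) {
    p_new <- corr_argmax(ures)
    P0 <- rbind(if (!is.null(fitted)) fitted$P, p_new)
    op <- stats::optim(as.numeric(P0), penalized, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    P <- matrix(op$par, ncol = 3)
    o <- profile_fit(P)
    rel_new <- sqrt(o$ss / ss0)
    if (k > 1 && rel_new > relres * improve) break
    fitted <- list(P = P, a = o$a)
    relres <- rel_new
    if (relres <= rel_tol) break
    ures <- array(0, grid$shape)
    ures[sp$lin] <- pmax(o$res, 0)
  }
  keep <- fitted$a > 0
  out <- data.frame(x_mm = fitted$P[keep, 1], y_mm = fitted$P[keep, 2],
                    z_mm = fitted$P[keep, 3],
                    power_photons_s = fitted$a[keep])
  out <- out[order(-out$power_photons_s), , drop = FALSE]
  attr(out, "rel_residual") <- relres
  out
}

#' Localize point sources in a transparent (air) acquisition
#'
#' Each view's intensity-weighted image centroid defines a ray through the
#' lens center; the source position is initialized at the least-squares
#' intersection of all rays and refined, with its power, by nonlinear least
#' squares against the rendered pixel model. Additional components are
#' extracted from the residual images under the same model-order rule as the
#' turbid fit.
#'
#' @inheritParams fit_point_sources
#' @return Data frame as in [fit_point_sources()].
#' @export
fit_point_sources_air <- function(views, grid, medium,
                                  max_sources = 3L, rel_tol = 0.04,
                                  improve = 0.75) {
  nv <- length(views$images)
  eta <- lapply(seq_len(nv), function(i) {
    pixel_etendue(views$cameras[[i]], views$images[[i]]$binning)
  })
  meas <- lapply(seq_len(nv), function(i) views$images[[i]]$data * eta[[i]])
  render_unit <- function(P) {
    # detected photons/s per pixel for unit-power sources at rows of P
    lapply(seq_len(nv), function(i) {
      cam <- views$cameras[[i]]
      im <- views$images[[i]]
      src <- lapply(seq_len(nrow(P)), function(j) point_source(P[j, ], 1))
      sc <- scene_model(src, medium)
      r <- render_view(sc, cam, exposure = 1,
                       ccd = ccd_parameters(quantum_efficiency = 1,
                                            prnu_sd = 0),
                       binning = im$binning)
      r$data
    })
  }
  ray_intersect <- function(imgs) {
    # least-squares point closest to all image-centroid rays
    M <- matrix(0, 3, 3)
    b <- numeric(3)
    for (i in seq_len(nv)) {
      w <- imgs[[i]]
      tot <- sum(w)
      if (tot <= 0) next
      g <- camera_pixel_geometry(views$cameras[[i]],
                                 views$images[[i]]$binning)
      u0 <- sum(row(w) * w) / tot
      v0 <- sum(col(w) * w) / tot
      cam <- views$cameras[[i]]
      d <- cam$axis +
        (u0 - g$c0) * g$pitch / cam$image_distance * cam$right +
        (v0 - g$c0) * g$pitch / cam$image_distance * cam$up
      d <- d / sqrt(sum(d^2))
      Pm <- diag(3) - tcrossprod(d)
      M <- M + tot * Pm
      b <- b + tot * as.numeric(Pm %*% cam$position)
    }
    as.numeric(solve(M, b))
  }
  fit_k <- function(P0) {
    obj <- function(theta) {
      P <- matrix(theta, ncol = 3)
      # profile out per-component amplitudes via linear LS
      k <- nrow(P)
      A <- vapply(seq_len(k), function(j) {
        unlist(lapply(seq_len(nv), function(i) {
          as.numeric(render_unit(P[j, , drop = FALSE])[[i]])
        }))
      }, numeric(length(unlist(meas))))
      y <- unlist(meas)
      M <- crossprod(A)
      a <- tryCatch(pmax(as.numeric(solve(M, crossprod(A, y))), 0),
                    error = function(e) rep(0, k))
      sum((y - as.numeric(A %*% a))^2)
    }
    op <- stats::optim(as.numeric(P0), obj, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-8))
    P <- matrix(op$par, ncol = 3)
    k <- nrow(P)
    A <- vapply(seq_len(k), function(j) {
      unlist(lapply(render_unit(P[j, , drop = FALSE]), as.numeric))
    }, numeric(length(unlist(meas))))
    y <- unlist(meas)
    a <- tryCatch(pmax(as.numeric(solve(crossprod(A), crossprod(A, y))), 0),
                  error = function(e) rep(0, k))
    res <- y - as.numeric(A %*% a)
    list(P = P, a = a, relres = sqrt(sum(res^2) / sum(y^2)), res = res)
  }
  fitted <- NULL
  relres <- 1
  resid_imgs <- meas
  for (k in seq_len(max_sources)) {
    p_new <- tryCatch(ray_intersect(resid_imgs), error = function(e) c(0, 0, 0))
    f <- fit_k(rbind(if (!is.null(fitted)) fitted$P, p_new))
    if (k > 1 && f$relres > relres * improve) break
    fitted <- f
    relres <- f$relres
    if (relres <= rel_tol) break
    # residual images for the next extraction
    npix <- vapply(meas, length, 0L)
    splits <- split(pmax(fitted$res, 0), rep(seq_len(nv), npix))
    resid_imgs <- lapply(seq_len(nv), function(i) {
      matrix(splits[[i]], nrow(meas[[i]]), ncol(meas[[i]]))
    })
  }
  keep <- fitted$a > 0
  out <- data.frame(x_mm = fitted$P[keep, 1], y_mm = fitted$P[keep, 2],
                    z_mm = fitted$P[keep, 3],
                    power_photons_s = fitted$a[keep])
  out <- out[order(-out$power_photons_s), , drop = FALSE]
  attr(out, "rel_residual") <- relres
  out
}

# Deposit fitted point sources on the grid with trilinear mass splitting, so
# sub-voxel positions survive voxelization.
rasterize_sources <- function(fit, grid) {
  vol <- array(0, grid$shape)
  n <- grid$shape
  h <- grid$voxel_size
  for (j in seq_len(nrow(fit))) {
    f <- (c(fit$x_mm[j], fit$y_mm[j], fit$z_mm[j]) - grid$origin) / h + 0.5
    i0 <- floor(f)
    w <- f - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz)
      if (any(ii < 1) || any(ii > n)) next
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      vol[ii[1], ii[2], ii[3]] <- vol[ii[1], ii[2], ii[3]] +
        wt * fit$power_photons_s[j]
    }
  }
  structure(list(volume = vol, grid = grid, units = "photons_s"),
            class = "source_estimate")
}

#' Backprojection initialization
#'
#' Backprojects the detected surface intensities of every view along their
#' lines of sight into the voxel grid. For each voxel and view, the detected
#' intensity along the voxel's sight line is compensated for attenuation
#' with the inverse Green's function, `exp(+mu_eff * depth) * 4 pi D depth`
#' (depth = path from the voxel to the surface toward the camera), giving a
#' per-view source-power hypothesis; in air the compensation is the
#' inverse-square falloff. The boundary internal-reflection factor is
#' divided out of the data first, so the transmitted (not the internally
#' reflected) intensity is backprojected. Per-view hypotheses are
#' accumulated as their geometric mean, which is maximal where all views
#' agree: a voxel holding a real source receives consistent hypotheses from
#' every view, while the smear elsewhere is penalized for inconsistency.
#'
#' @param views A `view_set` of calibrated images.
#' @param mesh Phantom `surface_mesh` (`NULL` in air).
#' @param grid Reconstruction `voxel_grid`.
#' @param medium The `optical_medium`.
#' @param correct_boundary Divide out the boundary-exitance factor.
#' @return An object of class `source_estimate` (source-power scale).
#' @export
backproject_initial <- function(views, mesh, grid, medium,
                                correct_boundary = TRUE) {
  stopifnot(length(views$images) >= 2)
  ctr <- grid_centers(grid)
  nvox <- nrow(ctr)
  sel <- if (medium$turbid && !is.null(mesh)) {
    which(inside_mesh(mesh, ctr))
  } else {
    seq_len(nvox)
  }
  pts <- ctr[sel, , drop = FALSE]
  c_b <- if (medium$turbid && correct_boundary) {
    boundary_exitance(1, medium = medium)
  } else 1
  nv <- length(views$images)
  acc <- numeric(length(sel))      # sum of log hypotheses
  gmax <- 0
  hyp <- vector("list", nv)
  for (i in seq_len(nv)) {
    im <- views$images[[i]]
    if (im$units != "photons_s_mm2_sr") {
      stop("backprojection needs calibrated views (photons_s_mm2_sr)")
    }
    cam <- views$cameras[[i]]
    rate <- detected_rate(im, cam) / c_b
    pr <- project_to_pixels(cam, pts, im$binning)
    ok <- pr$in_fov
    p <- numeric(length(sel))
    if (any(ok)) {
      pix <- cbind(as.integer(round(pr$u[ok])), as.integer(round(pr$v[ok])))
      p[ok] <- rate[pix]
    }
    if (medium$turbid) {
      to_cam <- sweep(-pts, 2, cam$position, "+")
      d <- sqrt(rowSums(to_cam^2))
      hit <- ray_cylinder(pts, to_cam / d, mesh$primitive)
      depth <- pmax(ifelse(hit$hit, hit$t, 0), grid$voxel_size / 2)
      w <- exp(medium$mu_eff * depth) * 4 * pi * medium$D * depth
    } else {
      w <- 4 * pi * pr$dist^2 / (cam$aperture_area *
                                   (pr$depth / pr$dist)^4)
    }
    hyp[[i]] <- p * w
    gmax <- max(gmax, hyp[[i]])
  }
  est <- numeric(nvox)
  if (gmax > 0) {
    floor_val <- 1e-12 * gmax
    for (i in seq_len(nv)) acc <- acc + log(pmax(hyp[[i]], floor_val))
    est[sel] <- exp(acc / nv)
    est[est <= floor_val] <- 0
  }
  vol <- array(est, dim = grid$shape)
  structure(list(volume = vol, grid = grid, units = "photons_s"),
            class = "source_estimate")
}

# Per-view measured and predicted totals (photons/s) over a common pixel
# subset, given a candidate source volume. Turbid: predicted surface fluence
# is the Green's-function convolution interpolated at each pixel's surface
# hit point; air: direct inverse-square projection of the source voxels.
view_totals <- function(views, source_vol, grid, medium, mesh,
                        fluence_vol = NULL) {
  nv <- length(views$images)
  meas <- numeric(nv)
  pred <- numeric(nv)
  if (medium$turbid) {
    if (is.null(fluence_vol)) {
      fluence_vol <- greens_convolve(source_vol, grid, medium)
    }
    c_b <- boundary_exitance(1, medium = medium)
    zmax <- grid$origin[3] + grid$shape[3] * grid$voxel_size
    for (i in seq_len(nv)) {
      im <- views$images[[i]]
      cam <- views$cameras[[i]]
      pr <- camera_pixel_rays(cam, im$binning)
      orig <- matrix(cam$position, nrow(pr$dir), 3, byrow = TRUE)
      hit <- ray_cylinder(orig, pr$dir, mesh$primitive)
      idx <- which(hit$hit &
                     abs(hit$point[, 3]) < zmax - grid$voxel_size)
      phat <- interp_volume(fluence_vol, grid, hit$point[idx, , drop = FALSE])
      keep <- is.finite(phat)
      idx <- idx[keep]
      eta <- pixel_etendue(cam, im$binning)
      pred[i] <- sum(c_b * phat[keep] * eta[idx])
      meas[i] <- sum(detected_rate(im, cam)[idx])
    }
  } else {
    nz <- which(source_vol > max(source_vol) * 1e-9)
    pts <- index_to_world(grid, arrayInd(nz, grid$shape))
    s <- source_vol[nz]
    for (i in seq_len(nv)) {
      im <- views$images[[i]]
      cam <- views$cameras[[i]]
      pr <- project_to_pixels(cam, pts, im$binning)
      ok <- pr$in_fov
      cosa <- pr$depth / pr$dist
      pred[i] <- sum(s[ok] * cam$aperture_area /
                       (4 * pi * pr$dist[ok]^2) * cosa[ok]^4)
      meas[i] <- sum(detected_rate(im, cam))
    }
  }
  list(meas = meas, pred = pred)
}

#' Initial photon fluence from a backprojected source estimate
#'
#' Turbid media: convolves the estimate with the diffusion Green's function
#' and rescales it once so its re-projection onto the detectors matches the
#' measured per-view totals (the measured-over-estimated intensity ratio
#' applied as a global data-consistency weight). Transparent media bypass the
#' diffusion step and return the (rescaled) estimate itself.
#'
#' @param estimate A `source_estimate` from [backproject_initial()].
#' @param medium The `optical_medium`.
#' @param mesh Phantom `surface_mesh` (turbid media).
#' @param views The `view_set` (for the data-consistency weights).
#' @return An object of class `fluence_field` (`volume`, `grid`,
#'   `iteration = 0`).
#' @export
initial_fluence <- function(estimate, medium, mesh = NULL, views = NULL) {
  vol <- estimate$volume
  if (any(vol < 0)) stop("source estimate must be non-negative")
  grid <- estimate$grid
  if (all(vol == 0)) {
    warning("all-zero source estimate: zero fluence field")
    return(structure(list(volume = vol, grid = grid, iteration = 0L),
                     class = "fluence_field"))
  }
  if (medium$turbid) {
    phi <- greens_convolve(vol, grid, medium)
    phi[phi < 0] <- 0
  } else {
    phi <- vol
  }
  if (!is.null(views)) {
    vt <- view_totals(views, vol, grid, medium, mesh,
                      fluence_vol = if (medium$turbid) phi else NULL)
    scl <- sum(vt$meas) / sum(vt$pred)
    if (is.finite(scl) && scl > 0) phi <- phi * scl
  }
  structure(list(volume = phi, grid = grid, iteration = 0L),
            class = "fluence_field")
}

#' One Richardson-Lucy / EM deblurring iteration
#'
#' Multiplicative update
#' \deqn{\phi^{n+1} = \phi^n \cdot [ (d / (\phi^n \otimes \varrho))
#'   \otimes \hat\varrho ]}
#' with \eqn{\hat\varrho} the mirrored (here: symmetric, hence identical)
#' kernel. Ratios at zero-denominator voxels are defined as 0. Non-negativity
#' is preserved; with a unit-sum kernel and interior-supported data the total
#' intensity equals the total of `d` after every iteration.
#'
#' @param phi Current iterate: `fluence_field` or bare 3-D array, >= 0.
#' @param data Target field (same type/shape).
#' @param kernel A normalized `deblur_kernel`.
#' @return Updated iterate of the same type as `phi`.
#' @export
em_iterate <- function(phi, data, kernel) {
  is_field <- inherits(phi, "fluence_field")
  p <- if (is_field) phi$volume else phi
  d <- if (inherits(data, "fluence_field")) data$volume else data
  if (abs(sum(kernel$array) - 1) > 1e-9) {
    stop("deblurring kernel must be normalized to unit sum")
  }
  if (any(p < 0)) stop("EM iterate requires a non-negative field")
  blur <- convolve_kernel(p, kernel)
  ratio <- d / blur
  ratio[!is.finite(ratio)] <- 0
  out <- p * convolve_kernel(ratio, kernel)
  out[out < 0] <- 0   # guard tiny negative round-off
  if (is_field) {
    phi$volume <- out
    phi$iteration <- phi$iteration + 1L
    phi
  } else {
    out
  }
}

resolve_views_subset <- function(views, subset) {
  n <- length(views$images)
  idx <- if (is.character(subset)) {
    switch(subset,
           all = seq_len(n),
           odd = seq(1, n, by = 2),
           even = seq(2, n, by = 2),
           stop("unknown views_subset: ", subset))
  } else {
    as.integer(subset)
  }
  stopifnot(all(idx >= 1), all(idx <= n))
  views$images <- views$images[idx]
  views$cameras <- views$cameras[idx]
  views$exposure <- views$exposure[idx]
  views
}

# Per-view signal-to-noise heuristic: peak excursion of the 5x5
# box-smoothed detected rate over the spread of the unsmoothed residual.
# A real diffuse source is spatially coherent (smoothing preserves it while
# the residual stays at the noise floor); uncorrelated noise or sparse
# quantization speckle is suppressed 5-fold by the box, scoring order 1.
views_snr <- function(views) {
  vapply(seq_along(views$images), function(i) {
    r <- detected_rate(views$images[[i]], views$cameras[[i]])
    if (all(r == 0)) return(0)
    n1 <- nrow(r); n2 <- ncol(r)
    sm <- matrix(0, n1, n2)
    for (du in -2:2) for (dv in -2:2) {
      su <- pmin(pmax(seq_len(n1) + du, 1), n1)
      sv <- pmin(pmax(seq_len(n2) + dv, 1), n2)
      sm <- sm + r[su, sv] / 25
    }
    noise_est <- stats::sd(r - sm)
    if (noise_est <= 0) return(0)    # featureless frame
    (max(sm) - stats::median(sm)) / noise_est
  }, 0)
}

#' Full three-step reconstruction
#'
#' Backprojection initialization, diffusion initial fluence, and iterative
#' Gaussian EM deblurring, followed by a global data-consistency calibration
#' of the final map into absolute source power (photons/s): the map is
#' rescaled so its re-projection matches the measured per-view totals.
#'
#' @param views A `view_set` of calibrated images.
#' @param config A [recon_config()].
#' @param grid Reconstruction grid (default: 64^3 at 0.5 mm centered on the
#'   gantry axis).
#' @return An object of class `recon_result` with the final `fluence_field`,
#'   the absolute `source_estimate`, the per-iteration log (total intensity,
#'   relative change, relative residual), convergence and SNR flags.
#' @export
reconstruct <- function(views, config = recon_config(), grid = recon_grid()) {
  views <- resolve_views_subset(views, config$views_subset)
  medium <- views$scene$medium
  mesh <- views$scene$mesh
  snr <- views_snr(views)
  low_snr <- stats::median(snr) < 5

  fit <- if (medium$turbid) {
    fit_point_sources(views, grid, medium, mesh,
                      max_sources = config$max_sources,
                      rel_tol = config$fit_rel_tol,
                      improve = config$fit_improve)
  } else {
    fit_point_sources_air(views, grid, medium,
                          max_sources = config$max_sources,
                          rel_tol = config$fit_rel_tol,
                          improve = config$fit_improve)
  }
  est <- rasterize_sources(fit, grid)
  phi0 <- suppressWarnings(initial_fluence(est, medium, mesh, views))
  kernel <- make_kernel(config$sigma_mm, grid)
  splat_ref <- if (config$log_data_residual && medium$turbid) {
    surface_splat(views, grid, medium, mesh)
  } else NULL

  # EM deblurring restricted to the physical domain (phantom interior for
  # turbid scenes), with the kernel column-sum (sensitivity) normalization
  # that makes the multiplicative update correct at the domain boundary.
  mask <- if (medium$turbid && !is.null(mesh)) {
    array(inside_mesh(mesh, grid_centers(grid)), dim = grid$shape)
  } else {
    array(TRUE, dim = grid$shape)
  }
  sens <- convolve_kernel(array(as.numeric(mask), dim = grid$shape), kernel)
  sens[sens < 1e-12] <- 1

  d <- phi0$volume
  d[!mask] <- 0
  p <- d
  dnorm2 <- sqrt(mean(d^2))
  log_total <- numeric(0)
  log_change <- numeric(0)
  log_resid <- numeric(0)
  log_dresid <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    blur <- convolve_kernel(p, kernel)
    resid <- if (dnorm2 > 0) sqrt(mean((d - blur)^2)) / dnorm2 else 0
    ratio <- d / blur
    ratio[!is.finite(ratio)] <- 0
    pn <- p * convolve_kernel(ratio, kernel) / sens
    pn[!mask] <- 0
    pn[pn < 0] <- 0
    tot_prev <- sum(p)
    change <- if (tot_prev > 0) sum(abs(pn - p)) / tot_prev else 0
    p <- pn
    log_total <- c(log_total, sum(p))
    log_change <- c(log_change, change)
    log_resid <- c(log_resid, resid)
    if (!is.null(splat_ref)) {
      yhat <- splat_ref$q *
        greens_convolve(p, grid, medium)[splat_ref$lin]
      cs <- sum(splat_ref$y * yhat) / sum(yhat^2)
      if (!is.finite(cs)) cs <- 0
      log_dresid <- c(log_dresid,
                      sqrt(sum((splat_ref$y - cs * yhat)^2) /
                             sum(splat_ref$y^2)))
    }
    if (change < config$tol) {
      converged <- TRUE
      break
    }
  }

  # absolute power calibration by data consistency: the fitted point-source
  # amplitudes are the data-consistent total (their re-projection through
  # the exact forward model matches the measured views), so the deblurred
  # map is normalized to carry that total. If no source model was fitted,
  # fall back to re-projecting the volume itself.
  scl <- 1
  fit_total <- sum(fit$power_photons_s)
  if (sum(p) > 0) {
    if (fit_total > 0) {
      scl <- fit_total / sum(p)
    } else {
      vt <- view_totals(views, p, grid, medium, mesh)
      scl <- sum(vt$meas) / sum(vt$pred)
      if (!is.finite(scl) || scl <= 0) scl <- 1
    }
  }
  src <- structure(list(volume = p * scl, grid = grid,
                        units = "photons_s"),
                   class = "source_estimate")
  fluence <- structure(list(volume = p, grid = grid,
                            iteration = length(log_total)),
                       class = "fluence_field")
  log_df <- data.frame(iteration = seq_along(log_total),
                       total = log_total, rel_change = log_change,
                       rel_residual = log_resid)
  if (length(log_dresid)) log_df$data_residual <- log_dresid
  structure(list(
    fluence = fluence, source = src, fit = fit,
    log = log_df,
    converged = converged, low_snr = low_snr, snr = snr,
    power_scale = scl, config = config, grid = grid,
    n_views = length(views$images)
  ), class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "<recon_result> %d views, %d iterations (%s), total power %.4g photons/s%s\n",
    x$n_views, nrow(x$log),
    if (x$converged) "converged" else "max iterations",
    sum(x$source$volume),
    if (x$low_snr) " [LOW SNR]" else ""))
  invisible(x)
}
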