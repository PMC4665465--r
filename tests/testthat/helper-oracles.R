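# Independent oracles used by the test suite. These deliberately avoid the
# package's computational paths: brute-force loops, quadrature, and a
# Monte-Carlo photon-transport walk.

# Brute-force local-maximum detector: 26-neighborhood scan with explicit
# loops, no suppression, no refinement.
brute_local_maxima <- function(vol, threshold_frac) {
  n <- dim(vol)
  lev <- threshold_frac * max(vol)
  out <- NULL
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    v <- vol[i, j, k]
    if (v < lev) next
    is_max <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > n[1] || jj < 1 || jj > n[2] || kk < 1 || kk > n[3]) next
      if (vol[ii, jj, kk] > v) { is_max <- FALSE; break }
    }
    if (is_max) out <- rbind(out, c(i, j, k))
  }
  out
}

# Brute-force zero-padded convolution of a 3-D array with a separable
# kernel's full 3-D array, by direct summation.
brute_conv3 <- function(x, karr) {
  n <- dim(x)
  r <- (dim(karr)[1] - 1) / 2
  out <- array(0, n)
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    s <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > n[1] || jj < 1 || jj > n[2] || kk < 1 || kk > n[3]) next
      s <- s + x[ii, jj, kk] * karr[di + r + 1, dj + r + 1, dk + r + 1]
    }
    out[i, j, k] <- s
  }
  out
}

# One brute-force Richardson-Lucy iteration using brute_conv3.
brute_rl_iterate <- function(phi, data, karr) {
  blur <- brute_conv3(phi, karr)
  ratio <- data / blur
  ratio[!is.finite(ratio)] <- 0
  phi * brute_conv3(ratio, karr)
}

# Monte-Carlo photon transport in a turbid cylinder: isotropic-scattering
# random walk (similarity reduction), implicit absorption weighting, Fresnel
# reflection/transmission at the boundary, Lambertian capture tally per
# camera. Returns expected captured photons/s per view per unit source power.
mc_angular_profile <- function(src_pos, n_photons, medium, cameras,
                               radius = 15, height = 40, seed = 7) {
  set.seed(seed)
  mu_t <- medium$mu_a + medium$mu_s_prime
  albedo <- medium$mu_s_prime / mu_t
  n_rel <- medium$refractive_index
  prim <- list(type = "cylinder", radius = radius, height = height,
               center = c(0, 0, 0))
  camp <- t(vapply(cameras, `[[`, numeric(3), "position"))
  a_lens <- cameras[[1]]$aperture_area
  tot <- numeric(length(cameras))
  rand_dir <- function(n) {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(th), r * sin(th), z)
  }
  pos <- matrix(rep(src_pos, each = n_photons), n_photons, 3)
  dir <- rand_dir(n_photons)
  w <- rep(1, n_photons)
  for (step in 1:50000) {
    n <- nrow(pos)
    if (n == 0) break
    s <- -log(stats::runif(n)) / mu_t
    hit <- ray_cylinder(pos, dir, prim)
    t_exit <- ifelse(hit$hit, hit$t, Inf)
    exits <- s >= t_exit
    if (any(exits)) {
      P <- hit$point[exits, , drop = FALSE]
      Nr <- hit$normal[exits, , drop = FALSE]
      D <- dir[exits, , drop = FALSE]
      W <- w[exits]
      ci <- pmin(pmax(rowSums(D * Nr), 0), 1)
      refl_p <- fresnel_reflectance(acos(ci), n_rel, 1)
      trans <- stats::runif(length(W)) > refl_p
      if (any(trans)) {
        Pt <- P[trans, , drop = FALSE]
        Nt <- Nr[trans, , drop = FALSE]
        Wt <- W[trans]
        for (k in seq_along(cameras)) {
          tc <- sweep(-Pt, 2, camp[k, ], "+")
          d2 <- rowSums(tc^2)
          cosx <- rowSums(Nt * tc) / sqrt(d2)
          vis <- cosx > 0
          # Lambertian exit: radiance W/pi per unit area, lens solid angle
          tot[k] <- tot[k] + sum(Wt[vis] * cosx[vis] / pi * a_lens / d2[vis])
        }
      }
      # internally reflected photons continue from the boundary
      if (any(!trans)) {
        Pr <- P[!trans, , drop = FALSE]
        Dr <- D[!trans, , drop = FALSE]
        Nn <- Nr[!trans, , drop = FALSE]
        Dn <- Dr - 2 * rowSums(Dr * Nn) * Nn
        ridx <- which(exits)[!trans]
        pos[ridx, ] <- Pr - 1e-6 * Nn
        dir[ridx, ] <- Dn
      }
      kill <- exits
      kill[which(exits)[!trans]] <- FALSE
      keep <- !kill
      pos <- pos[keep, , drop = FALSE]
      dir <- dir[keep, , drop = FALSE]
      w <- w[keep]
      s <- s[keep]
      exits <- exits[keep]
    }
    # scattering move for photons that stayed inside
    mv <- which(!exits)
    if (length(mv)) {
      pos[mv, ] <- pos[mv, , drop = FALSE] + dir[mv, , drop = FALSE] * s[mv]
      dir[mv, ] <- rand_dir(length(mv))
      w[mv] <- w[mv] * albedo
    }
    keep <- w >= 1e-4
    pos <- pos[keep, , drop = FALSE]
    dir <- dir[keep, , drop = FALSE]
    w <- w[keep]
  }
  tot / n_photons
}
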