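#' Diffusion coefficient of a turbid medium
#'
#' Standard diffusion-theory relation \eqn{D = 1/(3 (\mu_a + \mu_s'))}.
#'
#' @param mu_a Absorption coefficient (1/mm), non-negative.
#' @param mu_s_prime Reduced scattering coefficient (1/mm), non-negative.
#' @return Diffusion coefficient in mm.
#' @export
#' @examples
#' diffusion_coefficient(0.002, 1.0)
diffusion_coefficient <- function(mu_a, mu_s_prime) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s_prime))
  if (any(mu_a < 0) || any(mu_s_prime < 0)) {
    stop("mu_a and mu_s_prime must be non-negative")
  }
  tot <- mu_a + mu_s_prime
  if (any(tot <= 0)) {
    stop("total attenuation mu_a + mu_s_prime must be positive")
  }
  1 / (3 * tot)
}

#' Effective attenuation coefficient
#'
#' \eqn{\mu_{eff} = \sqrt{\mu_a / D}}, the decay constant of the steady-state
#' diffuse fluence far from sources.
#'
#' @param mu_a Absorption coefficient (1/mm).
#' @param D Diffusion coefficient (mm), positive.
#' @return Effective attenuation coefficient (1/mm).
#' @export
effective_attenuation <- function(mu_a, D) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(mu_a < 0)) stop("mu_a must be non-negative")
  sqrt(mu_a / D)
}

#' Unpolarized Fresnel reflectance at a refractive-index step
#'
#' Reflectance for light inside a medium of index `n_in` hitting a boundary
#' with `n_out` at internal angle `theta` (radians). Total internal reflection
#' beyond the critical angle.
#'
#' @param theta Internal incidence angle, radians in [0, pi/2].
#' @param n_in,n_out Refractive indices inside and outside.
#' @return Reflectance in [0, 1].
#' @export
fresnel_reflectance <- function(theta, n_in, n_out = 1.0) {
  s <- (n_in / n_out) * sin(theta)
  r <- numeric(length(theta))
  tir <- s >= 1
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    tt <- asin(s[ok])          # refraction angle
    ti <- theta[ok]
    rs <- (sin(ti - tt) / sin(ti + tt))^2
    rp <- (tan(ti - tt) / tan(ti + tt))^2
    # normal incidence limit
    norm0 <- ti < 1e-9
    r0 <- ((n_in - n_out) / (n_in + n_out))^2
    val <- 0.5 * (rs + rp)
    val[norm0] <- r0
    r[ok] <- val
  }
  r
}

#' Effective internal reflection coefficient
#'
#' Angle-integrated effective reflection coefficient of a diffuse internal
#' light field at a refractive-index mismatched boundary (partial-current
#' model): \eqn{R_{eff} = (R_\phi + R_j) / (2 - R_\phi + R_j)} with
#' \eqn{R_\phi = \int 2\sin\theta\cos\theta\, R_F(\theta)\, d\theta} and
#' \eqn{R_j = \int 3\sin\theta\cos^2\theta\, R_F(\theta)\, d\theta},
#' evaluated by numeric quadrature of the unpolarized Fresnel reflectance.
#'
#' @param n Refractive index of the medium relative to the outside (air).
#' @return Effective reflection coefficient in [0, 1).
#' @export
effective_reflection <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (abs(n - 1) < 1e-12) return(0)
  key <- sprintf("%.9f", n)
  cached <- .mblt_cache$reff[[key]]
  if (!is.null(cached)) return(cached)
  r_phi <- stats::integrate(function(th) {
    2 * sin(th) * cos(th) * fresnel_reflectance(th, n)
  }, 0, pi / 2, rel.tol = 1e-10)$value
  r_j <- stats::integrate(function(th) {
    3 * sin(th) * cos(th)^2 * fresnel_reflectance(th, n)
  }, 0, pi / 2, rel.tol = 1e-10)$value
  val <- (r_phi + r_j) / (2 - r_phi + r_j)
  .mblt_cache$reff[[key]] <- val
  val
}

.mblt_cache <- new.env(parent = emptyenv())
.mblt_cache$reff <- list()

#' Construct an optical medium
#'
#' A homogeneous medium described by its absorption and reduced scattering
#' coefficients. Derived quantities (diffusion coefficient `D`, effective
#' attenuation `mu_eff`, effective boundary reflection `R_eff`) are computed
#' on construction. A transparent medium (`mu_s_prime = 0`, `turbid = FALSE`)
#' represents air and bypasses diffusion rendering.
#'
#' @param mu_a Absorption coefficient (1/mm).
#' @param mu_s_prime Reduced scattering coefficient (1/mm).
#' @param refractive_index Refractive index (dimensionless).
#' @param name Optional label.
#' @param turbid Logical; if `TRUE` (default when `mu_s_prime > 0`) the medium
#'   is rendered with the diffusion approximation.
#' @return An object of class `optical_medium`.
#' @export
#' @examples
#' optical_medium(0.002, 1.0, 1.34, name = "intralipid_1pct_560nm")
optical_medium <- function(mu_a, mu_s_prime, refractive_index = 1.0,
                           name = NULL, turbid = mu_s_prime > 0) {
  stopifnot(length(mu_a) == 1, length(mu_s_prime) == 1,
            mu_a >= 0, mu_s_prime >= 0, refractive_index >= 1)
  if (turbid && mu_a + mu_s_prime <= 0) {
    stop("a turbid medium needs mu_a + mu_s_prime > 0")
  }
  m <- list(
    name = if (is.null(name)) "custom" else name,
    mu_a = mu_a,
    mu_s_prime = mu_s_prime,
    refractive_index = refractive_index,
    turbid = isTRUE(turbid)
  )
  if (m$turbid) {
    m$D <- diffusion_coefficient(mu_a, mu_s_prime)
    m$mu_eff <- effective_attenuation(mu_a, m$D)
    m$R_eff <- effective_reflection(refractive_index)
  } else {
    m$D <- NA_real_
    m$mu_eff <- 0
    m$R_eff <- 0
  }
  class(m) <- "optical_medium"
  m
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf("<optical_medium '%s'>  mu_a=%g /mm  mu_s'=%g /mm  n=%g  %s\n",
              x$name, x$mu_a, x$mu_s_prime, x$refractive_index,
              if (x$turbid) sprintf("turbid (D=%.4g mm, mu_eff=%.4g /mm)",
                                    x$D, x$mu_eff)
              else "transparent"))
  invisible(x)
}

#' Built-in media registry
#'
#' Look up a named optical medium. Shipped entries: `"air"` (transparent),
#' `"intralipid_1pct_560nm"` (1\% Intralipid / 1\% agarose gel at 560 nm:
#' mu_s' = 1.0 /mm, mu_a = 0.002 /mm, n = 1.34) and `"soft_tissue_generic"`.
#'
#' @param name Medium name.
#' @return An `optical_medium`.
#' @export
medium_registry <- function(name) {
  switch(name,
    air = optical_medium(0, 0, 1.0, name = "air", turbid = FALSE),
    intralipid_1pct_560nm = optical_medium(0.002, 1.0, 1.34,
                                           name = "intralipid_1pct_560nm"),
    soft_tissue_generic = optical_medium(0.05, 1.0, 1.4,
                                         name = "soft_tissue_generic"),
    stop("unknown medium '", name, "'; known: air, intralipid_1pct_560nm, ",
         "soft_tissue_generic")
  )
}

#' Construct a steady-state point source
#'
#' @param position Numeric length-3, scene coordinates (mm).
#' @param power Emission rate (photons/s), non-negative.
#' @param wavelength Wavelength in nm.
#' @return An object of class `point_source`.
#' @export
point_source <- function(position, power, wavelength = 560) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3, is.finite(position),
            length(power) == 1, power >= 0, wavelength > 0)
  structure(list(position = position, power = power, wavelength = wavelength),
            class = "point_source")
}

#' Steady-state fluence of a point source in an infinite turbid medium
#'
#' Infinite-medium Green's function of the steady-state diffusion equation:
#' \deqn{\phi(r) = S \exp(-\mu_{eff} r) / (4 \pi D r).}
#' Boundary handling is applied separately at the surface (see
#' [boundary_exitance()]).
#'
#' @param source A [point_source()].
#' @param observation_point Numeric length-3 or n-by-3 matrix of points (mm).
#' @param medium A turbid [optical_medium()].
#' @return Fluence rate(s), photons/s/mm^2.
#' @export
point_source_fluence <- function(source, observation_point, medium) {
  stopifnot(inherits(source, "point_source"), inherits(medium, "optical_medium"))
  if (!medium$turbid) stop("point_source_fluence needs a turbid medium")
  pts <- if (is.matrix(observation_point)) observation_point
         else matrix(as.numeric(observation_point), ncol = 3)
  d <- sweep(pts, 2, source$position)
  r <- sqrt(rowSums(d^2))
  if (any(r <= 0)) stop("observation point coincides with the source (r = 0)")
  source$power * exp(-medium$mu_eff * r) / (4 * pi * medium$D * r)
}

#' Diffusion Green's function at given distances
#'
#' Per-unit-power kernel \eqn{\exp(-\mu_{eff} r) / (4 \pi D r)} used by the
#' fluence model and the reconstruction.
#'
#' @param r Distances (mm), positive.
#' @param medium A turbid `optical_medium`.
#' @return Kernel values, 1/mm^2.
#' @export
diffusion_greens <- function(r, medium) {
  stopifnot(medium$turbid)
  exp(-medium$mu_eff * r) / (4 * pi * medium$D * r)
}

#' Outward radiance at a diffusive boundary
#'
#' Converts the internal fluence at a surface point into the Lambertian
#' radiance emitted outward, after loss by internal reflection at the
#' refractive-index mismatch (partial-current model):
#' \deqn{L = (1 - R_{eff}) \, \phi / (4 \pi (1 + R_{eff})).}
#'
#' @param fluence_at_surface Fluence rate(s) at the surface, photons/s/mm^2.
#' @param surface_normal Outward unit normal (unused by the scalar model; kept
#'   for interface symmetry and validated for shape).
#' @param medium The turbid `optical_medium` of the interior.
#' @return Emitted radiance, photons/s/mm^2/sr.
#' @export
boundary_exitance <- function(fluence_at_surface, surface_normal = c(0, 0, 1),
                              medium = NULL) {
  if (any(fluence_at_surface < 0)) stop("fluence must be non-negative")
  r_eff <- if (is.null(medium)) 0 else medium$R_eff
  (1 - r_eff) * fluence_at_surface / (4 * pi * (1 + r_eff))
}
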