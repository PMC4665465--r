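# Coordinate conventions: right-handed, units mm, gantry rotation axis = +z,
# view angle 0 deg puts the camera on +x. Voxel indices are 1-based in R;
# the center of voxel (i,j,k) sits at origin + (index - 0.5) * voxel_size.

#' Construct a voxel grid
#'
#' Isotropic axis-aligned voxel grid. `origin` is the world position of the
#' grid's low corner (not the first voxel center).
#'
#' @param shape Integer length-3, number of voxels per axis (>= 1).
#' @param voxel_size Edge length in mm (> 0).
#' @param origin Numeric length-3, low-corner world position (mm).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = 0.5, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(voxel_size) == 1, voxel_size > 0,
            length(origin) == 3, is.finite(origin))
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %dx%dx%d @ %g mm, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel index to world coordinates
#'
#' @param grid A `voxel_grid`.
#' @param index Integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of voxel-center world coordinates (mm).
#' @export
index_to_world <- function(grid, index) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  sweep((idx - 0.5) * grid$voxel_size, 2, grid$origin, "+")
}

#' World coordinates to voxel index
#'
#' Exact inverse of [index_to_world()] at voxel centers; arbitrary points map
#' to the containing voxel.
#'
#' @param grid A `voxel_grid`.
#' @param world n x 3 matrix or length-3 vector of world coordinates (mm).
#' @param clamp Clamp out-of-grid indices to the boundary voxels.
#' @return n x 3 integer matrix of 1-based indices.
#' @export
world_to_index <- function(grid, world, clamp = FALSE) {
  w <- if (is.matrix(world)) world else matrix(as.numeric(world), ncol = 3)
  idx <- floor(sweep(w, 2, grid$origin) / grid$voxel_size) + 1L
  mode(idx) <- "integer"
  if (clamp) {
    for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1L), grid$shape[a])
  }
  idx
}

#' All voxel-center coordinates of a grid
#'
#' @param grid A `voxel_grid`.
#' @return (prod(shape)) x 3 matrix, ordered with the first axis fastest
#'   (R array order).
#' @export
grid_centers <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 0.5) * grid$voxel_size
  })
  cbind(rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
        rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
        rep(ax[[3]], each = grid$shape[1] * grid$shape[2]))
}

new_surface_mesh <- function(vertices, triangles, primitive = NULL) {
  vertices <- unname(as.matrix(vertices))
  triangles <- unname(as.matrix(triangles))
  mode(triangles) <- "integer"
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  structure(list(
    vertices = vertices,
    triangles = triangles,
    normals = cr / nrm2,
    areas = nrm2 / 2,
    centroids = (v1 + v2 + v3) / 3,
    primitive = primitive
  ), class = "surface_mesh")
}

#' Signed volume enclosed by a triangle mesh
#'
#' Positive for a closed, consistently outward-oriented mesh.
#'
#' @param mesh A `surface_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c3 <- v[t[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, volume %.2f mm^3%s\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x),
              if (!is.null(x$primitive)) paste0(" (", x$primitive$type, ")")
              else ""))
  invisible(x)
}

#' Build a cylindrical phantom
#'
#' Axis-aligned (+z) cylinder centered at the world origin: voxel grid
#' covering its bounding box, a closed triangulated surface (side wall and
#' caps, outward-oriented), and the per-voxel inside mask.
#'
#' @param diameter Cylinder diameter (mm).
#' @param height Cylinder height (mm).
#' @param voxel_size Voxel edge (mm); must not exceed the diameter.
#' @param n_theta Angular tessellation of the side wall.
#' @param ring_height Approximate axial extent of one side-wall ring (mm).
#' @return List with elements `grid` (`voxel_grid`), `mesh` (`surface_mesh`)
#'   and `mask` (logical array of grid shape, `TRUE` for voxel centers inside
#'   the cylinder).
#' @export
#' @examples
#' ph <- build_cylinder_phantom(30, 40, 1)
#' sum(ph$mask) * 1^3 / (pi * 15^2 * 40)  # ~1
build_cylinder_phantom <- function(diameter, height, voxel_size = 0.5,
                                   n_theta = 96, ring_height = 2) {
  stopifnot(diameter > 0, height > 0, voxel_size > 0)
  if (voxel_size > diameter) stop("voxel_size must not exceed the diameter")
  radius <- diameter / 2
  nx <- max(1L, as.integer(ceiling(diameter / voxel_size)))
  nz <- max(1L, as.integer(ceiling(height / voxel_size)))
  shape <- c(nx, nx, nz)
  origin <- -c(nx, nx, nz) * voxel_size / 2
  grid <- voxel_grid(shape, voxel_size, origin)

  n_rings <- max(1L, as.integer(round(height / ring_height)))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(-height / 2, height / 2, length.out = n_rings + 1)
  ring <- cbind(radius * cos(theta), radius * sin(theta))
  verts <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  vid <- function(iz, it) (iz - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  side <- vector("list", n_rings)
  for (iz in seq_len(n_rings)) {
    it <- seq_len(n_theta)
    # outward (CCW seen from outside): lower ring -> upper ring
    t1 <- cbind(vid(iz, it), vid(iz, it + 1L), vid(iz + 1L, it + 1L))
    t2 <- cbind(vid(iz, it), vid(iz + 1L, it + 1L), vid(iz + 1L, it))
    side[[iz]] <- rbind(t1, t2)
  }
  side <- do.call(rbind, side)
  nv <- nrow(verts)
  verts <- rbind(verts, c(0, 0, -height / 2), c(0, 0, height / 2))
  bot_c <- nv + 1L
  top_c <- nv + 2L
  it <- seq_len(n_theta)
  bottom <- cbind(rep(bot_c, n_theta), vid(1L, it + 1L), vid(1L, it))
  top <- cbind(rep(top_c, n_theta), vid(n_rings + 1L, it),
               vid(n_rings + 1L, it + 1L))
  tris <- rbind(side, bottom, top)
  prim <- list(type = "cylinder", radius = radius, height = height,
               center = c(0, 0, 0))
  mesh <- new_surface_mesh(verts, tris, primitive = prim)

  ctr <- grid_centers(grid)
  inside <- (ctr[, 1]^2 + ctr[, 2]^2) < radius^2 &
    abs(ctr[, 3]) < height / 2
  mask <- array(inside, dim = shape)
  list(grid = grid, mesh = mesh, mask = mask)
}

#' Is a point inside a phantom surface?
#'
#' Uses the analytic primitive attached to the mesh.
#'
#' @param mesh A `surface_mesh` with a primitive.
#' @param points n x 3 matrix or length-3 vector (mm).
#' @param margin Require points at least this far inside (mm).
#' @return Logical vector.
#' @export
inside_mesh <- function(mesh, points, margin = 0) {
  p <- mesh$primitive
  if (is.null(p)) stop("mesh has no analytic primitive; cannot test insidedness")
  x <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 3)
  if (p$type != "cylinder") stop("unsupported primitive: ", p$type)
  d <- sweep(x, 2, p$center)
  sqrt(d[, 1]^2 + d[, 2]^2) <= p$radius - margin &
    abs(d[, 3]) <= p$height / 2 - margin
}

#' First intersection of rays with a cylinder surface
#'
#' Vectorized ray/finite-cylinder (side wall + caps) intersection.
#'
#' @param origin n x 3 matrix of ray origins (mm).
#' @param dir n x 3 matrix of ray directions (need not be unit).
#' @param primitive Cylinder primitive list (`radius`, `height`, `center`).
#' @param t_min Minimum accepted ray parameter (in units of `|dir|`).
#' @return List with `t` (NA when no hit), `point` (n x 3), `normal` (n x 3,
#'   outward), `hit` (logical).
#' @export
ray_cylinder <- function(origin, dir, primitive, t_min = 1e-9) {
  o <- sweep(origin, 2, primitive$center)
  R <- primitive$radius
  hh <- primitive$height / 2
  n <- nrow(o)
  tbest <- rep(NA_real_, n)
  # side wall: (ox+t dx)^2 + (oy+t dy)^2 = R^2
  a <- dir[, 1]^2 + dir[, 2]^2
  b <- 2 * (o[, 1] * dir[, 1] + o[, 2] * dir[, 2])
  cc <- o[, 1]^2 + o[, 2]^2 - R^2
  disc <- b^2 - 4 * a * cc
  ok <- disc >= 0 & a > 0
  sq <- sqrt(pmax(disc, 0))
  for (sgn in c(-1, 1)) {
    t <- (-b + sgn * sq) / (2 * a)
    z <- o[, 3] + t * dir[, 3]
    good <- ok & t > t_min & abs(z) <= hh
    tbest[good] <- pmin(tbest[good], t[good], na.rm = TRUE)
  }
  # caps
  dz <- dir[, 3]
  for (zc in c(-hh, hh)) {
    t <- (zc - o[, 3]) / dz
    px <- o[, 1] + t * dir[, 1]
    py <- o[, 2] + t * dir[, 2]
    good <- is.finite(t) & t > t_min & (px^2 + py^2) <= R^2
    tbest[good] <- pmin(tbest[good], t[good], na.rm = TRUE)
  }
  hit <- !is.na(tbest)
  pt <- o + tbest * dir
  # outward normal at hit
  nrm <- matrix(0, n, 3)
  onside <- hit & abs(abs(pt[, 3]) - hh) > 1e-9
  nrm[onside, 1:2] <- pt[onside, 1:2, drop = FALSE] / R
  oncap <- hit & !onside
  nrm[oncap, 3] <- sign(pt[oncap, 3])
  point <- sweep(pt, 2, primitive$center, "+")
  point[!hit, ] <- NA_real_
  list(t = tbest, point = point, normal = nrm, hit = hit)
}

# Project points just outside the nearest face of the analytic primitive.
push_to_surface <- function(points, primitive, eps = 1e-9) {
  stopifnot(primitive$type == "cylinder")
  p <- sweep(points, 2, primitive$center)
  r_xy <- sqrt(p[, 1]^2 + p[, 2]^2)
  hh <- primitive$height / 2
  side_gap <- primitive$radius - r_xy
  cap_gap <- hh - abs(p[, 3])
  to_side <- side_gap <= cap_gap
  scl <- (primitive$radius + eps) / pmax(r_xy, 1e-12)
  p[to_side, 1:2] <- p[to_side, 1:2, drop = FALSE] * scl[to_side]
  p[!to_side, 3] <- sign(p[!to_side, 3]) * (hh + eps)
  sweep(p, 2, primitive$center, "+")
}

#' Construct a camera pose on the gantry circle
#'
#' Pinhole camera with a thin lens focused on the gantry rotation axis. The
#' optical axis points from the camera position to the axis; the up-vector is
#' the gantry axis (+z).
#'
#' @param view_angle Angle on the gantry circle, degrees in [0, 360).
#' @param radius Standoff from the rotation axis (mm). The default puts a
#'   30 mm object across about 2/3 of the field of view.
#' @param z Height of the optical axis (mm).
#' @param focal_mm Lens focal length (mm).
#' @param f_number Aperture f-number.
#' @param pixel_pitch_mm Native detector pixel pitch (mm).
#' @param n_pixels Native detector format (pixels per side).
#' @param camera_id Integer id of the physical camera head.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(view_angle = 0, radius = 116.5, z = 0,
                        focal_mm = 25, f_number = 0.95,
                        pixel_pitch_mm = 0.024, n_pixels = 512L,
                        camera_id = 1L) {
  stopifnot(radius > focal_mm, n_pixels >= 2)
  view_angle <- view_angle %% 360
  th <- view_angle * pi / 180
  pos <- c(radius * cos(th), radius * sin(th), z)
  fwd <- c(-cos(th), -sin(th), 0)
  right <- c(-sin(th), cos(th), 0)
  up <- c(0, 0, 1)
  di <- 1 / (1 / focal_mm - 1 / radius)   # image distance, focused on axis
  structure(list(view_angle = view_angle, position = pos, axis = fwd,
                 right = right, up = up, focal_mm = focal_mm,
                 f_number = f_number, pixel_pitch_mm = pixel_pitch_mm,
                 n_pixels = as.integer(n_pixels), camera_id = as.integer(camera_id),
                 radius = radius, image_distance = di,
                 aperture_area = pi * (focal_mm / f_number / 2)^2),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf(
    "<camera_pose> angle %g deg, standoff %g mm, f=%g mm f/%g, %dx%d px\n",
    x$view_angle, x$radius, x$focal_mm, x$f_number, x$n_pixels, x$n_pixels))
  invisible(x)
}

#' Gantry configuration
#'
#' @param n_cameras Number of camera heads (default 4).
#' @param n_views Total angular views (default 20).
#' @param angular_step Step between consecutive views, degrees (default 18).
#' @return An object of class `gantry_config`.
#' @export
gantry_config <- function(n_cameras = 4, n_views = 20, angular_step = 18) {
  stopifnot(n_cameras >= 1, n_views >= 1, angular_step > 0)
  if (abs(n_views * angular_step - 360) > 1e-9) {
    stop("n_views * angular_step must equal 360 degrees")
  }
  if (n_views %% n_cameras != 0) {
    stop("n_views must be divisible by n_cameras")
  }
  structure(list(n_cameras = as.integer(n_cameras),
                 n_views = as.integer(n_views),
                 angular_step = angular_step),
            class = "gantry_config")
}

#' Build the full set of camera poses for a gantry
#'
#' Camera heads sit `360 / n_cameras` degrees apart; the gantry rotates
#' through `n_views / n_cameras` stops of `angular_step` degrees, so the view
#' set covers every multiple of the step exactly once. Poses are returned in
#' increasing view-angle order.
#'
#' @param config A [gantry_config()].
#' @param camera_template A [camera_pose()] supplying the optics and detector
#'   parameters shared by all heads.
#' @param radius Gantry radius (mm); defaults to the template's.
#' @return List of `camera_pose` objects, one per view.
#' @export
build_gantry <- function(config = gantry_config(),
                         camera_template = camera_pose(),
                         radius = camera_template$radius) {
  stops <- config$n_views / config$n_cameras
  head_sep <- 360 / config$n_cameras
  poses <- list()
  for (cam in seq_len(config$n_cameras)) {
    for (s in seq_len(stops)) {
      ang <- (cam - 1) * head_sep + (s - 1) * config$angular_step
      poses[[length(poses) + 1L]] <- camera_pose(
        view_angle = ang, radius = radius, z = camera_template$position[3],
        focal_mm = camera_template$focal_mm,
        f_number = camera_template$f_number,
        pixel_pitch_mm = camera_template$pixel_pitch_mm,
        n_pixels = camera_template$n_pixels, camera_id = cam)
    }
  }
  poses[order(vapply(poses, function(p) p$view_angle, 0))]
}

# Effective pixel geometry at a given binning: count, pitch, principal point.
camera_pixel_geometry <- function(camera, binning = 1L) {
  n <- camera$n_pixels %/% as.integer(binning)
  pitch <- camera$pixel_pitch_mm * binning
  list(n = n, pitch = pitch, c0 = (n + 1) / 2)
}

#' Project world points onto the detector
#'
#' Pinhole projection through the lens center. Returns fractional pixel
#' coordinates (1-based pixel centers) at the given binning.
#'
#' @param camera A `camera_pose`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param binning Pixel binning factor.
#' @return List with `u`, `v` (fractional pixel coords), `depth` (distance
#'   along the optical axis, mm), `dist` (euclidean distance to the lens
#'   center, mm), `in_fov` (logical).
#' @export
project_to_pixels <- function(camera, points, binning = 1L) {
  g <- camera_pixel_geometry(camera, binning)
  w <- sweep(points, 2, camera$position)
  zf <- w %*% camera$axis
  xm <- w %*% camera$right
  ym <- w %*% camera$up
  scale <- camera$image_distance / (zf * g$pitch)
  u <- g$c0 + xm * scale
  v <- g$c0 + ym * scale
  ok <- zf > 0 & u >= 0.5 & u < g$n + 0.5 & v >= 0.5 & v < g$n + 0.5
  list(u = as.numeric(u), v = as.numeric(v), depth = as.numeric(zf),
       dist = sqrt(rowSums(w^2)), in_fov = as.logical(ok))
}

# Unit ray directions through every (binned) pixel center; rows ordered with
# u fastest (matches as.vector of an n x n image matrix indexed [u, v]).
camera_pixel_rays <- function(camera, binning = 1L) {
  g <- camera_pixel_geometry(camera, binning)
  s <- (seq_len(g$n) - g$c0) * g$pitch / camera$image_distance
  du <- rep(s, times = g$n)
  dv <- rep(s, each = g$n)
  d <- cbind(
    camera$axis[1] + du * camera$right[1] + dv * camera$up[1],
    camera$axis[2] + du * camera$right[2] + dv * camera$up[2],
    camera$axis[3] + du * camera$right[3] + dv * camera$up[3])
  nr <- sqrt(rowSums(d^2))
  list(dir = d / nr, cos_alpha = 1 / nr, n = g$n, pitch = g$pitch)
}

#' Map visible surface triangles to detector pixels
#'
#' For each mesh triangle visible from the camera (front-facing and not
#' occluded by the phantom body), gives the pixel its centroid images to and
#' a geometric weight `area * cos(obliqueness) * aperture solid angle`
#' (mm^2 sr): the etendue collecting light from that patch into the lens.
#'
#' @param mesh A `surface_mesh`.
#' @param camera A `camera_pose`; must be outside the mesh.
#' @param binning Pixel binning factor.
#' @return Data frame with columns `tri`, `u`, `v` (integer pixel indices),
#'   `weight`.
#' @export
surface_pixel_map <- function(mesh, camera, binning = 1L) {
  if (!is.null(mesh$primitive) &&
      isTRUE(inside_mesh(mesh, camera$position))) {
    stop("camera must be outside the mesh")
  }
  to_cam <- sweep(-mesh$centroids, 2, camera$position, "+")
  d <- sqrt(rowSums(to_cam^2))
  cosv <- rowSums(mesh$normals * to_cam) / d
  vis <- cosv > 1e-9
  if (!is.null(mesh$primitive)) {
    # occlusion: ray from just outside the centroid toward the camera must
    # not re-enter the body
    idx <- which(vis)
    if (length(idx)) {
      # triangle centroids sit slightly inside the analytic surface (chord
      # sagitta); push them onto it so the ray test cannot clip the body
      # spuriously near the limb
      org <- push_to_surface(mesh$centroids[idx, , drop = FALSE],
                             mesh$primitive)
      hit <- ray_cylinder(org, to_cam[idx, , drop = FALSE], mesh$primitive,
                          t_min = 1e-7)
      blocked <- hit$hit & hit$t < 1 - 1e-7
      vis[idx[blocked]] <- FALSE
    }
  }
  pr <- project_to_pixels(camera, mesh$centroids, binning)
  keep <- vis & pr$in_fov
  w <- mesh$areas * cosv * camera$aperture_area / d^2
  data.frame(tri = which(keep),
             u = as.integer(round(pr$u[keep])),
             v = as.integer(round(pr$v[keep])),
             weight = w[keep])
}

#' Write a mesh to OFF or ASCII PLY
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path; format from extension (`.off` or `.ply`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  tr <- mesh$triangles - 1L   # zero-based on disk
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(tr)), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(tr)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}

#' Read a mesh from OFF or ASCII PLY
#'
#' @param path Input path written by [write_mesh()] (or any ASCII OFF/PLY
#'   with triangular faces).
#' @return A `surface_mesh` (without analytic primitive).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  ln <- readLines(path)
  if (ext == "off") {
    stopifnot(trimws(ln[1]) == "OFF")
    cnt <- scan(text = ln[2], quiet = TRUE)
    nv <- cnt[1]; nf <- cnt[2]
    v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3,
                byrow = TRUE)
    f <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                ncol = 4, byrow = TRUE)
    stopifnot(all(f[, 1] == 3))
    tr <- f[, 2:4, drop = FALSE] + 1L
  } else if (ext == "ply") {
    hdr_end <- which(trimws(ln) == "end_header")[1]
    nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                         grep("element vertex", ln, value = TRUE)[1]))
    nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                         grep("element face", ln, value = TRUE)[1]))
    v <- matrix(scan(text = ln[(hdr_end + 1):(hdr_end + nv)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
    f <- matrix(scan(text = ln[(hdr_end + nv + 1):(hdr_end + nv + nf)],
                     quiet = TRUE), ncol = 4, byrow = TRUE)
    stopifnot(all(f[, 1] == 3))
    tr <- f[, 2:4, drop = FALSE] + 1L
  } else {
    stop("unsupported mesh format: ", ext)
  }
  mode(tr) <- "integer"
  new_surface_mesh(v, tr)
}
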