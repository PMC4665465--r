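# Voxel grids, phantom meshes, gantry poses and the surface-to-pixel map.

test_that("world/voxel transforms round-trip exactly at voxel centers", {
  g <- voxel_grid(c(7, 9, 11), 0.5, origin = c(-1.75, -2.25, -2.75))
  idx <- as.matrix(expand.grid(1:7, 1:9, 1:11))
  colnames(idx) <- NULL
  w <- index_to_world(g, idx)
  back <- world_to_index(g, w)
  expect_identical(back, idx)
  expect_equal(nrow(grid_centers(g)), 7 * 9 * 11)
  expect_error(voxel_grid(c(0, 1, 1), 0.5))
  expect_error(voxel_grid(c(1, 1, 1), 0))
})

test_that("cylinder phantom has the right volume, mask and orientation", {
  ph <- build_cylinder_phantom(30, 40, 0.5)
  expect_true(all(ph$grid$shape >= c(60, 60, 80)))
  true_vol <- pi * 15^2 * 40
  expect_equal(sum(ph$mask) * 0.5^3, true_vol, tolerance = 0.01)
  expect_equal(mesh_volume(ph$mesh), true_vol, tolerance = 0.01)
  expect_gt(mesh_volume(ph$mesh), 0)
  # unit normals
  expect_equal(max(abs(sqrt(rowSums(ph$mesh$normals^2)) - 1)), 0,
               tolerance = 1e-9)
  # closed, consistently oriented: every directed edge appears exactly once
  tr <- ph$mesh$triangles
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  fwd <- paste(edges[, 1], edges[, 2])
  rev <- paste(edges[, 2], edges[, 1])
  expect_true(all(fwd %in% rev))
  expect_false(any(duplicated(fwd)))
})

test_that("degenerate-size phantom still builds a closed mesh", {
  ph <- build_cylinder_phantom(2, 2, 1)   # diameter = 2 voxels
  expect_gt(sum(ph$mask), 0)
  expect_gt(mesh_volume(ph$mesh), 0)
  expect_equal(mesh_volume(ph$mesh), pi * 1^2 * 2, tolerance = 0.01)
  expect_error(build_cylinder_phantom(1, 10, 2), "exceed")
})

test_that("gantry covers every angle once with the right camera assignment", {
  poses <- build_gantry()
  expect_length(poses, 20)
  angles <- vapply(poses, `[[`, 0, "view_angle")
  expect_equal(sort(angles), seq(0, 342, by = 18))
  ids <- vapply(poses, `[[`, 0L, "camera_id")
  expect_true(all(table(ids) == 5))   # 5 rotational stops per camera
  # all poses look at the rotation axis
  for (p in poses) {
    expect_equal(as.numeric(p$position[1:2] / p$radius + p$axis[1:2]),
                 c(0, 0), tolerance = 1e-12)
  }
  # rigid gantry: any two poses differ by a pure rotation about z
  r1 <- sqrt(sum(poses[[1]]$position[1:2]^2))
  for (p in poses[-1]) {
    expect_equal(sqrt(sum(p$position[1:2]^2)), r1, tolerance = 1e-9)
    expect_equal(p$position[3], poses[[1]]$position[3])
  }
  p4 <- build_gantry(gantry_config(1, 4, 90))
  expect_length(p4, 4)
  expect_equal(vapply(p4, `[[`, 0, "view_angle"), c(0, 90, 180, 270))
  expect_error(gantry_config(3, 20, 18), "divisible")
  expect_error(gantry_config(4, 21, 18), "360")
})

test_that("surface-pixel map weights carry the cosine obliqueness factor", {
  # two identical distant patches, one head-on and one tilted 60 degrees
  d <- 116.5
  v <- rbind(c(0, -1, -1), c(0, 1, -1), c(0, 0, 2))        # facing +x
  th <- 60 * pi / 180
  vt <- v
  vt[, 1] <- v[, 2] * sin(th)       # rotate about z by 60 deg
  vt[, 2] <- v[, 2] * cos(th)
  mesh <- mblt:::new_surface_mesh(rbind(v, vt),
                                  rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  cam <- camera_pose(0, radius = d)
  m <- surface_pixel_map(mesh, cam)
  expect_equal(nrow(m), 2)
  expect_equal(m$weight[1] / m$weight[2], 2, tolerance = 0.02)
})

test_that("far-side triangles are excluded and coverage matches geometry", {
  ph <- build_cylinder_phantom(30, 40, 0.5)
  cam <- camera_pose(0)
  m <- surface_pixel_map(ph$mesh, cam)
  expect_gt(nrow(m), 0)
  # every mapped triangle faces the camera
  to_cam <- sweep(-ph$mesh$centroids[m$tri, ], 2, cam$position, "+")
  expect_true(all(rowSums(ph$mesh$normals[m$tri, ] * to_cam) > 0))
  # patch on the far side is absent
  far <- which(ph$mesh$centroids[, 1] < -5)
  expect_length(intersect(m$tri, far), 0)

  side <- which(abs(ph$mesh$normals[, 3]) < 1e-6)
  side_area <- sum(ph$mesh$areas[side])
  cover <- function(radius) {
    m1 <- surface_pixel_map(ph$mesh, camera_pose(0, radius = radius))
    m2 <- surface_pixel_map(ph$mesh, camera_pose(180, radius = radius))
    sum(ph$mesh$areas[intersect(union(m1$tri, m2$tri), side)]) / side_area
  }
  # finite-standoff tangency: visible fraction = 2*acos(R/d)/pi per pair
  expect_equal(cover(116.5), 2 * acos(15 / 116.5) / pi, tolerance = 0.01)
  # a distant camera pair sees essentially the whole side wall
  expect_gt(cover(500), 0.95)
  # camera inside the phantom is rejected
  expect_error(surface_pixel_map(ph$mesh,
                                 camera_pose(0, radius = 10, focal_mm = 5)),
               "outside")
})

test_that("total map weight is stable under mesh refinement", {
  cam <- camera_pose(0)
  w <- vapply(c(64, 128), function(nt) {
    ph <- build_cylinder_phantom(30, 40, 1, n_theta = nt, ring_height = 1)
    sum(surface_pixel_map(ph$mesh, cam)$weight)
  }, 0)
  expect_equal(w[1], w[2], tolerance = 0.02)
})

test_that("ray-cylinder intersection finds the right entry points", {
  prim <- list(type = "cylinder", radius = 5, height = 10, center = c(0, 0, 0))
  # ray along -x from outside hits the near wall at x = 5
  h <- ray_cylinder(matrix(c(20, 0, 0), 1), matrix(c(-1, 0, 0), 1), prim)
  expect_true(h$hit)
  expect_equal(as.numeric(h$point), c(5, 0, 0))
  expect_equal(as.numeric(h$normal), c(1, 0, 0))
  # from inside, exit through the wall
  h2 <- ray_cylinder(matrix(c(0, 0, 0), 1), matrix(c(0, 1, 0), 1), prim)
  expect_equal(as.numeric(h2$point), c(0, 5, 0))
  # cap hit
  h3 <- ray_cylinder(matrix(c(1, 1, 20), 1), matrix(c(0, 0, -1), 1), prim)
  expect_equal(as.numeric(h3$point), c(1, 1, 5))
  expect_equal(as.numeric(h3$normal), c(0, 0, 1))
  # miss
  h4 <- ray_cylinder(matrix(c(20, 20, 0), 1), matrix(c(1, 0, 0), 1), prim)
  expect_false(h4$hit)
})

test_that("meshes round-trip through OFF and PLY", {
  ph <- build_cylinder_phantom(10, 8, 1, n_theta = 16)
  for (ext in c("off", "ply")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mesh(ph$mesh, f)
    m2 <- read_mesh(f)
    expect_equal(m2$vertices, ph$mesh$vertices, tolerance = 1e-7)
    expect_identical(m2$triangles, ph$mesh$triangles)
    expect_equal(mesh_volume(m2), mesh_volume(ph$mesh), tolerance = 1e-7)
    unlink(f)
  }
})
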