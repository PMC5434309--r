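test_that("nearest-plane fill produces the expected slab between two planes", {
  px <- 5
  xs <- (1:80 - 0.5) * px
  disk <- outer(xs, xs, function(y, x) (x - 200)^2 + (y - 200)^2 <= 100^2)
  lm <- matrix(tissue_code("resin"), 80, 80)
  lm[disk] <- tissue_code("bone")
  poses <- list(identity_pose(35), identity_pose(70))
  vol <- rasterize_stack(list(lm, lm), poses, 5, c(400, 400, 200), px,
                         z_range = c(35, 70))
  vv <- class_voxel_volumes(vol)
  expect_lt(abs(vv[["bone"]] - pi * 100^2 * 35) / (pi * 100^2 * 35), 0.02)

  expect_error(rasterize_stack(list(lm), poses[1], 5, c(400, 400, 200), px),
               "at least 2")
  # two coincident planes have zero local gap
  expect_error(rasterize_stack(list(lm, lm), list(identity_pose(35),
                                                  identity_pose(35)),
                               5, c(400, 400, 200), px),
               "overlapping")
})

test_that("iso-surface of a voxelized ball is watertight with Euler characteristic 2", {
  spec <- make_ossicle_phantom("offset_sphere", 0)
  vol <- label_volume(array(0L, dim = c(60, 60, 60)), 10, c(260, 260, 130))
  tv <- voxelize_phantom(spec, vol)
  mesh <- surface_from_volume(tv, "bone", smoothing_iters = 10)
  expect_true(mesh$watertight)
  expect_equal(mesh$euler_characteristic, 2)
  v <- mesh_volume_tetra(mesh)
  truth <- 4 / 3 * pi * 250^3
  expect_lt(abs(v - truth) / truth, 0.02)

  # smoothing is volume-preserving within 1 %
  m0 <- surface_from_volume(tv, "bone", smoothing_iters = 0)
  m20 <- surface_from_volume(tv, "bone", smoothing_iters = 20)
  expect_lt(abs(mesh_volume_tetra(m20) - mesh_volume_tetra(m0)) /
              mesh_volume_tetra(m0), 0.01)

  expect_error(surface_from_volume(tv, "cartilage"), "absent")
})

test_that("lofting identical squares yields the exact prism volume", {
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  stacks <- lapply(1:5, function(k) ring_set(list(sq), k * 35))
  mesh <- loft_contours(stacks)
  expect_true(mesh$watertight)
  v <- mesh_volume_tetra(mesh)
  expect_lt(abs(v - 1e6 * 140) / (1e6 * 140), 0.001)

  expect_error(loft_contours(stacks[1]), ">= 2 slices")
})

test_that("lofted circles match the prism over the resampled polygon", {
  rings <- lapply(1:4, function(k)
    ring_set(list(circle_ring(500, 500, 100, 48)), k * 35, "vessel"))
  mesh <- loft_contours(rings, n_profile = 48)
  expect_true(mesh$watertight)
  # exact volume of the 48-gon prism
  poly_area <- 0.5 * 48 * sin(2 * pi / 48) * 100^2
  v <- mesh_volume_tetra(mesh)
  expect_lt(abs(v - poly_area * 105) / (poly_area * 105), 0.001)
})

test_that("a branching vessel lofts to a watertight genus-0 surface", {
  stacks <- list(
    ring_set(list(circle_ring(500, 500, 60)), 35, "vessel"),
    ring_set(list(circle_ring(500, 500, 60)), 70, "vessel"),
    ring_set(list(circle_ring(470, 500, 55), circle_ring(540, 500, 55)),
             105, "vessel"),
    ring_set(list(circle_ring(430, 500, 50), circle_ring(570, 500, 50)),
             140, "vessel"),
    ring_set(list(circle_ring(400, 500, 50), circle_ring(600, 500, 50)),
             175, "vessel"))
  expect_message(mesh <- loft_contours(stacks), "branching")
  expect_true(mesh$watertight)
  expect_equal((2 - mesh$euler_characteristic) / 2, 0)  # genus 0
})

test_that("tilt-aware fill beats flat stacking on a tilted phantom", {
  spec <- make_ossicle_phantom("offset_sphere", 0)
  sched <- grinding_schedule(17, 35, tilt = tilt_for_spread(spec))
  sim <- simulate_grinding(spec, sched, default_stain_model(0), seed = 4)
  poses <- build_pose_stack(sim$images, sim$csv, spec$fiducial_columns,
                            spec$block_size[3], 5, 8)
  lms <- lapply(sim$images, function(im)
    classify_pixels(im, default_stain_model(0))$labels)
  zr <- c(0, 800)
  vt <- rasterize_stack(lms, poses, 20, spec$block_size, 5, z_range = zr)
  vf <- rasterize_stack(lms, poses, 20, spec$block_size, 5, flat = TRUE,
                        z_range = zr)
  truth <- voxelize_phantom(spec, vt)
  expect_lt(voxel_error(vt, truth), voxel_error(vf, truth))
})
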