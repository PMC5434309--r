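cube_mesh <- function(edge = 1000, shift = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  v <- sweep(v, 2, shift, "+")
  tri <- rbind(  # 12 consistently outward-wound triangles
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = edge
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = edge
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = edge
  structure(list(vertices = v, triangles = tri, class = "bone",
                 watertight = TRUE), class = "surface_mesh")
}

tetra_mesh <- function(a = 1000) {
  v <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
             c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  tri <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(3, 1, 4))
  structure(list(vertices = v, triangles = tri, class = "bone",
                 watertight = TRUE), class = "surface_mesh")
}

test_that("tetrahedral mesh volume is exact and translation invariant", {
  expect_equal(mesh_volume_tetra(cube_mesh(1000)), 1e9)
  a <- 1000
  expect_equal(mesh_volume_tetra(tetra_mesh(a)), a^3 / (6 * sqrt(2)),
               tolerance = 1e-9)
  far <- cube_mesh(1000, shift = c(1e6, -3e5, 7e4))
  expect_equal(mesh_volume_tetra(far), 1e9, tolerance = 1e-9)

  holed <- cube_mesh(1000)
  holed$triangles <- holed$triangles[-1, ]
  expect_error(mesh_volume_tetra(holed), "not watertight")
})

test_that("not-calcified fraction arithmetic and phantom recovery", {
  expect_equal(not_calcified_fraction(c(bone = 9.9e7, vessel = 1e6)), 1)
  expect_equal(not_calcified_fraction(c(bone = 5e8)), 0)
  expect_error(not_calcified_fraction(c(vessel = 1e6)), "bone")

  # direct voxelization of the calibrated 1 % phantom
  spec <- make_ossicle_phantom("sphere_channel", 0)
  vol <- label_volume(array(0L, dim = c(110, 110, 110)), 10, c(50, 50, 100))
  tv <- voxelize_phantom(spec, vol)
  iv <- interior_class_volumes(tv, "bone")
  f <- not_calcified_fraction(iv)
  expect_lt(abs(f - 1.0), 0.05)
})

test_that("open through-channels are excluded from the strict interior", {
  # the two_sphere tube pierces the sphere on both sides: not enclosed
  spec <- make_ossicle_phantom("two_sphere_test", 0)
  vol <- label_volume(array(0L, dim = c(65, 65, 70)), 20, c(0, 0, 0))
  tv <- voxelize_phantom(spec, vol)
  iv <- interior_class_volumes(tv, "bone")
  expect_equal(unname(iv["vessel"]), 0)
})

test_that("skeleton diameters are within one voxel on constructed tubes", {
  vox <- 5
  for (dia in c(20, 50, 80)) {
    n <- ceiling((dia + 60) / vox)
    ctr <- (floor(n / 2) - 0.5) * vox  # axis through voxel centres
    vol <- fx_solid_volume(function(x, y, z)
      ifelse((x - ctr)^2 + (y - ctr)^2 <= (dia / 2)^2,
             tissue_code("vessel"), 0L),
      vox, c(n, n, 30))
    est <- channel_diameters(vol)$summary[["median"]]
    expect_lt(abs(est - dia), vox + 1e-9)
  }

  # torus: tube diameter 30 um bent around a ring
  vox <- 5
  n <- 90
  ctr <- 225
  vol <- fx_solid_volume(function(x, y, z) {
    rr <- sqrt((x - ctr)^2 + (y - ctr)^2)
    ifelse((rr - 120)^2 + (z - ctr)^2 <= 15^2, tissue_code("vessel"), 0L)
  }, vox, c(n, n, n))
  est <- channel_diameters(vol)$summary[["median"]]
  expect_lt(abs(est - 30), 5 + 1e-9)

  empty <- label_volume(array(0L, dim = c(5, 5, 5)), 5)
  cd <- channel_diameters(empty)
  expect_length(cd$diameters_um, 0)
})

test_that("diffusion screen matches closed forms", {
  vox <- 10
  # solid sphere r = 500: flagged core fraction ((500-150)/500)^3
  n <- 110
  vol <- fx_solid_volume(function(x, y, z)
    ifelse((x - 550)^2 + (y - 550)^2 + (z - 550)^2 <= 500^2, 1L, 0L),
    vox, c(n, n, n))
  wt <- wall_thickness(vol, "bone", 150)
  expect_lt(abs(wt$flagged_fraction_pct - 100 * (350 / 500)^3), 2)
  expect_false(wt$fully_supplied)
  # local thickness of a ball is its diameter
  expect_lt(abs(wt$thickness_um[["median"]] - 1000) / 1000, 0.05)

  # hollow cylinder with 120 um wall: everything within reach
  n2 <- 80
  vol2 <- fx_solid_volume(function(x, y, z) {
    r2 <- (x - 400)^2 + (y - 400)^2
    ifelse(r2 <= 350^2 & r2 >= 230^2, 1L, 0L)
  }, vox, c(n2, n2, n2))
  wt2 <- wall_thickness(vol2, "bone", 150)
  expect_equal(wt2$flagged_fraction_pct, 0)
  expect_true(wt2$fully_supplied)
  expect_lt(abs(wt2$thickness_um[["median"]] - 120), vox + 1e-9)

  # plate of thickness 300 at the 150 um limit: boundary case
  vol3 <- fx_solid_volume(function(x, y, z)
    ifelse(z > 200 & z <= 500, 1L, 0L), vox, c(60, 60, 70))
  wt3 <- wall_thickness(vol3, "bone", 150)
  expect_lt(wt3$flagged_fraction_pct, 100 * vox / 300)

  expect_error(wall_thickness(vol3, "cartilage"), "absent")
})

test_that("modality comparison reports volume differences", {
  vol <- fx_solid_volume(function(x, y, z)
    ifelse((x - 200)^2 + (y - 200)^2 + (z - 200)^2 <= 150^2, 1L, 0L),
    10, c(40, 40, 40))
  rep1 <- morphometry_report(vol, "sphere")
  tab <- compare_modalities(rep1, rep1)
  expect_true(all(tab$abs_diff_um3 == 0))
  expect_true(all(tab$rel_diff_pct == 0))

  vol2 <- vol
  vol2$labels[vol2$labels == 1L] <- 2L  # cartilage-only report
  rep2 <- suppressWarnings(morphometry_report(vol2, "other",
                                              structure_class = "cartilage"))
  expect_error(compare_modalities(rep1, rep2), "no shared")
})
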