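test_that("fiducial detection finds sub-pixel centers on clean slices", {
  fx <- fx_flat10_clean()
  spec <- fx$spec
  fid <- detect_fiducials(fx$sim$images[[1]], expected_radius_px = 8)
  # no jitter: image frame equals block frame, centers in px = anchors / px
  expected <- canonical_order_points(spec$fiducial_columns / 5)
  expect_lt(max(abs(fid$centers_px - expected)), 0.25)
})

test_that("fiducial detection fails cleanly and is rotation-equivariant", {
  fx <- fx_flat10_clean()
  img <- fx$sim$images[[1]]
  # paint the fiducials over with resin colour
  lab <- classify_pixels(img, default_stain_model(0), majority_radius = 0)
  masked <- img
  for (ch in 1:3) {
    pl <- masked[, , ch]
    pl[lab$labels == tissue_code("fiducial")] <-
      default_stain_model()$means["resin", ch] / 255
    masked[, , ch] <- pl
  }
  expect_error(detect_fiducials(masked, 8), "detection failure")

  # rotate image by 90 degrees: same physical marks are found
  rot <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , ]
  fid <- detect_fiducials(img, 8)
  fid_rot <- detect_fiducials(rot, 8)
  H <- dim(img)[1]
  # (x, y) -> (y, W - x) under this rotation
  mapped <- cbind(fid$centers_px[, 2], dim(img)[2] - fid$centers_px[, 1])
  err <- vapply(seq_len(3), function(i)
    min(sqrt(rowSums(sweep(fid_rot$centers_px, 2, mapped[i, ])^2))),
    numeric(1))
  expect_lt(max(err), 0.5)
})

test_that("three-point similarity is exact and reports reflections", {
  anchors <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  # identity: detections at anchors (in px at 1 um/px)
  tr <- estimate_inplane_transform(anchors, anchors, pixel_size = 1)
  expect_equal(tr$angle_deg, 0)
  expect_equal(c(tr$tx_um, tr$ty_um), c(0, 0))
  expect_equal(tr$residual_px, 0)

  # rotating detections by +10 deg about the centroid is undone exactly
  th <- 10 * pi / 180
  ctr <- colMeans(anchors)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  det10 <- sweep(sweep(anchors, 2, ctr) %*% t(R), 2, ctr, "+")
  tr10 <- estimate_inplane_transform(det10, anchors, 1)
  expect_equal(tr10$angle_deg, -10, tolerance = 1e-6)
  expect_lt(tr10$residual_px, 1e-6)

  mirrored <- anchors %*% diag(c(-1, 1))
  expect_error(estimate_inplane_transform(mirrored, anchors, 1), "reflection")
})

test_that("plane estimation is exact interpolation of the caliper readings", {
  anchors <- rbind(c(0, 0), c(10000, 0), c(0, 10000))
  flat <- plane_from_abrasion(c(20000, 20000, 20000), 25000, anchors)
  expect_equal(c(flat$gx, flat$gy), c(0, 0))
  expect_equal(flat$c_um, 5000)

  tilted <- plane_from_abrasion(c(20000, 19900, 20000), 25000, anchors)
  expect_equal(tilted$gx, 0.01)
  expect_equal(tilted$gy, 0)
  expect_equal(tilted$tilt_um_per_mm, 10)

  collinear <- rbind(c(0, 0), c(100, 100), c(200, 200))
  expect_error(plane_from_abrasion(c(1, 2, 3), 100, collinear), "collinear")
})

test_that("pose stack recovery is exact without noise", {
  fx <- fx_flat10_clean()
  poses <- build_pose_stack(fx$sim$images, fx$sim$csv,
                            fx$spec$fiducial_columns,
                            fx$spec$block_size[3], 5, 8)
  expect_length(poses, 10)
  expect_equal(mean(attr(poses, "gaps_um")), 35)
  for (k in seq_along(poses)) {
    tp <- fx$sim$truth$poses[[k]]
    expect_lt(abs(poses[[k]]$angle_deg - tp$angle_deg), 1e-3)
    expect_lt(abs(poses[[k]]$c_um - tp$c_um), 0.5)
    expect_lt(abs(poses[[k]]$tx_um - tp$tx_um), 1)
  }
})

test_that("pose stack is order-independent and validates its inputs", {
  fx <- fx_flat10_clean()
  spec <- fx$spec
  ref <- build_pose_stack(fx$sim$images, fx$sim$csv, spec$fiducial_columns,
                          spec$block_size[3], 5, 8)
  shuffled <- fx$sim$csv[rev(seq_len(nrow(fx$sim$csv))), ]
  p2 <- build_pose_stack(fx$sim$images, shuffled, spec$fiducial_columns,
                         spec$block_size[3], 5, 8)
  expect_equal(lapply(ref, `[[`, "c_um"), lapply(p2, `[[`, "c_um"))

  expect_error(build_pose_stack(fx$sim$images, fx$sim$csv[-4, ],
                                spec$fiducial_columns, spec$block_size[3],
                                5, 8),
               "missing abrasion CSV row for run\\(s\\): 4")

  bad <- fx$sim$csv
  bad[5, 2:4] <- bad[2, 2:4]  # run 5 suddenly shallower again
  expect_error(build_pose_stack(fx$sim$images, bad, spec$fiducial_columns,
                                spec$block_size[3], 5, 8),
               "non-monotone")
})

test_that("pose stacks serialize to JSON and back", {
  fx <- fx_flat10_clean()
  poses <- build_pose_stack(fx$sim$images, fx$sim$csv,
                            fx$spec$fiducial_columns,
                            fx$spec$block_size[3], 5, 8)
  path <- file.path(tempdir(), "poses.json")
  write_pose_stack(poses, path)
  back <- read_pose_stack(path)
  expect_equal(length(back), length(poses))
  expect_equal(back[[3]]$c_um, poses[[3]]$c_um)
  expect_equal(back[[3]]$angle_deg, poses[[3]]$angle_deg)
})
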