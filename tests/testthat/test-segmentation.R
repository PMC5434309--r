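test_that("stain model fitting recovers the generating colours", {
  gen <- default_stain_model(5)
  set.seed(1)
  samples <- do.call(rbind, lapply(tissue_classes(), function(cl) {
    mu <- gen$means[cl, ]
    data.frame(class = cl, r = rnorm(400, mu[1], 5), g = rnorm(400, mu[2], 5),
               b = rnorm(400, mu[3], 5))
  }))
  fit <- fit_stain_model(samples)
  expect_lt(max(abs(fit$means - gen$means)), 2)

  # two classes with identical samples -> separability warning
  twin <- samples
  twin[twin$class == "bone", c("r", "g", "b")] <-
    twin[twin$class == "vessel", c("r", "g", "b")]
  expect_warning(fit_stain_model(twin), "separable")

  expect_error(fit_stain_model(samples[samples$class != "cartilage", ]),
               "cartilage")
  tiny <- rbind(samples[samples$class != "vessel", ],
                samples[samples$class == "vessel", ][1:10, ])
  expect_error(fit_stain_model(tiny), "only 10")
})

test_that("pixel classification is exact at class means and accurate on phantoms", {
  m <- default_stain_model(5)
  img <- array(0, dim = c(1, 1, 3))
  img[1, 1, ] <- m$means["bone", ] / 255
  lm <- classify_pixels(img, m, majority_radius = 0)
  expect_equal(lm$labels[1, 1], tissue_code("bone"))

  fx <- fx_flat10_clean()
  lm0 <- classify_pixels(fx$sim$images[[5]], default_stain_model(0))
  expect_gte(mean(lm0$labels == fx$sim$truth$labels[[5]]), 0.995)

  fx33 <- fx_flat33()
  lm5 <- classify_pixels(fx33$sim$images[[16]], default_stain_model(5))
  expect_gte(mean(lm5$labels == fx33$sim$truth$labels[[16]]), 0.97)
})

test_that("contour extraction matches closed-form areas and orientation", {
  px <- 2
  xs <- (1:200 - 0.5) * px
  disk <- outer(xs, xs, function(y, x) (x - 200)^2 + (y - 200)^2 <= 100^2)
  labm <- matrix(tissue_code("resin"), 200, 200)
  labm[disk] <- tissue_code("bone")
  cs <- extract_contours(labm, "bone", pixel_size = px)
  expect_length(cs, 1)
  expect_false(cs[[1]]$hole)
  expect_lt(abs(cs[[1]]$area_um2 - pi * 100^2) / (pi * 100^2), 0.01)
  # pixel-count area agrees with shoelace area within 2 %
  expect_lt(abs(cs[[1]]$area_um2 - sum(disk) * px^2) / cs[[1]]$area_um2, 0.02)

  ann <- disk & !outer(xs, xs, function(y, x)
    (x - 200)^2 + (y - 200)^2 <= 50^2)
  labm2 <- matrix(tissue_code("resin"), 200, 200)
  labm2[ann] <- tissue_code("bone")
  cs2 <- extract_contours(labm2, "bone", pixel_size = px)
  expect_length(cs2, 2)
  holes <- vapply(cs2, `[[`, logical(1), "hole")
  expect_equal(sort(holes), c(FALSE, TRUE))
  signs <- vapply(cs2, function(r) {
    xy <- r$xy
    j <- c(2:nrow(xy), 1)
    sign(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]))
  }, numeric(1))
  expect_equal(signs[!holes], 1)   # outer CCW
  expect_equal(signs[holes], -1)   # hole CW

  none <- extract_contours(matrix(tissue_code("resin"), 50, 50), "bone",
                           pixel_size = px)
  expect_length(none, 0)

  # components below the area threshold are dropped
  labm3 <- matrix(tissue_code("resin"), 50, 50)
  labm3[25, 25] <- tissue_code("bone")  # one pixel = 4 um^2
  expect_length(extract_contours(labm3, "bone", pixel_size = px,
                                 min_area_um2 = 200), 0)
})

test_that("contours land at the same block coordinates under 180-deg rotation", {
  px <- 2
  xs <- (1:120 - 0.5) * px
  disk <- outer(xs, xs, function(y, x) (x - 90)^2 + (y - 140)^2 <= 50^2)
  labm <- matrix(tissue_code("resin"), 120, 120)
  labm[disk] <- tissue_code("bone")
  cs <- extract_contours(labm, "bone", pose = identity_pose(), pixel_size = px)
  rot <- labm[120:1, 120:1]
  # pose undoing a 180-deg rotation about the image centre
  W <- 120 * px
  pose180 <- list(angle_deg = 180, tx_um = W, ty_um = W, scale = 1,
                  gx = 0, gy = 0, c_um = 0)
  cs_rot <- extract_contours(rot, "bone", pose = pose180, pixel_size = px)
  c1 <- colMeans(cs[[1]]$xy)
  c2 <- colMeans(cs_rot[[1]]$xy)
  expect_lt(max(abs(c1 - c2)), 0.5)
  expect_lt(abs(cs[[1]]$area_um2 - cs_rot[[1]]$area_um2) / cs[[1]]$area_um2,
            1e-6)
  # directed nearest-point distance (discrete Hausdorff) below 0.5 um
  d <- apply(cs[[1]]$xy, 1, function(p)
    min(sqrt((cs_rot[[1]]$xy[, 1] - p[1])^2 +
             (cs_rot[[1]]$xy[, 2] - p[2])^2)))
  expect_lt(max(d), 0.5)
})

test_that("manual contours are validated, oriented and transformed", {
  dir <- tempdir()
  sq <- data.frame(class = "bone", polygon_id = 1L, ring_id = 1L,
                   x_um = c(0, 1000, 1000, 0, 0),
                   y_um = c(0, 0, 1000, 1000, 0))
  f <- file.path(dir, "sq.csv")
  write.csv(sq, f, row.names = FALSE)
  mc <- load_manual_contours(f)
  expect_equal(mc$bone[[1]]$area_um2, 1e6)

  # clockwise input is reoriented to CCW
  cw <- sq[c(1, 4, 3, 2, 1), ]
  write.csv(cw, f, row.names = FALSE)
  mc2 <- load_manual_contours(f)
  xy <- mc2$bone[[1]]$xy
  j <- c(2:nrow(xy), 1)
  expect_gt(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]), 0)

  write.csv(sq[1:4, ], f, row.names = FALSE)
  expect_error(load_manual_contours(f), "not closed")

  bow <- data.frame(class = "bone", polygon_id = 2L, ring_id = 1L,
                    x_um = c(0, 1000, 0, 1000, 0),
                    y_um = c(0, 1000, 1000, 0, 0))
  write.csv(bow, f, row.names = FALSE)
  expect_error(load_manual_contours(f), "self-intersecting")
})

test_that("contour CSV files round-trip through the manual loader", {
  px <- 2
  xs <- (1:100 - 0.5) * px
  disk <- outer(xs, xs, function(y, x) (x - 100)^2 + (y - 100)^2 <= 60^2)
  labm <- matrix(tissue_code("resin"), 100, 100)
  labm[disk] <- tissue_code("bone")
  cs <- extract_contours(labm, "bone", pixel_size = px)
  f <- file.path(tempdir(), "rt.csv")
  write_contours(cs, f)
  back <- load_manual_contours(f)
  expect_lt(abs(back$bone[[1]]$area_um2 - cs[[1]]$area_um2) /
              cs[[1]]$area_um2, 1e-6)
})
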