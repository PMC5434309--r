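## Virtual grinding: turn an analytic phantom into a stack of stained
## block-surface photographs, per-run caliper readings and a ground-truth
## bundle.

#' Stain colour model
#'
#' Mean RGB colour (0-255) and covariance per tissue class, plus the
#' show-through model for structures shimmering through the uncoloured resin
#' just below the ground surface. The default palette mimics a
#' Mann-Dominici-type surface stain: eosinophilic pink/orange bone matrix,
#' metachromatic violet cartilage, dark red vessel lumina, blue soft tissue,
#' pale amber resin and brown wooden fiducials.
#'
#' @param means 6x3 matrix of class mean colours, rows named by class
#' @param covs list of six 3x3 covariance matrices
#' @param show_through list with `depth` (um probed below the surface),
#'   `opacity` (blend weight at zero depth) and `attenuation` (exponential
#'   length, um)
#' @param check_distinct reject models whose class mean colours coincide
#'   (default TRUE)
#' @return a `stain_model` object
#' @export
stain_model <- function(means, covs, show_through = list(depth = 150,
                                                         opacity = 0.35,
                                                         attenuation = 60),
                        check_distinct = TRUE) {
  cl <- tissue_classes()
  means <- as.matrix(means)
  stopifnot(nrow(means) == length(cl), ncol(means) == 3,
            length(covs) == length(cl))
  rownames(means) <- cl
  names(covs) <- cl
  # class means must be pairwise distinct, covariances positive definite
  d <- as.matrix(dist(means))
  if (check_distinct && any(d[upper.tri(d)] < 1e-6))
    stop("stain class mean colours are not distinct")
  for (v in covs)
    if (any(eigen(v, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("stain covariance not positive definite")
  structure(list(means = means, covs = covs, show_through = show_through),
            class = "stain_model")
}

#' @rdname stain_model
#' @param noise_sd per-channel colour standard deviation used for every class
#' @export
default_stain_model <- function(noise_sd = 5) {
  means <- rbind(
    resin       = c(235, 228, 215),
    bone        = c(230, 150, 120),
    cartilage   = c(150,  90, 170),
    vessel      = c(140,  40,  50),
    soft_tissue = c( 90, 110, 200),
    fiducial    = c(120,  85,  50))
  covs <- rep(list(diag(3) * max(noise_sd, 1e-3)^2), 6)
  m <- stain_model(means, covs)
  m$noise_sd <- noise_sd
  m
}

#' Grinding schedule
#'
#' Describes the virtual grinding process: number of runs, nominal abrasion
#' per run, plane tilt, measurement noise, in-plane photography jitter and
#' pixel size. `tilt` is the per-run gradient increment (dimensionless
#' dz/dx, dz/dy): the plane of run k has gradient `k * tilt`, i.e. the
#' machine skew accumulates, which makes the abrasion per run vary across
#' the block (uniform only when `tilt = c(0, 0)`). Planes are anchored at
#' fiducial column A, where each run removes exactly the nominal abrasion
#' (plus noise).
#'
#' @param n_runs number of grinding runs
#' @param nominal_abrasion um removed per run at fiducial A (default 35)
#' @param tilt length-2 per-run gradient increment (dz/dx, dz/dy)
#' @param abrasion_noise_sd sd of per-run abrasion noise, um
#' @param jitter_trans_sd_px sd of in-plane translation jitter, pixels
#' @param jitter_rot_sd_deg sd of in-plane rotation jitter, degrees
#' @param pixel_size um per pixel (default 5)
#' @return a `grinding_schedule` object
#' @export
grinding_schedule <- function(n_runs, nominal_abrasion = 35, tilt = c(0, 0),
                              abrasion_noise_sd = 0, jitter_trans_sd_px = 0,
                              jitter_rot_sd_deg = 0, pixel_size = 5) {
  stopifnot(n_runs >= 1, nominal_abrasion > 0, pixel_size > 0,
            length(tilt) == 2, abrasion_noise_sd >= 0)
  structure(list(n_runs = as.integer(n_runs),
                 nominal_abrasion = nominal_abrasion, tilt = as.numeric(tilt),
                 abrasion_noise_sd = abrasion_noise_sd,
                 jitter_trans_sd_px = jitter_trans_sd_px,
                 jitter_rot_sd_deg = jitter_rot_sd_deg,
                 pixel_size = pixel_size),
            class = "grinding_schedule")
}

#' Tilt increment reproducing a nominal-vs-peripheral abrasion spread
#'
#' Returns the per-run gradient increment such that each run removes
#' `nominal` um at fiducial A but `peripheral` um at the block corner
#' farthest from A (e.g. 35 um at the ossicles and 94 um in the periphery).
#'
#' @param spec a [phantom_spec()]
#' @param nominal abrasion at fiducial A, um
#' @param peripheral abrasion at the far corner, um
#' @return length-2 tilt vector for [grinding_schedule()]
#' @export
tilt_for_spread <- function(spec, nominal = 35, peripheral = 94) {
  A <- spec$fiducial_columns["A", ]
  corners <- rbind(c(0, 0), c(spec$block_size[1], 0),
                   c(0, spec$block_size[2]), spec$block_size[1:2])
  d <- sqrt(rowSums(sweep(corners, 2, A)^2))
  far <- corners[which.max(d), ]
  u <- (far - A) / max(d)
  u * (peripheral - nominal) / max(d)
}

# plane height (z, um) of run k at block coordinates (x, y)
plane_z <- function(pose, x, y) pose$gx * x + pose$gy * y + pose$c_um

# apply / invert the in-plane similarity (image um -> block um)
apply_pose_xy <- function(pose, x, y) {
  th <- pose$angle_deg * pi / 180
  s <- pose$scale
  list(x = s * (cos(th) * x - sin(th) * y) + pose$tx_um,
       y = s * (sin(th) * x + cos(th) * y) + pose$ty_um)
}
invert_pose_xy <- function(pose, x, y) {
  th <- pose$angle_deg * pi / 180
  s <- pose$scale
  dx <- (x - pose$tx_um) / s
  dy <- (y - pose$ty_um) / s
  list(x = cos(th) * dx + sin(th) * dy,
       y = -sin(th) * dx + cos(th) * dy)
}

#' Simulate the microgrinding and photography process
#'
#' Grinds the phantom away run by run. The cut surface of run k is the plane
#' `z(x, y) = c_k + gx_k x + gy_k y`; its height at fiducial A advances by
#' the nominal abrasion (plus noise) each run and its gradient is
#' `k * tilt`. For every run the function renders the stained surface photo
#' (true classes coloured by the stain model, structures up to
#' `show_through$depth` um below the surface shimmering through the resin
#' with exponentially attenuated opacity, fiducial disks at the jittered
#' camera pose), records the remaining thickness at the three fiducial
#' anchors rounded to 1 um (caliper precision), and stores the true pose and
#' label raster in the truth bundle. Simulation stops early, with a message,
#' if the next plane would exit the block.
#'
#' @param spec a [phantom_spec()]
#' @param schedule a [grinding_schedule()]
#' @param stain a [stain_model()]
#' @param seed integer; rendering and jitter are reproducible given the seed
#' @param out_dir optional directory; if given, images, CSV and truth bundle
#'   are written via [write_grinding_result()]
#' @return a `grinding_result`: list with `images` (list of H x W x 3 arrays
#'   in `[0,1]`), `csv` (data.frame run, thickness_A_um, thickness_B_um,
#'   thickness_C_um), `truth` (poses and label rasters), plus the inputs.
#' @export
simulate_grinding <- function(spec, schedule, stain = default_stain_model(),
                              seed = spec$seed, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(schedule, "grinding_schedule"))
  px <- schedule$pixel_size
  depth <- spec$block_size[3]
  A <- spec$fiducial_columns["A", ]
  fm <- spec$fiducial_columns
  W <- ceiling(spec$block_size[1] / px)
  H <- ceiling(spec$block_size[2] / px)
  cw <- W * px / 2
  ch <- H * px / 2

  xs <- (seq_len(W) - 0.5) * px
  ys <- (seq_len(H) - 0.5) * px
  xg <- rep(xs, each = H)   # column-major over H x W matrix
  yg <- rep(ys, times = W)

  with_local_seed(seed, {
    images <- list()
    labels <- list()
    poses <- list()
    csv <- data.frame(run = integer(), thickness_A_um = numeric(),
                      thickness_B_um = numeric(), thickness_C_um = numeric())
    hk <- 0
    stopped <- FALSE
    for (k in seq_len(schedule$n_runs)) {
      hk <- hk + schedule$nominal_abrasion +
        (if (schedule$abrasion_noise_sd > 0) rnorm(1, 0, schedule$abrasion_noise_sd) else 0)
      g <- k * schedule$tilt
      c_um <- hk - sum(g * A)
      # grinding becomes unmeasurable once a fiducial anchor is ground away
      z_anchor <- fm[, 1] * g[1] + fm[, 2] * g[2] + c_um
      if (max(z_anchor) >= depth - 0.5) {
        message("fiducial anchor ground through at run ", k,
                "; stopping after ", k - 1L, " completed runs")
        stopped <- TRUE
        break
      }

      th <- if (schedule$jitter_rot_sd_deg > 0)
        rnorm(1, 0, schedule$jitter_rot_sd_deg) else 0
      dt <- if (schedule$jitter_trans_sd_px > 0)
        rnorm(2, 0, schedule$jitter_trans_sd_px * px) else c(0, 0)
      thr <- th * pi / 180
      # image um -> block um: rotate about image centre, then translate
      tx <- cw - (cos(thr) * cw - sin(thr) * ch) + dt[1]
      ty <- ch - (sin(thr) * cw + cos(thr) * ch) + dt[2]
      pose <- list(run = k, angle_deg = th, tx_um = tx, ty_um = ty,
                   scale = 1, gx = g[1], gy = g[2], c_um = c_um)

      bxy <- apply_pose_xy(pose, xg, yg)
      zb <- plane_z(pose, bxy$x, bxy$y)
      cls <- query_classes(spec, bxy$x, bxy$y, zb)
      # outside the block, or where the wedge-shaped plane has already left
      # the block bottom, there is nothing (air): render as resin
      outside <- bxy$x < 0 | bxy$x > spec$block_size[1] |
                 bxy$y < 0 | bxy$y > spec$block_size[2] | zb > depth
      cls[outside] <- tissue_code("resin")

      col <- stain$means[cls + 1L, , drop = FALSE]
      # show-through of deeper structures below uncoloured resin
      st <- stain$show_through
      if (st$depth > 0 && st$opacity > 0) {
        open <- which(cls == tissue_code("resin") & !outside)
        step <- 10
        for (delta in seq(step, st$depth, by = step)) {
          if (length(open) == 0) break
          deep <- query_classes(spec, bxy$x[open], bxy$y[open],
                                zb[open] + delta, fiducials = FALSE)
          hit <- deep != tissue_code("resin")
          if (any(hit)) {
            w <- st$opacity * exp(-delta / st$attenuation)
            idx <- open[hit]
            col[idx, ] <- w * stain$means[deep[hit] + 1L, , drop = FALSE] +
              (1 - w) * col[idx, , drop = FALSE]
            open <- open[!hit]
          }
        }
      }
      # anti-aliased fiducial edges: a camera pixel integrates light over its
      # footprint, so disk edges ramp over ~1 px instead of stepping
      fr <- spec$fiducial_radius
      for (i in 1:3) {
        dfid <- sqrt((bxy$x - fm[i, 1])^2 + (bxy$y - fm[i, 2])^2)
        band <- which(abs(dfid - fr) < px & !outside)
        if (length(band) == 0) next
        f <- pmin(pmax((fr + px / 2 - dfid[band]) / px, 0), 1)
        uc <- query_classes(spec, bxy$x[band], bxy$y[band], zb[band],
                            fiducials = FALSE)
        ucol <- stain$means[uc + 1L, , drop = FALSE]
        fcol <- stain$means[tissue_code("fiducial") + 1L, ]
        col[band, ] <- f * rep(fcol, each = length(band)) + (1 - f) * ucol
      }
      # per-class Gaussian colour noise
      for (ci in seq_along(tissue_classes())) {
        sel <- which(cls == ci - 1L)
        if (length(sel) == 0) next
        Lc <- chol(stain$covs[[ci]])
        noise <- matrix(rnorm(3 * length(sel)), ncol = 3) %*% Lc
        col[sel, ] <- col[sel, ] + noise
      }
      col <- pmin(pmax(round(col), 0), 255)
      img <- array(0, dim = c(H, W, 3))
      img[, , 1] <- matrix(col[, 1], H, W)
      img[, , 2] <- matrix(col[, 2], H, W)
      img[, , 3] <- matrix(col[, 3], H, W)
      images[[k]] <- img / 255
      labels[[k]] <- matrix(cls, H, W)
      poses[[k]] <- pose
      thick <- unname(round(depth - (fm[, 1] * g[1] + fm[, 2] * g[2] + c_um)))
      csv <- rbind(csv, data.frame(run = k, thickness_A_um = thick[1],
                                   thickness_B_um = thick[2],
                                   thickness_C_um = thick[3]))
    }
    res <- structure(list(images = images, csv = csv,
                          truth = list(poses = poses, labels = labels),
                          spec = spec, schedule = schedule, stain = stain,
                          stopped = stopped, pixel_size = px),
                     class = "grinding_result")
    if (!is.null(out_dir)) write_grinding_result(res, out_dir)
    res
  })
}

#' @export
print.grinding_result <- function(x, ...) {
  cat("grinding_result:", length(x$images), "runs,",
      paste(dim(x$images[[1]])[1:2], collapse = " x "), "px,",
      "pixel", x$pixel_size, "um\n")
  invisible(x)
}

#' Write a grinding result to disk
#'
#' Writes `run_0001.tif` ... (8-bit RGB TIFF), `abrasion.csv`
#' (`run,thickness_A_um,thickness_B_um,thickness_C_um`), and a truth bundle
#' under `truth/`: `poses.json` (true poses plus a spec echo) and per-run
#' 8-bit label PNGs whose pixel value is the tissue class code (0-5, see
#' [tissue_classes()]).
#'
#' @param res a `grinding_result`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_grinding_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (k in seq_along(res$images)) {
    tiff::writeTIFF(res$images[[k]],
                    file.path(dir, sprintf("run_%04d.tif", k)),
                    bits.per.sample = 8L, compression = "none")
    png::writePNG(res$truth$labels[[k]] / 255,
                  file.path(dir, "truth", sprintf("run_%04d.png", k)))
  }
  write.csv(res$csv, file.path(dir, "abrasion.csv"), row.names = FALSE)
  meta <- list(
    poses = res$truth$poses,
    pixel_size_um = res$pixel_size,
    block_size_um = res$spec$block_size,
    fiducial_columns_um = as.data.frame(res$spec$fiducial_columns),
    fiducial_radius_um = res$spec$fiducial_radius,
    class_palette = setNames(as.list(seq_along(tissue_classes()) - 1L),
                             tissue_classes()))
  jsonlite::write_json(meta, file.path(dir, "truth", "poses.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
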