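## Slice pose recovery: fiducial detection, in-plane similarity fit, and
## inclined-plane estimation from the three caliper readings.

#' Detect the three fiducial marks in a slice image
#'
#' Classifies pixels against the stain model, labels connected components of
#' the fiducial class, keeps disk-like candidates of plausible area and
#' returns the three highest-confidence sub-pixel centroids in canonical
#' A/B/C order (see [canonical_order_points()]). Confidence is the agreement
#' between observed and expected disk area. If a fourth candidate scores
#' within 90% of the third, a warning is issued and the top three are kept.
#'
#' @param image H x W x 3 array in `[0,1]`
#' @param expected_radius_px expected fiducial disk radius in pixels
#' @param stain a [stain_model()] used for colour classification
#' @return a `fiducial_set`: list with `centers_px` (3x2, x/y in pixels,
#'   canonical order) and `confidence`
#' @export
detect_fiducials <- function(image, expected_radius_px,
                             stain = default_stain_model()) {
  lab <- classify_pixels(image, stain, majority_radius = 0)
  mask <- lab$labels == tissue_code("fiducial")
  H <- nrow(mask); W <- ncol(mask)
  comp <- .label_components3d(array(mask, dim = c(H, W, 1L)),
                              c(H, W, 1L), 6L)
  comp <- matrix(comp, H, W)
  ncomp <- max(comp)
  if (ncomp < 3)
    stop("fiducial detection failure: found ", ncomp,
         " candidate marks (need 3)")
  exp_area <- pi * expected_radius_px^2
  sizes <- tabulate(comp[comp > 0], nbins = ncomp)
  conf <- 1 - abs(sizes - exp_area) / exp_area
  conf[sizes < 0.2 * exp_area | sizes > 5 * exp_area] <- -Inf
  keep <- order(conf, decreasing = TRUE)
  if (sum(is.finite(conf)) < 3)
    stop("fiducial detection failure: only ", sum(is.finite(conf)),
         " plausible disk candidates")
  if (ncomp >= 4 && is.finite(conf[keep[4]]) &&
      conf[keep[4]] >= 0.9 * conf[keep[3]])
    warning("ambiguous fiducial detection: 4th candidate nearly as good as 3rd; keeping top 3")
  top <- keep[1:3]
  centers <- t(vapply(top, function(i) {
    idx <- which(comp == i, arr.ind = TRUE)
    refine_disk_center(image, stain, idx, expected_radius_px)
  }, numeric(2)))
  ord <- canonical_order_points(centers)
  # pairwise separation and non-collinearity
  d <- as.matrix(dist(ord))
  if (any(d[upper.tri(d)] <= 5))
    stop("fiducial detection failure: detected centers closer than 5 px")
  perm <- apply(ord, 1, function(r)
    which(centers[, 1] == r[1] & centers[, 2] == r[2])[1])
  structure(list(centers_px = ord, confidence = conf[top][perm]),
            class = "fiducial_set")
}

# sub-pixel disk centre: posterior-weighted centroid of fiducial-class
# probability in a window around the component (anti-aliased disk edges
# carry the sub-pixel information)
refine_disk_center <- function(image, stain, idx, radius_px) {
  H <- dim(image)[1]; W <- dim(image)[2]
  pad <- ceiling(radius_px / 2) + 2
  rows <- max(1, min(idx[, 1]) - pad):min(H, max(idx[, 1]) + pad)
  cols <- max(1, min(idx[, 2]) - pad):min(W, max(idx[, 2]) + pad)
  X <- cbind(as.vector(image[rows, cols, 1]),
             as.vector(image[rows, cols, 2]),
             as.vector(image[rows, cols, 3])) * 255
  cl <- tissue_classes()
  ll <- matrix(NA_real_, nrow(X), length(cl))
  for (i in seq_along(cl)) {
    d <- sweep(X, 2, stain$means[i, ])
    ll[, i] <- -0.5 * rowSums((d %*% solve(stain$covs[[i]])) * d) -
      0.5 * log(det(stain$covs[[i]]))
  }
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  w <- p[, tissue_code("fiducial") + 1L] / rowSums(p)
  wm <- matrix(w, length(rows), length(cols))
  # sub-pixel disk edge: 0.5-level contour of the posterior crosses the true
  # circle where edge coverage is one half; an algebraic circle fit (Kasa)
  # through those points gives the centre
  cc <- contourLines(cols - 0.5, rows - 0.5, t(wm), levels = 0.5)
  if (length(cc) > 0) {
    cc <- cc[[which.max(vapply(cc, function(l) length(l$x), 1L))]]
    x <- cc$x; y <- cc$y
    if (length(x) >= 6) {
      A <- cbind(x, y, 1)
      b <- -(x^2 + y^2)
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (!is.null(sol)) return(c(-sol[1] / 2, -sol[2] / 2))
    }
  }
  rg <- expand.grid(row = rows, col = cols)
  c(sum(w * (rg$col - 0.5)) / sum(w), sum(w * (rg$row - 0.5)) / sum(w))
}

#' Least-squares in-plane similarity from fiducial correspondences
#'
#' Procrustes fit of rotation, translation and (optionally, clamped)
#' isotropic scale mapping detected fiducial centers (pixels) to the known
#' block anchors (um). Three non-collinear point pairs make the fit exact up
#' to detection noise; the RMS residual is still computed and reported as a
#' drift alarm (e.g. fiducial stick wobble). A fit that would require a
#' reflection is an error: ground surfaces cannot be mirrored.
#'
#' @param found a `fiducial_set` from [detect_fiducials()], or a 3x2 matrix
#'   of centers in pixels (canonical order)
#' @param reference_anchors 3x2 matrix of block anchor coordinates, um
#'   (canonical order)
#' @param pixel_size um per pixel
#' @param allow_scale estimate isotropic scale (default TRUE)
#' @param scale_clamp allowed relative scale range (default 0.98-1.02)
#' @return list with `angle_deg`, `tx_um`, `ty_um`, `scale` (relative to
#'   `pixel_size`) and `residual_px`
#' @export
estimate_inplane_transform <- function(found, reference_anchors, pixel_size,
                                       allow_scale = TRUE,
                                       scale_clamp = c(0.98, 1.02)) {
  P <- if (inherits(found, "fiducial_set")) found$centers_px else as.matrix(found)
  Q <- as.matrix(reference_anchors)
  stopifnot(nrow(P) == 3, nrow(Q) == 3)
  P <- P * pixel_size  # image um
  tri_sign <- function(M)
    sign((M[2, 1] - M[1, 1]) * (M[3, 2] - M[1, 2]) -
         (M[3, 1] - M[1, 1]) * (M[2, 2] - M[1, 2]))
  if (tri_sign(P) == 0 || tri_sign(Q) == 0)
    stop("degenerate (collinear) fiducial triangle")
  if (tri_sign(P) != tri_sign(Q))
    stop("fit would require a reflection; slices cannot be mirrored")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  a <- sum(Pc * Qc)                       # sum p.q
  b <- sum(Pc[, 1] * Qc[, 2] - Pc[, 2] * Qc[, 1])  # sum p x q
  th <- atan2(b, a)
  s <- if (allow_scale) {
    s0 <- sqrt(a^2 + b^2) / sum(Pc^2)
    min(max(s0, scale_clamp[1]), scale_clamp[2])
  } else 1
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- qc - s * as.numeric(Rm %*% pc)
  fit <- sweep(s * Pc %*% t(Rm), 2, qc, "+")
  res_px <- sqrt(mean(rowSums((fit - Q)^2))) / pixel_size
  list(angle_deg = th * 180 / pi, tx_um = t[1], ty_um = t[2], scale = s,
       residual_px = res_px)
}

#' Grinding plane from the three caliper readings
#'
#' The three remaining-thickness measurements at the fiducial anchors fix
#' the (possibly inclined) grinding plane exactly: three unknowns
#' `(gx, gy, c)` of `z(x, y) = gx x + gy y + c`, three equations
#' `z(anchor_i) = block_depth - thickness_i`. This is interpolation, not
#' regression; the residual at the anchors is exactly zero.
#'
#' @param csv_row numeric length-3 thickness readings (um), order A, B, C,
#'   or a one-row data.frame with `thickness_A_um` ... columns
#' @param block_depth total block depth, um
#' @param anchors 3x2 matrix of anchor coordinates, um
#' @return list with `gx`, `gy`, `c_um`, and `tilt_um_per_mm` (gradient
#'   magnitude)
#' @export
plane_from_abrasion <- function(csv_row, block_depth, anchors) {
  if (is.data.frame(csv_row))
    th <- as.numeric(csv_row[1, c("thickness_A_um", "thickness_B_um",
                                  "thickness_C_um")])
  else th <- as.numeric(csv_row)
  stopifnot(length(th) == 3, all(is.finite(th)))
  A <- cbind(as.matrix(anchors), 1)
  if (abs(det(A)) < 1e-9) stop("singular geometry: anchors are collinear")
  sol <- solve(A, block_depth - th)
  list(gx = sol[1], gy = sol[2], c_um = sol[3],
       tilt_um_per_mm = sqrt(sol[1]^2 + sol[2]^2) * 1000)
}

#' Recover the full pose of every slice
#'
#' Combines fiducial-based in-plane registration with caliper-based plane
#' estimation into one `slice_pose` per run. Runs are sorted by index; a
#' missing CSV row is an error naming the run, and a non-monotone mean plane
#' height (a later run shallower than an earlier one) is a hard error
#' listing the offending runs. Mean abrasion per run (gap sizes) is attached
#' as an attribute.
#'
#' @param images list of H x W x 3 arrays, or a directory containing
#'   `run_NNNN.tif`
#' @param csv abrasion data.frame (`run`, `thickness_A_um`,
#'   `thickness_B_um`, `thickness_C_um`) or path to the CSV
#' @param anchors 3x2 matrix of fiducial anchor block coordinates, um
#'   (canonical order)
#' @param block_depth block depth, um
#' @param pixel_size um per pixel
#' @param expected_radius_px expected fiducial radius, pixels
#' @param stain stain model for fiducial detection
#' @param allow_scale,scale_clamp passed to [estimate_inplane_transform()]
#' @return a `slice_pose_stack`: list of per-run poses (`run`, `angle_deg`,
#'   `tx_um`, `ty_um`, `scale`, `gx`, `gy`, `c_um`, `residual_px`), with
#'   attribute `gaps_um`
#' @export
build_pose_stack <- function(images, csv, anchors, block_depth, pixel_size,
                             expected_radius_px,
                             stain = default_stain_model(),
                             allow_scale = TRUE, scale_clamp = c(0.98, 1.02)) {
  if (is.character(images)) images <- read_image_dir(images)
  if (is.character(csv)) csv <- read.csv(csv)
  anchors <- canonical_order_points(anchors)
  runs <- if (is.null(names(images))) seq_along(images)
          else sort(unique(as.integer(names(images))))
  csv <- csv[order(csv$run), ]
  missing <- setdiff(runs, csv$run)
  if (length(missing) > 0)
    stop("missing abrasion CSV row for run(s): ",
         paste(missing, collapse = ", "))
  poses <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    k <- runs[i]
    img <- images[[if (!is.null(names(images))) as.character(k) else i]]
    fid <- detect_fiducials(img, expected_radius_px, stain)
    tr <- estimate_inplane_transform(fid, anchors, pixel_size,
                                     allow_scale = allow_scale,
                                     scale_clamp = scale_clamp)
    pl <- plane_from_abrasion(csv[csv$run == k, ], block_depth, anchors)
    poses[[i]] <- c(list(run = k), tr[c("angle_deg", "tx_um", "ty_um",
                                        "scale", "residual_px")],
                    pl[c("gx", "gy", "c_um")])
  }
  mean_h <- vapply(poses, function(p)
    mean(p$gx * anchors[, 1] + p$gy * anchors[, 2] + p$c_um), numeric(1))
  bad <- which(diff(mean_h) <= 0)
  if (length(bad) > 0)
    stop("non-monotone mean plane height at run(s): ",
         paste(runs[bad + 1], collapse = ", "))
  structure(poses, class = "slice_pose_stack", gaps_um = diff(mean_h),
            anchors = anchors)
}

#' @export
print.slice_pose_stack <- function(x, ...) {
  g <- attr(x, "gaps_um")
  cat("slice_pose_stack:", length(x), "runs, mean gap",
      round(mean(g), 2), "um\n")
  invisible(x)
}

#' Serialize / load a pose stack as JSON
#' @param poses a `slice_pose_stack`
#' @param path JSON file path
#' @export
write_pose_stack <- function(poses, path) {
  jsonlite::write_json(lapply(poses, function(p) p[c(
    "run", "angle_deg", "tx_um", "ty_um", "scale", "gx", "gy", "c_um",
    "residual_px")]), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pose_stack
#' @export
read_pose_stack <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(lapply(raw, function(p) lapply(p, function(v)
    if (is.numeric(v) || is.integer(v)) v else as.numeric(v))),
    class = "slice_pose_stack")
}

# read run_NNNN.tif files from a directory into a named list
read_image_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^run_\\d+\\.tif$", full.names = TRUE))
  if (length(files) == 0) stop("no run_NNNN.tif images found in ", dir)
  imgs <- lapply(files, tiff::readTIFF)
  names(imgs) <- as.integer(sub("^run_0*(\\d+)\\.tif$", "\\1", basename(files)))
  imgs
}
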