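## Stain-based tissue segmentation: Gaussian colour model per class,
## maximum-likelihood pixel classification with a majority filter, and
## sub-pixel contour extraction.

#' Fit a stain colour model from labelled pixel samples
#'
#' Estimates per-class mean RGB colour and covariance from labelled sample
#' pixels (RGB in 0-255). Every tissue class must be represented by at least
#' 50 samples. A small ridge (0.25 intensity^2) is added to each covariance
#' so degenerate samples (e.g. constant colour) still give a usable model.
#' Classes whose fitted means are closer than `separability` intensity units
#' trigger a warning.
#'
#' @param samples data.frame with columns `class`, `r`, `g`, `b`
#' @param separability minimum mean-colour distance before warning
#' @return a [stain_model()]
#' @export
fit_stain_model <- function(samples, separability = 20) {
  cl <- tissue_classes()
  missing <- setdiff(cl, unique(samples$class))
  if (length(missing) > 0)
    stop("missing class(es) in samples: ", paste(missing, collapse = ", "))
  means <- matrix(NA_real_, length(cl), 3, dimnames = list(cl, NULL))
  covs <- vector("list", length(cl))
  for (i in seq_along(cl)) {
    s <- samples[samples$class == cl[i], c("r", "g", "b")]
    if (nrow(s) < 50)
      stop("class '", cl[i], "' has only ", nrow(s),
           " sample pixels (need >= 50)")
    means[i, ] <- colMeans(s)
    covs[[i]] <- stats::cov(as.matrix(s)) + diag(3) * 0.25
  }
  d <- as.matrix(dist(means))
  diag(d) <- Inf
  if (any(d < separability)) {
    bad <- which(d < separability, arr.ind = TRUE)
    warning("poorly separable stain classes: ",
            paste(unique(apply(bad, 1, function(ij)
              paste(sort(cl[ij]), collapse = "/"))), collapse = ", "))
  }
  stain_model(means, covs, check_distinct = FALSE)
}

#' Classify every pixel of a slice image
#'
#' Per-pixel maximum-likelihood tissue class under the per-class Gaussian
#' colour model, followed by a majority (mode) filter of the given radius.
#' Ties, both in likelihood and in the majority vote, break to the lowest
#' class code in the documented class order. Pixels classified as resin but
#' with colour far from the resin mean (Mahalanobis^2 above the 99.9%
#' chi-square quantile) are flagged in the `deep_evidence` attribute: these
#' are typically deeper structures shimmering through the transparent resin.
#'
#' @param image H x W x 3 array in `[0,1]`
#' @param model a [stain_model()]
#' @param majority_radius majority filter radius in pixels (default 1,
#'   i.e. a 3x3 window; 0 disables). The filter biases the apparent width of
#'   structures thinner than ~2 px.
#' @param pixel_size um per pixel, stored on the result
#' @param run run index, stored on the result
#' @return a `tissue_label_map`: list with `labels` (H x W integer class
#'   codes), `pixel_size`, `run`; attribute `deep_evidence`
#' @export
classify_pixels <- function(image, model, majority_radius = 1,
                            pixel_size = NA_real_, run = NA_integer_) {
  H <- dim(image)[1]; W <- dim(image)[2]
  X <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3])) * 255
  cl <- tissue_classes()
  nll <- matrix(NA_real_, nrow(X), length(cl))
  for (i in seq_along(cl)) {
    S <- model$covs[[i]]
    Si <- solve(S)
    d <- sweep(X, 2, model$means[i, ])
    q <- rowSums((d %*% Si) * d)
    nll[, i] <- 0.5 * q + 0.5 * log(det(S))
  }
  cls <- max.col(-nll, ties.method = "first") - 1L
  labm <- matrix(cls, H, W)
  if (majority_radius > 0)
    labm <- majority_filter(labm, majority_radius, length(cl))
  # deep-structure evidence among resin pixels
  ri <- tissue_code("resin") + 1L
  dres <- sweep(X, 2, model$means[ri, ])
  q <- rowSums((dres %*% solve(model$covs[[ri]])) * dres)
  deep <- matrix(cls == tissue_code("resin") &
                 q > stats::qchisq(0.999, df = 3), H, W)
  structure(list(labels = labm, pixel_size = pixel_size, run = run),
            class = "tissue_label_map", deep_evidence = deep)
}

# mode filter over a (2r+1)^2 window via shifted sums of class indicators;
# ties go to the lowest class code
majority_filter <- function(labm, r, n_classes) {
  H <- nrow(labm); W <- ncol(labm)
  best_count <- matrix(-1L, H, W)
  best_class <- matrix(0L, H, W)
  for (ci in 0:(n_classes - 1L)) {
    ind <- matrix(0L, H + 2 * r, W + 2 * r)
    ind[r + seq_len(H), r + seq_len(W)] <- (labm == ci)
    cnt <- matrix(0L, H, W)
    for (dy in -r:r)
      for (dx in -r:r)
        cnt <- cnt + ind[r + dy + seq_len(H), r + dx + seq_len(W)]
    upd <- cnt > best_count
    best_count[upd] <- cnt[upd]
    best_class[upd] <- ci
  }
  best_class
}

signed_ring_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1)
  sum(x * y[j] - x[j] * y) / 2
}

point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

#' Extract closed tissue contours from a label map
#'
#' Sub-pixel iso-contours (level 0.5) of the class indicator, computed on
#' the pixel-centre grid, transformed by the slice pose into block
#' coordinates. Components with area below `min_area_um2` are discarded.
#' Orientation is normalized: outer boundaries counter-clockwise, holes
#' clockwise (in block coordinates).
#'
#' @param labels a `tissue_label_map` (or plain H x W code matrix)
#' @param class tissue class name
#' @param pose slice pose (list with `angle_deg`, `tx_um`, `ty_um`, `scale`,
#'   `gx`, `gy`, `c_um`); identity if NULL
#' @param pixel_size um per pixel (taken from `labels` when available)
#' @param min_area_um2 minimum enclosed area (default 200 um^2, i.e. stain
#'   debris scale)
#' @return a `contour_set`: list of rings, each a list with `xy` (n x 2,
#'   block um, not closed), `area_um2`, `hole`, `polygon_id`, `ring_id`;
#'   attributes `class` and `pose`
#' @export
extract_contours <- function(labels, class, pose = NULL,
                             pixel_size = NULL, min_area_um2 = 200) {
  labm <- if (inherits(labels, "tissue_label_map")) labels$labels else labels
  if (is.null(pixel_size))
    pixel_size <- if (inherits(labels, "tissue_label_map") &&
                      is.finite(labels$pixel_size)) labels$pixel_size else 1
  if (is.null(pose))
    pose <- list(angle_deg = 0, tx_um = 0, ty_um = 0, scale = 1,
                 gx = 0, gy = 0, c_um = 0)
  H <- nrow(labm); W <- ncol(labm)
  mask <- labm == tissue_code(class)
  if (!any(mask)) return(empty_contour_set(class, pose))
  # pad with background so boundary-touching components close
  zm <- matrix(0, W + 2, H + 2)
  zm[1 + seq_len(W), 1 + seq_len(H)] <- t(mask) * 1
  xs <- (seq_len(W + 2) - 1.5) * pixel_size  # pixel centres incl. pad
  ys <- (seq_len(H + 2) - 1.5) * pixel_size
  cls <- contourLines(xs, ys, zm, levels = 0.5)
  if (length(cls) == 0) return(empty_contour_set(class, pose))
  rings <- lapply(cls, function(cc) {
    xy <- cbind(cc$x, cc$y)
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    xy
  })
  rings <- rings[vapply(rings, nrow, 1L) >= 3]
  if (length(rings) == 0) return(empty_contour_set(class, pose))
  areas <- vapply(rings, function(r) abs(signed_ring_area(r)), numeric(1))
  # containment depth decides hole status (even depth = outer)
  n <- length(rings)
  depth <- integer(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && areas[j] > areas[i] &&
          point_in_ring(rings[[i]][1, 1], rings[[i]][1, 2], rings[[j]]))
        depth[i] <- depth[i] + 1L
  keep <- areas >= min_area_um2
  rings <- rings[keep]; areas <- areas[keep]; depth <- depth[keep]
  if (length(rings) == 0) return(empty_contour_set(class, pose))
  hole <- depth %% 2L == 1L
  # assign each hole to its smallest containing outer ring
  outer_idx <- which(!hole)
  poly_of <- integer(length(rings))
  poly_of[outer_idx] <- seq_along(outer_idx)
  for (i in which(hole)) {
    cands <- outer_idx[vapply(outer_idx, function(j)
      areas[j] > areas[i] &&
        point_in_ring(rings[[i]][1, 1], rings[[i]][1, 2], rings[[j]]),
      logical(1))]
    poly_of[i] <- if (length(cands) > 0)
      poly_of[cands[which.min(areas[cands])]] else 0L
  }
  out <- vector("list", length(rings))
  ring_counter <- integer(max(poly_of, 1L))
  for (i in seq_along(rings)) {
    xy <- rings[[i]]
    sa <- signed_ring_area(xy)
    want_ccw <- !hole[i]
    if ((sa > 0) != want_ccw) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    bl <- apply_pose_xy(pose, xy[, 1], xy[, 2])
    pid <- max(poly_of[i], 1L)
    ring_counter[pid] <- ring_counter[pid] + 1L
    out[[i]] <- list(xy = cbind(bl$x, bl$y), area_um2 = abs(sa),
                     hole = hole[i], polygon_id = pid,
                     ring_id = ring_counter[pid])
  }
  structure(out, class = "contour_set", tissue = class, pose = pose)
}

empty_contour_set <- function(class, pose) {
  structure(list(), class = "contour_set", tissue = class, pose = pose)
}

#' @export
print.contour_set <- function(x, ...) {
  cat("contour_set (", attr(x, "tissue"), "): ", length(x), " ring(s)\n",
      sep = "")
  invisible(x)
}

# proper self-intersection test (O(n^2), fine for manual contours)
ring_self_intersects <- function(xy) {
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), , drop = FALSE])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

#' Load manually drawn contours
#'
#' Reads contours in the package's polyline CSV dialect
#' `class,polygon_id,ring_id,x_um,y_um` (image coordinates, um). Every ring
#' must be explicitly closed (last point repeats the first) and simple;
#' open or self-intersecting rings are errors naming the polygon. Rings are
#' reoriented to the package convention (outer CCW, holes CW; `ring_id` 1 is
#' the outer ring) and transformed by the pose into block coordinates.
#'
#' @param path CSV file path
#' @param pose slice pose (identity if NULL)
#' @return list of `contour_set`s, one per class present in the file
#' @export
load_manual_contours <- function(path, pose = NULL) {
  if (is.null(pose))
    pose <- list(angle_deg = 0, tx_um = 0, ty_um = 0, scale = 1,
                 gx = 0, gy = 0, c_um = 0)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "polygon_id", "ring_id", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("manual contour file must have columns ", paste(need, collapse = ","))
  out <- list()
  for (cls in unique(df$class)) {
    sub <- df[df$class == cls, ]
    rings <- list()
    for (pid in unique(sub$polygon_id)) {
      for (rid in unique(sub$ring_id[sub$polygon_id == pid])) {
        xy <- as.matrix(sub[sub$polygon_id == pid & sub$ring_id == rid,
                            c("x_um", "y_um")])
        if (nrow(xy) < 4 || any(xy[1, ] != xy[nrow(xy), ]))
          stop("polygon ", pid, " ring ", rid, " of class '", cls,
               "' is not closed (last point must repeat the first)")
        xy <- xy[-nrow(xy), , drop = FALSE]
        if (ring_self_intersects(xy))
          stop("polygon ", pid, " ring ", rid, " of class '", cls,
               "' is self-intersecting")
        hole <- rid != 1
        sa <- signed_ring_area(xy)
        if ((sa > 0) == hole) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
        bl <- apply_pose_xy(pose, xy[, 1], xy[, 2])
        rings[[length(rings) + 1]] <-
          list(xy = cbind(bl$x, bl$y), area_um2 = abs(sa), hole = hole,
               polygon_id = pid, ring_id = rid)
      }
    }
    out[[cls]] <- structure(rings, class = "contour_set", tissue = cls,
                            pose = pose)
  }
  out
}

#' Write a contour set in the polyline CSV dialect
#' @param contours a `contour_set`
#' @param path CSV file path
#' @export
write_contours <- function(contours, path) {
  rows <- do.call(rbind, lapply(contours, function(r) {
    xy <- rbind(r$xy, r$xy[1, ])  # explicit closing point
    data.frame(class = attr(contours, "tissue"), polygon_id = r$polygon_id,
               ring_id = r$ring_id, x_um = xy[, 1], y_um = xy[, 2])
  }))
  if (is.null(rows))
    rows <- data.frame(class = character(), polygon_id = integer(),
                       ring_id = integer(), x_um = numeric(), y_um = numeric())
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
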