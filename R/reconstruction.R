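## Fusing posed label maps into a 3D label volume and extracting watertight
## surfaces.

#' Label volume container
#'
#' A 3D tissue-class raster with isotropic voxels. Voxel centres sit at
#' `origin + (i - 0.5) * voxel_um` along each axis (i = 1-based index).
#'
#' @param labels 3D integer array of class codes
#' @param voxel_um isotropic voxel edge length, um (> 0)
#' @param origin length-3 block coordinates of the array corner, um
#' @return a `label_volume`
#' @export
label_volume <- function(labels, voxel_um, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, voxel_um > 0, length(origin) == 3)
  structure(list(labels = labels, voxel_um = voxel_um,
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$labels), collapse = " x "),
      "voxels at", x$voxel_um, "um\n")
  invisible(x)
}

#' Fuse posed label maps into a label volume
#'
#' Every voxel takes the class of the pixel on the nearest grinding plane
#' (along z) whose tilted surface passes within half the local inter-plane
#' gap; voxels outside coverage are resin. Nearest-plane ties break toward
#' the shallower run. This is zero-order (nearest-plane) fill: the ground
#' material between planes is gone, so no intermediate shapes are invented;
#' the cost is a bias of order gap/2 at structure caps.
#'
#' With `flat = TRUE` the per-slice tilt is ignored and each slice is
#' stacked at its mean measured height (the mean of the three caliper
#' readings) — the naive flat-stacking baseline.
#'
#' @param labelmaps list of `tissue_label_map`s (or H x W code matrices),
#'   one per run, same order as `poses`
#' @param poses a `slice_pose_stack` (or list of pose lists)
#' @param voxel_um isotropic voxel size; warned about if larger than half
#'   the median plane gap
#' @param block_size length-3 block dimensions, um
#' @param pixel_size um per pixel of the label maps
#' @param flat ignore plane tilt (flat-stacking baseline)?
#' @param z_range optional length-2 z interval (um) for the output grid;
#'   default: the covered depth range. Supplying the same `z_range` to two
#'   reconstructions puts them on identical grids for voxel-wise comparison.
#' @return a [label_volume()]
#' @export
rasterize_stack <- function(labelmaps, poses, voxel_um, block_size,
                            pixel_size, flat = FALSE, z_range = NULL) {
  if (length(labelmaps) < 2) stop("need at least 2 slices to rasterize")
  stopifnot(length(labelmaps) == length(poses))
  ord <- order(vapply(poses, function(p) p$c_um +
                        p$gx * block_size[1] / 2 + p$gy * block_size[2] / 2,
                      numeric(1)))
  poses <- poses[ord]
  labelmaps <- labelmaps[ord]
  K <- length(poses)
  if (flat) {
    anchors <- attr(poses, "anchors")
    poses <- lapply(poses, function(p) {
      zc <- if (!is.null(anchors))
        mean(p$gx * anchors[, 1] + p$gy * anchors[, 2] + p$c_um)
      else p$c_um + p$gx * block_size[1] / 2 + p$gy * block_size[2] / 2
      p$gx <- 0; p$gy <- 0; p$c_um <- zc
      p
    })
  }
  xs <- seq(voxel_um / 2, block_size[1], by = voxel_um)
  ys <- seq(voxel_um / 2, block_size[2], by = voxel_um)
  nx <- length(xs); ny <- length(ys)
  xg <- rep(xs, times = ny)  # (nx, ny) column-major
  yg <- rep(ys, each = nx)
  zk <- vapply(poses, function(p) plane_z(p, xg, yg), numeric(nx * ny))
  gaps <- diff(t(zk))  # (K-1) x (nx*ny): local inter-plane gaps
  if (K >= 2 && any(gaps <= 0)) stop("overlapping grinding planes (negative local gap)")
  med_gap <- median(gaps)
  if (voxel_um > med_gap / 2)
    warning("voxel size ", voxel_um, " um exceeds half the median plane gap (",
            round(med_gap, 1), " um)")
  if (is.null(z_range)) {
    zmin <- max(0, min(zk[, 1]) - med_gap / 2)
    zmax <- min(block_size[3], max(zk[, K]) + med_gap / 2)
  } else {
    zmin <- z_range[1]
    zmax <- z_range[2]
  }
  zs <- seq(zmin + voxel_um / 2, zmax, by = voxel_um)
  nz <- length(zs)
  nvox <- nx * ny * nz

  best_d <- rep(Inf, nvox)
  best_k <- rep(0L, nvox)
  zarr <- rep(zs, each = nx * ny)
  for (k in seq_len(K)) {
    d <- abs(zarr - rep(zk[, k], times = nz))
    upd <- d < best_d  # strict: ties keep the shallower (earlier) run
    best_d[upd] <- d[upd]
    best_k[upd] <- k
  }
  labels <- rep(tissue_code("resin"), nvox)
  half_up <- rbind(gaps[1, , drop = FALSE], gaps) / 2      # K x (nx*ny)
  half_dn <- rbind(gaps, gaps[K - 1, , drop = FALSE]) / 2
  for (k in seq_len(K)) {
    sel <- which(best_k == k)
    if (length(sel) == 0) next
    pix <- (sel - 1L) %% (nx * ny) + 1L
    dz <- zarr[sel] - rep(zk[, k], times = nz)[sel]
    ok <- (dz >= 0 & dz <= half_dn[k, pix]) | (dz < 0 & -dz <= half_up[k, pix])
    sel <- sel[ok]; pix <- pix[ok]
    if (length(sel) == 0) next
    im <- invert_pose_xy(poses[[k]], xg[pix], yg[pix])
    lm <- labelmaps[[k]]
    if (inherits(lm, "tissue_label_map")) lm <- lm$labels
    col <- ceiling(im$x / pixel_size)
    row <- ceiling(im$y / pixel_size)
    inb <- col >= 1 & col <= ncol(lm) & row >= 1 & row <= nrow(lm)
    cls <- rep(tissue_code("resin"), length(sel))
    cls[inb] <- lm[cbind(row[inb], col[inb])]
    labels[sel] <- cls
  }
  label_volume(array(labels, dim = c(nx, ny, nz)), voxel_um,
               origin = c(0, 0, zmin))
}

#' Voxelize an analytic phantom on a volume's grid
#'
#' Ground-truth label volume for voxel-wise comparison with a
#' reconstruction: evaluates the phantom classes directly at the voxel
#' centres of `vol` (no grinding, no information loss).
#'
#' @param spec a [phantom_spec()]
#' @param vol a [label_volume()] supplying grid and origin
#' @param fiducials include fiducial columns (default FALSE)
#' @return a [label_volume()] on the same grid
#' @export
voxelize_phantom <- function(spec, vol, fiducials = FALSE) {
  d <- dim(vol$labels)
  xs <- vol$origin[1] + (seq_len(d[1]) - 0.5) * vol$voxel_um
  ys <- vol$origin[2] + (seq_len(d[2]) - 0.5) * vol$voxel_um
  zs <- vol$origin[3] + (seq_len(d[3]) - 0.5) * vol$voxel_um
  xg <- rep(xs, times = d[2] * d[3])
  yg <- rep(rep(ys, each = d[1]), times = d[3])
  zg <- rep(zs, each = d[1] * d[2])
  cls <- query_classes(spec, xg, yg, zg, fiducials = fiducials)
  label_volume(array(cls, dim = d), vol$voxel_um, vol$origin)
}

#' Voxel disagreement between two label volumes
#'
#' Fraction of voxels whose class differs; fiducial voxels can be excluded
#' (the sticks are not part of the specimen).
#'
#' @param a,b `label_volume`s on the same grid
#' @param ignore_fiducial exclude voxels that are fiducial in either volume
#' @return scalar disagreement fraction in `[0, 1]`
#' @export
voxel_error <- function(a, b, ignore_fiducial = TRUE) {
  stopifnot(all(dim(a$labels) == dim(b$labels)))
  keep <- rep(TRUE, length(a$labels))
  if (ignore_fiducial) {
    fc <- tissue_code("fiducial")
    keep <- a$labels != fc & b$labels != fc
  }
  mean(a$labels[keep] != b$labels[keep])
}

#' Extract a watertight surface mesh of one tissue class
#'
#' Iso-surface (level 0.5) of the class indicator via marching tetrahedra,
#' after dropping connected components smaller than
#' `min_component_voxels`, followed by optional volume-preserving Taubin
#' smoothing. Watertightness (every edge shared by exactly two consistently
#' wound triangles) is verified and flagged; the Euler characteristic is
#' recorded.
#'
#' @param vol a [label_volume()]
#' @param class tissue class name
#' @param smoothing_iters Taubin smoothing iterations (default 10)
#' @param min_component_voxels drop specks below this voxel count (default 8)
#' @return a `surface_mesh`: list with `vertices` (n x 3 um), `triangles`
#'   (m x 3, 1-based), `class`, `watertight`, `euler_characteristic`,
#'   `n_boundary_edges`
#' @export
surface_from_volume <- function(vol, class, smoothing_iters = 10,
                                min_component_voxels = 8) {
  mask <- vol$labels == tissue_code(class)
  if (!any(mask)) stop("class '", class, "' absent from volume: empty mesh")
  d <- dim(mask)
  comp <- .label_components3d(mask, as.integer(d), 6L)
  sizes <- tabulate(comp[comp > 0L])
  keep_ids <- which(sizes >= min_component_voxels)
  if (length(keep_ids) == 0)
    stop("class '", class, "' has no component with >= ",
         min_component_voxels, " voxels")
  mask <- array(comp %in% keep_ids, dim = d)
  # pad one background voxel so the surface closes at the array border
  pd <- d + 2L
  vals <- array(0, dim = pd)
  vals[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  m <- .marching_tets(as.numeric(vals), pd, 0.5, vol$voxel_um,
                      vol$origin - vol$voxel_um)
  V <- m$vertices; T <- m$triangles
  if (smoothing_iters > 0) V <- taubin_smooth(V, T, smoothing_iters)
  finalize_mesh(V, T, class)
}

# volume-preserving Taubin lambda/mu smoothing
taubin_smooth <- function(V, T, iters, lambda = 0.5, mu = -0.53) {
  e <- rbind(T[, 1:2], T[, 2:3], T[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- e[!duplicated(e[, 1] * (nrow(V) + 1) + e[, 2]), , drop = FALSE]
  deg <- tabulate(e[, 1], nbins = nrow(V))
  step <- function(V, f) {
    nb <- rowsum(V[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
    lap <- nb / deg - V
    V + f * lap
  }
  for (i in seq_len(iters)) {
    V <- step(V, lambda)
    V <- step(V, mu)
  }
  V
}

# watertightness, consistency, Euler characteristic
finalize_mesh <- function(V, T, class = NA_character_) {
  ea <- c(T[, 1], T[, 2], T[, 3])
  eb <- c(T[, 2], T[, 3], T[, 1])
  nv <- nrow(V)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  ukey <- sort(lo * (nv + 1) + hi)
  r <- rle(ukey)
  n_bad <- sum(r$lengths != 2)
  # orientation-consistent: each undirected edge appears once per direction
  dkey <- ea * (nv + 1) + eb
  consistent <- n_bad == 0 && !anyDuplicated(dkey)
  nedge <- length(r$lengths); nf <- nrow(T)
  euler <- nv - nedge + nf
  watertight <- n_bad == 0 && consistent
  structure(list(vertices = V, triangles = T, class = class,
                 watertight = watertight,
                 euler_characteristic = euler,
                 n_boundary_edges = n_bad),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh (", x$class, "): ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, watertight: ", x$watertight,
      ", Euler characteristic ", x$euler_characteristic, "\n", sep = "")
  invisible(x)
}
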