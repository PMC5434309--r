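## Synthetic specimen ("phantom") definitions.
##
## Coordinate convention (used everywhere in the package): right-handed,
## units micrometres, z is depth ground away (z = 0 is the first-run block
## surface, z increases downward into the block). Origin of x/y at the block
## corner; images use row-major pixel grids with pixel centres at
## (i + 0.5) * pixel_size.

#' Construct an analytic solid for a phantom
#'
#' Solids are simple analytic primitives carrying a tissue class. Supported
#' shapes: `"sphere"` (center, r), `"ellipsoid"` (center, semiaxes, optional
#' 3x3 rotation), `"cylinder"` (p1, p2, r; flat caps) and `"capsule"`
#' (p1, p2, r; hemispherical caps). All lengths in micrometres.
#'
#' @param class tissue class name (see [tissue_classes()])
#' @param shape one of "sphere", "ellipsoid", "cylinder", "capsule"
#' @param ... shape parameters (`center`, `r`, `semiaxes`, `rotation`,
#'   `p1`, `p2`)
#' @return a `phantom_solid` object
#' @export
phantom_solid <- function(class, shape, ...) {
  shape <- match.arg(shape, c("sphere", "ellipsoid", "cylinder", "capsule"))
  stopifnot(class %in% tissue_classes())
  p <- list(...)
  s <- c(list(class = class, shape = shape), p)
  if (shape == "sphere") stopifnot(length(s$center) == 3, s$r > 0)
  if (shape == "ellipsoid") {
    stopifnot(length(s$center) == 3, length(s$semiaxes) == 3, all(s$semiaxes > 0))
    if (is.null(s$rotation)) s$rotation <- diag(3)
  }
  if (shape %in% c("cylinder", "capsule"))
    stopifnot(length(s$p1) == 3, length(s$p2) == 3, s$r > 0)
  structure(s, class = "phantom_solid")
}

# vectorized inside test; x, y, z equal-length numeric vectors
solid_inside <- function(solid, x, y, z) {
  switch(solid$shape,
    sphere = {
      c0 <- solid$center
      (x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 <= solid$r^2
    },
    ellipsoid = {
      c0 <- solid$center
      R <- solid$rotation
      dx <- x - c0[1]; dy <- y - c0[2]; dz <- z - c0[3]
      u <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
      v <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
      w <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
      a <- solid$semiaxes
      (u / a[1])^2 + (v / a[2])^2 + (w / a[3])^2 <= 1
    },
    cylinder = ,
    capsule = {
      p1 <- solid$p1; p2 <- solid$p2
      ax <- p2 - p1
      L2 <- sum(ax^2)
      dx <- x - p1[1]; dy <- y - p1[2]; dz <- z - p1[3]
      t <- (dx * ax[1] + dy * ax[2] + dz * ax[3]) / L2
      tc <- if (solid$shape == "capsule") pmin(pmax(t, 0), 1) else t
      qx <- dx - tc * ax[1]; qy <- dy - tc * ax[2]; qz <- dz - tc * ax[3]
      d2 <- qx^2 + qy^2 + qz^2
      if (solid$shape == "cylinder") d2 <= solid$r^2 & t >= 0 & t <= 1
      else d2 <= solid$r^2
    }
  )
}

#' Create a phantom specification
#'
#' A `phantom_spec` bundles the analytic solids of a synthetic specimen, the
#' resin block dimensions and the three vertical fiducial columns (wooden
#' reference sticks). Fiducial columns must be mutually non-collinear and all
#' solids must lie inside the block.
#'
#' @param solids list of [phantom_solid()] objects
#' @param block_size 3-vector, block extent in micrometres (x, y, depth)
#' @param fiducial_columns 3x2 matrix of x/y anchor points (um) of the
#'   vertical fiducial columns, rows labelled A, B, C
#' @param fiducial_radius column radius in micrometres
#' @param seed integer seed recorded with the spec
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(solids, block_size, fiducial_columns,
                         fiducial_radius = 40, seed = 0L) {
  stopifnot(length(block_size) == 3, all(block_size > 0))
  fm <- as.matrix(fiducial_columns)
  stopifnot(nrow(fm) == 3, ncol(fm) == 2)
  rownames(fm) <- c("A", "B", "C")
  # non-collinearity: triangle area strictly positive
  area2 <- abs((fm[2, 1] - fm[1, 1]) * (fm[3, 2] - fm[1, 2]) -
               (fm[3, 1] - fm[1, 1]) * (fm[2, 2] - fm[1, 2]))
  if (area2 <= 1e-9) stop("fiducial columns are collinear")
  for (s in solids) {
    bb <- solid_bbox(s)
    if (any(bb[1, ] < 0) || any(bb[2, ] > block_size))
      stop("solid of class '", s$class, "' extends outside the block")
    # a stick drilled through the specimen would displace tissue
    zs <- seq(0, block_size[3], length.out = 60)
    for (i in 1:3) {
      for (off in list(c(0, 0), c(fiducial_radius, 0), c(-fiducial_radius, 0),
                       c(0, fiducial_radius), c(0, -fiducial_radius))) {
        if (any(solid_inside(s, rep(fm[i, 1] + off[1], length(zs)),
                             rep(fm[i, 2] + off[2], length(zs)), zs))) {
          warning("fiducial column ", c("A", "B", "C")[i],
                  " intersects a ", s$class, " solid")
          break
        }
      }
    }
  }
  structure(list(solids = solids, block_size = as.numeric(block_size),
                 fiducial_columns = fm, fiducial_radius = fiducial_radius,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

solid_bbox <- function(s) {
  switch(s$shape,
    sphere = rbind(s$center - s$r, s$center + s$r),
    ellipsoid = {
      e <- sqrt(rowSums((s$rotation %*% diag(s$semiaxes))^2))
      rbind(s$center - e, s$center + e)
    },
    cylinder = ,
    capsule = rbind(pmin(s$p1, s$p2) - s$r, pmax(s$p1, s$p2) + s$r)
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", length(x$solids), "solids, block",
      paste(round(x$block_size), collapse = " x "), "um\n")
  for (s in x$solids)
    cat("  -", s$class, s$shape, "\n")
  invisible(x)
}

#' Query tissue classes at 3D points
#'
#' Evaluates the analytic phantom at arbitrary points. Overlapping solids are
#' resolved by the documented precedence vessel > cartilage > bone >
#' soft_tissue, so internal channels are never occluded by their host bone.
#' Points inside a fiducial column (any depth) are class `fiducial`;
#' everything else is `resin`.
#'
#' @param spec a [phantom_spec()]
#' @param x,y,z equal-length coordinate vectors (um)
#' @param fiducials include the fiducial columns (default TRUE)
#' @return integer vector of class codes
#' @export
query_classes <- function(spec, x, y, z, fiducials = TRUE) {
  out <- rep.int(tissue_code("resin"), length(x))
  for (cls in .class_precedence) {
    for (s in spec$solids) {
      if (s$class != cls) next
      out[solid_inside(s, x, y, z)] <- tissue_code(cls)
    }
  }
  if (fiducials) {
    fm <- spec$fiducial_columns
    r2 <- spec$fiducial_radius^2
    for (i in 1:3) {
      hit <- (x - fm[i, 1])^2 + (y - fm[i, 2])^2 <= r2
      out[hit] <- tissue_code("fiducial")
    }
  }
  out
}

#' Ground-truth class volumes by dense voxelization
#'
#' Oracle volumes of every tissue class, computed by evaluating the analytic
#' phantom on a dense voxel grid (default 2 um voxels, evaluated in z-slabs
#' to bound memory). Overlaps are resolved by the same precedence as
#' [query_classes()]. The voxel count used is attached as an attribute.
#'
#' @param spec a [phantom_spec()]
#' @param oracle_voxel_um oracle voxel edge length, um (default 2)
#' @param fiducials count fiducial columns as a class (default FALSE: the
#'   sticks are not part of the specimen)
#' @return named numeric vector of volumes (um^3) per class, with attribute
#'   `n_voxels`
#' @export
analytic_class_volumes <- function(spec, oracle_voxel_um = 2,
                                   fiducials = FALSE) {
  h <- oracle_voxel_um
  bs <- spec$block_size
  cl <- tissue_classes()
  counts <- setNames(numeric(length(cl)), cl)
  if (length(spec$solids) == 0) {
    vols <- counts
    attr(vols, "n_voxels") <- 0
    return(vols)
  }
  # restrict the grid to the union bounding box of the solids
  bb <- sapply(spec$solids, solid_bbox, simplify = "array")
  lo <- pmax(apply(bb[1, , , drop = FALSE], 2, min), 0)
  hi <- pmin(apply(bb[2, , , drop = FALSE], 2, max), bs)
  xs <- seq(lo[1] + h / 2, hi[1], by = h)
  ys <- seq(lo[2] + h / 2, hi[2], by = h)
  zs <- seq(lo[3] + h / 2, hi[3], by = h)
  nxy <- length(xs) * length(ys)
  slab <- max(1L, floor(4e6 / nxy))
  xg <- rep(xs, times = length(ys))
  yg <- rep(ys, each = length(xs))
  i <- 1L
  while (i <= length(zs)) {
    j <- min(i + slab - 1L, length(zs))
    zsl <- zs[i:j]
    n <- nxy * length(zsl)
    xa <- rep(xg, times = length(zsl))
    ya <- rep(yg, times = length(zsl))
    za <- rep(zsl, each = nxy)
    cls <- query_classes(spec, xa, ya, za, fiducials = fiducials)
    tb <- tabulate(cls + 1L, nbins = length(cl))
    counts <- counts + tb
    i <- j + 1L
  }
  vols <- counts * h^3
  vols["resin"] <- 0  # background is unbounded; not a specimen volume
  attr(vols, "n_voxels") <- sum(counts)
  attr(vols, "oracle_voxel_um") <- h
  vols
}
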