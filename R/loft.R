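## Direct contour-to-surface lofting: stitch matched closed contours on
## successive (possibly tilted) planes into a watertight mesh. This mirrors
## the CAD freeform-surface operation; the rasterize -> iso-surface path is
## the robust primary route and also serves as the fallback here.

ring_centroid <- function(xy) colMeans(xy)

# resample closed ring (n x 2 or n x 3, not closed) to N points by arc length
resample_ring <- function(xy, N) {
  n <- nrow(xy)
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-(n + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1]
  at <- seq(0, total, length.out = N + 1)[seq_len(N)]
  out <- matrix(NA_real_, N, ncol(xy))
  for (j in seq_len(ncol(xy)))
    out[, j] <- stats::approx(cum, closed[, j], xout = at)$y
  out
}

# best cyclic offset aligning two equally sampled rings
best_offset <- function(P, Q) {
  N <- nrow(P)
  costs <- vapply(0:(N - 1), function(o) {
    idx <- ((seq_len(N) - 1 + o) %% N) + 1
    sum((P - Q[idx, , drop = FALSE])^2)
  }, numeric(1))
  which.min(costs) - 1L
}

# ear-clipping triangulation of a simple CCW polygon; returns m x 3 indices
ear_clip <- function(xy) {
  n <- nrow(xy)
  if (signed_ring_area(xy) < 0) stop("ear_clip expects a CCW ring")
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  while (length(idx) > 3) {
    m <- length(idx)
    clipped <- FALSE
    # strict pass: proper convex ears; relaxed pass additionally accepts
    # zero-area ears (collinear leftovers) which are volume-neutral but
    # keep the cap combinatorially closed
    for (strict in c(TRUE, FALSE)) {
      for (i in seq_len(m)) {
        ip <- idx[if (i == 1) m else i - 1]
        ic <- idx[i]
        inx <- idx[if (i == m) 1 else i + 1]
        a <- xy[ip, ]; b <- xy[ic, ]; c <- xy[inx, ]
        cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
        if ((strict && cross <= 0) || (!strict && cross < 0)) next  # reflex
        others <- setdiff(idx, c(ip, ic, inx))
        if (length(others) > 0 &&
            any(point_in_triangle(xy[others, 1], xy[others, 2], a, b, c)))
          next
        tris <- rbind(tris, c(ip, ic, inx))
        idx <- idx[-i]
        clipped <- TRUE
        break
      }
      if (clipped) break
    }
    if (!clipped) stop("ear clipping failed (degenerate ring)")
  }
  rbind(tris, idx)
}

point_in_triangle <- function(px, py, a, b, c) {
  s1 <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  s2 <- (c[1] - b[1]) * (py - b[2]) - (c[2] - b[2]) * (px - b[1])
  s3 <- (a[1] - c[1]) * (py - c[2]) - (a[2] - c[2]) * (px - c[1])
  (s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0)
}

# make triangle winding consistent across each connected component, then fix
# the global sign so enclosed volume is positive
orient_mesh <- function(V, T) {
  nt <- nrow(T)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(T[, 1], T[, 2], seq_len(nt)),
                 cbind(T[, 2], T[, 3], seq_len(nt)),
                 cbind(T[, 3], T[, 1], seq_len(nt)))
  keys <- ekey(edges[, 1], edges[, 2])
  inc <- split(seq_len(nrow(edges)), keys)
  visited <- rep(FALSE, nt)
  for (start in seq_len(nt)) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    while (length(queue) > 0) {
      t0 <- queue[1]; queue <- queue[-1]
      t0edges <- rbind(T[t0, 1:2], T[t0, 2:3], T[t0, c(3, 1)])
      for (r in 1:3) {
        k <- ekey(t0edges[r, 1], t0edges[r, 2])
        for (ei in inc[[k]]) {
          tn <- edges[ei, 3]
          if (tn == t0 || visited[tn]) next
          # neighbour consistent iff it holds the shared edge reversed
          tne <- rbind(T[tn, 1:2], T[tn, 2:3], T[tn, c(3, 1)])
          same_dir <- any(tne[, 1] == t0edges[r, 1] & tne[, 2] == t0edges[r, 2])
          if (same_dir) T[tn, ] <- T[tn, c(1, 3, 2)]
          visited[tn] <- TRUE
          queue <- c(queue, tn)
        }
      }
    }
  }
  v1 <- V[T[, 1], , drop = FALSE]
  v2 <- V[T[, 2], , drop = FALSE]
  v3 <- V[T[, 3], , drop = FALSE]
  vol6 <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
              v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
              v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]))
  if (vol6 < 0) T <- T[, c(1, 3, 2)]
  T
}

#' Loft a surface through stacked contours
#'
#' Direct contour-to-surface path: outer contours of one class on
#' successive planes are matched (centroid distance gated by the rings'
#' equivalent radii), matched rings are resampled, cyclically aligned and
#' stitched with triangle strips, and unmatched chain ends are capped
#' (structure start/end). Detected branchings (a ring in one slice facing
#' two nearby rings in the next), or a stitch that fails validation, fall
#' back to contour rasterization plus [surface_from_volume()] with a
#' message. Ring holes are ignored in the stitched path (and honoured in
#' the fallback).
#'
#' @param contour_stacks list of `contour_set`s, one per slice (same class),
#'   each carrying its slice pose
#' @param n_profile resampling points per ring (default 64)
#' @param fallback_voxel_um voxel size of the fallback rasterization
#'   (default: a third of the median plane gap)
#' @return a `surface_mesh`
#' @export
loft_contours <- function(contour_stacks, n_profile = 64,
                          fallback_voxel_um = NULL) {
  cls <- attr(contour_stacks[[1]], "tissue")
  slices <- lapply(contour_stacks, function(cs)
    Filter(function(r) !r$hole, unclass(cs)))
  poses <- lapply(contour_stacks, attr, "pose")
  nonempty <- which(vapply(slices, length, 1L) > 0)
  if (length(nonempty) < 2)
    stop("lofting needs >= 2 slices with at least one ring of class '",
         cls, "'")

  # ---- match rings between consecutive non-empty slices --------------------
  ring_at <- function(s, i) {
    r <- slices[[s]][[i]]
    z <- plane_z(poses[[s]], r$xy[, 1], r$xy[, 2])
    cbind(r$xy, z)
  }
  matches <- list()   # per consecutive pair: 2-col matrix of ring indices
  branching <- FALSE
  for (p in seq_len(length(nonempty) - 1)) {
    s1 <- nonempty[p]; s2 <- nonempty[p + 1]
    r1 <- slices[[s1]]; r2 <- slices[[s2]]
    c1 <- t(vapply(r1, function(r) ring_centroid(r$xy), numeric(2)))
    c2 <- t(vapply(r2, function(r) ring_centroid(r$xy), numeric(2)))
    rad1 <- sqrt(vapply(r1, `[[`, numeric(1), "area_um2") / pi)
    rad2 <- sqrt(vapply(r2, `[[`, numeric(1), "area_um2") / pi)
    cost <- outer(seq_along(r1), seq_along(r2), Vectorize(function(i, j)
      sqrt(sum((c1[i, ] - c2[j, ])^2))))
    gate <- outer(rad1, rad2, "+")
    pairs <- which(cost <= gate, arr.ind = TRUE)
    pairs <- pairs[order(cost[pairs]), , drop = FALSE]
    used1 <- logical(length(r1)); used2 <- logical(length(r2))
    mm <- matrix(0L, 0, 2)
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      if (used1[i] || used2[j]) {
        branching <- TRUE  # a ring faces two nearby partners: merge/split
        next
      }
      used1[i] <- TRUE; used2[j] <- TRUE
      mm <- rbind(mm, c(i, j))
    }
    matches[[p]] <- mm
  }
  if (branching) {
    message("branching contours detected; falling back to rasterized iso-surface")
    return(loft_fallback(contour_stacks, cls, fallback_voxel_um))
  }

  # ---- build chains --------------------------------------------------------
  chains <- list()   # each: list of (slice, ring) pairs
  open_chain <- list()  # keyed by "slice:ring" of chain tail
  for (p in seq_along(nonempty)) {
    s <- nonempty[p]
    for (i in seq_along(slices[[s]])) {
      key <- paste(s, i)
      if (is.null(open_chain[[key]])) {
        chains[[length(chains) + 1]] <- list(c(s, i))
        open_chain[[key]] <- length(chains)
      }
    }
    if (p < length(nonempty)) {
      mm <- matches[[p]]
      s2 <- nonempty[p + 1]
      for (q in seq_len(nrow(mm))) {
        ci <- open_chain[[paste(s, mm[q, 1])]]
        chains[[ci]] <- c(chains[[ci]], list(c(s2, mm[q, 2])))
        open_chain[[paste(s2, mm[q, 2])]] <- ci
      }
    }
  }
  chains <- Filter(function(ch) length(ch) >= 2, chains)
  if (length(chains) == 0)
    stop("no contour chain spans >= 2 slices for class '", cls, "'")

  # ---- stitch each chain ---------------------------------------------------
  V <- matrix(0, 0, 3)
  T <- matrix(0L, 0, 3)
  for (ch in chains) {
    profs <- vector("list", length(ch))
    for (q in seq_along(ch)) {
      rr <- ring_at(ch[[q]][1], ch[[q]][2])
      P <- resample_ring(rr, n_profile)
      if (q > 1) {
        o <- best_offset(profs[[q - 1]], P)
        idx <- ((seq_len(n_profile) - 1 + o) %% n_profile) + 1
        P <- P[idx, , drop = FALSE]
      }
      profs[[q]] <- P
    }
    base <- nrow(V)
    V <- rbind(V, do.call(rbind, profs))
    idx_of <- function(q, i) base + (q - 1L) * n_profile + i
    N <- n_profile
    for (q in seq_len(length(ch) - 1)) {
      i <- seq_len(N); j <- c(2:N, 1)
      T <- rbind(T,
                 cbind(idx_of(q, i), idx_of(q, j), idx_of(q + 1, j)),
                 cbind(idx_of(q, i), idx_of(q + 1, j), idx_of(q + 1, i)))
    }
    # caps on both chain ends
    for (endq in c(1L, length(ch))) {
      ring2d <- profs[[endq]][, 1:2, drop = FALSE]
      flipped <- FALSE
      if (signed_ring_area(ring2d) < 0) {
        ring2d <- ring2d[rev(seq_len(N)), , drop = FALSE]
        flipped <- TRUE
      }
      ct <- ear_clip(ring2d)
      map <- if (flipped) rev(seq_len(N)) else seq_len(N)
      T <- rbind(T, matrix(idx_of(endq, map[ct]), ncol = 3))
    }
  }
  T <- orient_mesh(V, T)
  mesh <- finalize_mesh(V, T, cls)
  if (!mesh$watertight) {
    message("lofted mesh failed watertightness validation; ",
            "falling back to rasterized iso-surface")
    return(loft_fallback(contour_stacks, cls, fallback_voxel_um))
  }
  mesh
}

# rasterize the contour stack onto a block-aligned grid, then iso-surface
loft_fallback <- function(contour_stacks, cls, voxel_um = NULL) {
  poses <- lapply(contour_stacks, attr, "pose")
  zmid <- vapply(seq_along(poses), function(s) {
    rs <- unclass(contour_stacks[[s]])
    if (length(rs) == 0) return(NA_real_)
    ctr <- colMeans(do.call(rbind, lapply(rs, function(r) r$xy)))
    plane_z(poses[[s]], ctr[1], ctr[2])
  }, numeric(1))
  gaps <- diff(vapply(poses, function(p) p$c_um, numeric(1)))
  if (is.null(voxel_um))
    voxel_um <- max(stats::median(abs(gaps)) / 3, 1)
  allxy <- do.call(rbind, lapply(contour_stacks, function(cs)
    do.call(rbind, lapply(unclass(cs), function(r) r$xy))))
  pad <- 2 * voxel_um
  xr <- range(allxy[, 1]) + c(-pad, pad)
  yr <- range(allxy[, 2]) + c(-pad, pad)
  code <- tissue_code(cls)
  # binary label map per slice on the block-aligned grid
  xs <- seq(xr[1] + voxel_um / 2, xr[2], by = voxel_um)
  ys <- seq(yr[1] + voxel_um / 2, yr[2], by = voxel_um)
  xg <- rep(xs, times = length(ys))
  yg <- rep(ys, each = length(xs))
  lms <- lapply(seq_along(contour_stacks), function(s) {
    m <- rep(FALSE, length(xg))
    for (r in unclass(contour_stacks[[s]])) {
      inside <- point_in_ring(xg - xr[1], yg - yr[1],
                              cbind(r$xy[, 1] - xr[1], r$xy[, 2] - yr[1]))
      if (r$hole) m <- m & !inside else m <- m | inside
    }
    matrix(ifelse(m, code, tissue_code("resin")),
           nrow = length(ys), ncol = length(xs), byrow = TRUE)
  })
  # identity in-plane pose on the shifted grid, planes from the slice poses
  id_poses <- lapply(seq_along(poses), function(s) {
    p <- poses[[s]]
    list(run = s, angle_deg = 0, tx_um = 0, ty_um = 0, scale = 1,
         gx = p$gx, gy = p$gy,
         c_um = p$c_um + p$gx * xr[1] + p$gy * yr[1])
  })
  bs <- c(xr[2] - xr[1], yr[2] - yr[1],
          max(vapply(id_poses, function(p) p$c_um, numeric(1))) + 10 * voxel_um)
  vol <- rasterize_stack(lms, id_poses, voxel_um, bs, voxel_um)
  vol$origin <- vol$origin + c(xr[1], yr[1], 0)
  surface_from_volume(vol, cls, smoothing_iters = 5)
}
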