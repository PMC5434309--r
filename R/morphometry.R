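## Quantification of reconstructed structures: tetrahedral mesh volumes,
## not-calcified fractions, channel diameters, wall thickness and the
## diffusion-limit screen.

#' Tetrahedral mesh volume
#'
#' Volume enclosed by a watertight, consistently oriented triangle mesh:
#' each triangle forms a tetrahedron with the origin and the signed
#' tetrahedron volumes are summed. The signed sum is translation invariant,
#' so the choice of origin does not matter; the absolute value is returned.
#'
#' @param mesh a `surface_mesh`
#' @return volume in um^3
#' @export
mesh_volume_tetra <- function(mesh) {
  chk <- finalize_mesh(mesh$vertices, mesh$triangles)
  if (!chk$watertight)
    stop("mesh is not watertight (", chk$n_boundary_edges,
         " defective edges); cannot compute a tetrahedral volume")
  V <- mesh$vertices; T <- mesh$triangles
  v1 <- V[T[, 1], , drop = FALSE]
  v2 <- V[T[, 2], , drop = FALSE]
  v3 <- V[T[, 3], , drop = FALSE]
  vol6 <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
              v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
              v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]))
  abs(vol6) / 6
}

#' Voxel-count class volumes of a label volume
#'
#' @param vol a [label_volume()]
#' @return named numeric vector, um^3 per class
#' @export
class_voxel_volumes <- function(vol) {
  cl <- tissue_classes()
  counts <- tabulate(vol$labels + 1L, nbins = length(cl))
  setNames(counts * vol$voxel_um^3, cl)
}

#' Class volumes interior to a structure's outer surface
#'
#' Finds the voxels enclosed by the given structural class (flood fill from
#' the volume border over non-structure voxels; whatever is not reached is
#' interior) and returns per-class volumes of the structure plus its
#' interior. This is the denominator set used for the not-calcified
#' fraction: internal vessels, cartilage and soft tissue count; the mucosal
#' layer outside the bone surface does not.
#'
#' @param vol a [label_volume()]
#' @param structure_class outer-surface class (default "bone")
#' @return named numeric vector of volumes (um^3) over
#'   structure + enclosed classes
#' @export
interior_class_volumes <- function(vol, structure_class = "bone") {
  sc <- tissue_code(structure_class)
  d <- dim(vol$labels)
  open <- vol$labels != sc
  comp <- .label_components3d(open, as.integer(d), 6L)
  border_ids <- unique(c(comp[1, , ], comp[d[1], , ], comp[, 1, ],
                         comp[, d[2], ], comp[, , 1], comp[, , d[3]]))
  border_ids <- border_ids[border_ids > 0]
  enclosed <- open & !(array(comp %in% border_ids, dim = d))
  cl <- tissue_classes()
  counts <- setNames(numeric(length(cl)), cl)
  inside_labels <- vol$labels[enclosed | !open]
  tb <- tabulate(inside_labels + 1L, nbins = length(cl))
  counts[] <- tb
  counts * vol$voxel_um^3
}

#' Not-calcified fraction
#'
#' Percentage of a structure's interior occupied by vessels, cartilage and
#' internal soft tissue rather than mineralized bone:
#' `100 * (vessel + cartilage + soft) / (bone + vessel + cartilage + soft)`.
#' Volumes must already be restricted to the structure's interior (see
#' [interior_class_volumes()]). Missing classes count as zero.
#'
#' @param volumes named numeric vector of class volumes (um^3)
#' @return percentage in `[0, 100]`
#' @export
not_calcified_fraction <- function(volumes) {
  gv <- function(n) if (n %in% names(volumes)) volumes[[n]] else 0
  bone <- gv("bone")
  if (bone <= 0) stop("bone volume must be positive")
  nc <- gv("vessel") + gv("cartilage") + gv("soft_tissue")
  100 * nc / (bone + nc)
}

# Euclidean distance (um) of every foreground voxel to the nearest
# background voxel centre; the array border counts as background.
edt_um <- function(mask, voxel_um) {
  d <- dim(mask)
  pd <- d + 2L
  padded <- array(FALSE, dim = pd)
  padded[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  sq <- .edt3d_sq(padded, as.integer(pd))
  sqrt(sq[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])]) * voxel_um
}

#' Channel diameter distribution
#'
#' Skeleton-based diameter estimate of a tubular class (vessels): the
#' medial axis is taken as the ridge of the Euclidean distance transform
#' (voxels whose distance is not exceeded in their 26-neighbourhood) and
#' the local diameter at each skeleton voxel is twice its distance
#' transform value. Per-component (branch) summaries are included.
#'
#' @param vol a [label_volume()]
#' @param class tubular class name (default "vessel")
#' @return a list with `diameters_um` (all skeleton samples), `summary`
#'   (min/quartiles/median/max), and `per_branch` (data.frame); empty
#'   distribution if the class is absent
#' @export
channel_diameters <- function(vol, class = "vessel") {
  mask <- vol$labels == tissue_code(class)
  if (!any(mask))
    return(list(diameters_um = numeric(0),
                summary = c(min = NA, q25 = NA, median = NA, q75 = NA,
                            max = NA),
                per_branch = data.frame(branch = integer(),
                                        median_diameter_um = numeric(),
                                        n = integer())))
  ed <- edt_um(mask, vol$voxel_um)
  skel <- distance_ridge(ed, mask)
  comp <- .label_components3d(mask, as.integer(dim(mask)), 26L)
  dia <- 2 * ed[skel]
  br <- comp[skel]
  per_branch <- do.call(rbind, lapply(sort(unique(br)), function(b)
    data.frame(branch = b, median_diameter_um = median(dia[br == b]),
               n = sum(br == b))))
  list(diameters_um = dia,
       summary = c(min = min(dia),
                   q25 = unname(quantile(dia, 0.25)),
                   median = median(dia),
                   q75 = unname(quantile(dia, 0.75)),
                   max = max(dia)),
       per_branch = per_branch)
}

# ridge of the distance transform: foreground voxels whose EDT is >= every
# 26-neighbour (small tolerance keeps plateau ridges connected)
distance_ridge <- function(ed, mask, tol = 1e-6) {
  d <- dim(ed)
  pad <- array(-Inf, dim = d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- ed
  nbmax <- array(-Inf, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- pad[1 + dx + seq_len(d[1]), 1 + dy + seq_len(d[2]),
              1 + dz + seq_len(d[3])]
    nbmax <- pmax(nbmax, sh)
  }
  mask & (ed >= nbmax - tol)
}

#' Wall thickness and diffusion-limit screen
#'
#' Local thickness (largest inscribed sphere diameter containing each
#' voxel, computed by sphere-painting from the distance ridge) over a
#' class, plus the diffusion screen: a voxel is flagged when its distance
#' to the nearest non-class voxel exceeds `diffusion_limit_um`, i.e. no
#' surface (and hence no mucosal blood supply) is within reach. Distances
#' to the surface use the half-voxel boundary convention (the class
#' boundary lies halfway between foreground and background voxel centres).
#' The structure is "fully diffusion-supplied" when no voxel is flagged.
#'
#' @param vol a [label_volume()]
#' @param class class name (default "bone")
#' @param diffusion_limit_um diffusion distance limit (default 150, the
#'   literature value for lamellar bone)
#' @return list with `thickness_um` summary (min/quartiles/max of local
#'   thickness), `flagged_fraction_pct`, `fully_supplied`,
#'   `diffusion_limit_um`
#' @export
wall_thickness <- function(vol, class = "bone", diffusion_limit_um = 150) {
  mask <- vol$labels == tissue_code(class)
  if (!any(mask)) stop("class '", class, "' absent from volume")
  ed <- edt_um(mask, vol$voxel_um)
  surf_dist <- pmax(ed - 0.5 * vol$voxel_um, 0)
  lt <- local_thickness(ed, mask, vol$voxel_um)
  th <- lt[mask]
  flagged <- mean(surf_dist[mask] > diffusion_limit_um)
  list(thickness_um = c(min = min(th),
                        q25 = unname(quantile(th, 0.25)),
                        median = median(th),
                        q75 = unname(quantile(th, 0.75)),
                        max = max(th)),
       flagged_fraction_pct = 100 * flagged,
       fully_supplied = flagged == 0,
       diffusion_limit_um = diffusion_limit_um)
}

# medial voxels for local thickness: a voxel is redundant when some
# neighbour's inscribed sphere contains its own (ed[n] >= ed[s] + |n - s|,
# with half-voxel slack for grid misalignment)
medial_voxels <- function(ed, mask, voxel_um) {
  d <- dim(ed)
  pad <- array(-Inf, dim = d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- ed
  contained <- array(FALSE, dim = d)
  slack <- 0.5 * voxel_um
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    step <- sqrt(dx^2 + dy^2 + dz^2) * voxel_um
    sh <- pad[1 + dx + seq_len(d[1]), 1 + dy + seq_len(d[2]),
              1 + dz + seq_len(d[3])]
    contained <- contained | (sh >= ed + step - slack)
  }
  mask & !contained
}

# local thickness by painting inscribed spheres from the medial voxels,
# largest radius first; voxels no sphere reaches keep the 2*EDT lower bound
local_thickness <- function(ed, mask, voxel_um) {
  d <- dim(ed)
  ridge <- which(medial_voxels(ed, mask, voxel_um))
  ridge <- ridge[order(ed[ridge], decreasing = TRUE)]
  lt <- array(0, dim = d)
  nxy <- d[1] * d[2]
  for (s in ridge) {
    r_um <- ed[s]
    dia <- 2 * r_um
    if (dia <= lt[s]) next  # already covered by a bigger sphere
    rv <- r_um / voxel_um
    cz <- (s - 1) %/% nxy + 1
    rem <- (s - 1) %% nxy
    cy <- rem %/% d[1] + 1
    cx <- rem %% d[1] + 1
    rr <- floor(rv)
    xs <- max(1, cx - rr):min(d[1], cx + rr)
    ys <- max(1, cy - rr):min(d[2], cy + rr)
    zs <- max(1, cz - rr):min(d[3], cz + rr)
    dx2 <- (xs - cx)^2
    dy2 <- (ys - cy)^2
    dz2 <- (zs - cz)^2
    cube <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside <- cube <= rv^2
    sub <- lt[xs, ys, zs, drop = FALSE]
    sub[inside & sub < dia] <- dia
    lt[xs, ys, zs] <- sub
  }
  lt[mask] <- pmax(lt[mask], 2 * ed[mask])
  lt
}

#' Build a morphometry report
#'
#' Summarizes one reconstructed structure: per-class volumes (voxel-count
#' and, when meshes are supplied, mesh-tetrahedra), not-calcified fraction,
#' channel diameters, wall thickness and the diffusion screen. Volumes are
#' printed in um^3 and mm^3 side by side: at ossicle scale the two differ
#' by nine orders of magnitude, and keeping both units visible prevents a
#' unit mix-up from propagating silently.
#'
#' @param vol a [label_volume()] of the structure
#' @param structure_name name used in reports
#' @param meshes optional named list of `surface_mesh`es per class for
#'   mesh-tetrahedra volumes
#' @param structure_class outer-surface class (default "bone")
#' @param diffusion_limit_um diffusion screen limit (default 150)
#' @return a `morphometry_report`
#' @export
morphometry_report <- function(vol, structure_name = "specimen",
                               meshes = NULL, structure_class = "bone",
                               diffusion_limit_um = 150) {
  vox <- class_voxel_volumes(vol)
  interior <- interior_class_volumes(vol, structure_class)
  ncf <- if (structure_class == "bone" && interior["bone"] > 0)
    not_calcified_fraction(interior) else NA_real_
  mesh_vols <- if (!is.null(meshes))
    vapply(meshes, mesh_volume_tetra, numeric(1)) else NULL
  dia <- channel_diameters(vol, "vessel")
  wt <- if (any(vol$labels == tissue_code(structure_class)))
    wall_thickness(vol, structure_class, diffusion_limit_um) else NULL
  structure(list(
    structure = structure_name,
    voxel_um = vol$voxel_um,
    volumes_um3 = list(voxel_count = as.list(vox),
                       mesh_tetra = as.list(mesh_vols),
                       interior = as.list(interior)),
    not_calcified_pct = ncf,
    vessel_diameters_um = dia$summary,
    vessel_diameters_per_branch = dia$per_branch,
    wall = wt),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("Morphometry of '", x$structure, "' (voxel ", x$voxel_um, " um)\n",
      sep = "")
  vv <- unlist(x$volumes_um3$voxel_count)
  vv <- vv[vv > 0 & names(vv) != "resin"]
  for (n in names(vv))
    cat(sprintf("  %-12s %12.4g um^3  (%.6g mm^3)\n", n, vv[n], vv[n] / 1e9))
  if (is.finite(x$not_calcified_pct))
    cat(sprintf("  not calcified: %.3f %%\n", x$not_calcified_pct))
  if (!is.null(x$vessel_diameters_um) &&
      is.finite(x$vessel_diameters_um["median"]))
    cat(sprintf("  vessel diameter (um): min %.1f / median %.1f / max %.1f\n",
                x$vessel_diameters_um["min"], x$vessel_diameters_um["median"],
                x$vessel_diameters_um["max"]))
  if (!is.null(x$wall))
    cat(sprintf(
      "  wall thickness median %.1f um; >%g um core: %.2f %%%s\n",
      x$wall$thickness_um["median"], x$wall$diffusion_limit_um,
      x$wall$flagged_fraction_pct,
      if (x$wall$fully_supplied) " (fully diffusion-supplied)" else ""))
  invisible(x)
}

#' Compare two morphometry reports (e.g. histology vs micro-CT)
#'
#' Per-class absolute and relative volume differences between two reports
#' covering the same structure, mirroring a histology-versus-micro-CT
#' comparison. Classes absent from both are dropped; disjoint reports are
#' an error.
#'
#' @param report_A,report_B `morphometry_report`s
#' @return data.frame with class, volumes, absolute and relative difference
#' @export
compare_modalities <- function(report_A, report_B) {
  va <- unlist(report_A$volumes_um3$voxel_count)
  vb <- unlist(report_B$volumes_um3$voxel_count)
  shared <- intersect(names(va)[va > 0], names(vb)[vb > 0])
  shared <- setdiff(shared, "resin")
  if (length(shared) == 0)
    stop("reports have no shared structure classes to compare")
  data.frame(class = shared,
             volume_A_um3 = va[shared],
             volume_B_um3 = vb[shared],
             abs_diff_um3 = abs(va[shared] - vb[shared]),
             rel_diff_pct = 100 * abs(va[shared] - vb[shared]) /
               pmax(va[shared], vb[shared]),
             row.names = NULL)
}
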