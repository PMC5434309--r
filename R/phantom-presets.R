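## Built-in phantom presets. Each emulates a feature of real ossicle anatomy
## relevant to the pipeline: internal vascular channels, cartilage
## inclusions, thin-walled arches.

default_fiducial_columns <- function(block_size) {
  bx <- block_size[1]; by <- block_size[2]
  # three corners: far from any centred specimen so the sticks never pierce
  # it, and with well-separated x ranks so the canonical A/B/C labelling
  # stays stable under in-plane jitter
  canonical_order_points(rbind(c(140, 160), c(bx - 150, 180),
                               c(bx - 140, by - 150)))
}

#' Canonical A/B/C ordering of three 2D points
#'
#' A is the point with the lowest `x * 1e6 + y` rank; B and C follow
#' counter-clockwise. Used consistently for fiducial anchors and detections
#' so point correspondence never depends on colour or detection order.
#'
#' @param pts 3x2 matrix
#' @return 3x2 matrix with rows named A, B, C
#' @export
canonical_order_points <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(nrow(pts) == 3, ncol(pts) == 2)
  a <- order(pts[, 1] * 1e6 + pts[, 2])[1]
  rest <- setdiff(1:3, a)
  v1 <- pts[rest[1], ] - pts[a, ]
  v2 <- pts[rest[2], ] - pts[a, ]
  if (v1[1] * v2[2] - v1[2] * v2[1] < 0) rest <- rev(rest)
  out <- pts[c(a, rest), , drop = FALSE]
  rownames(out) <- c("A", "B", "C")
  out
}

# channel radius giving an exact target not-calcified fraction for a
# cylinder of length L inside a sphere of radius R:
#   pi r^2 L = frac * 4/3 pi R^3
.channel_radius <- function(R, L, frac) sqrt(frac * (4 / 3) * R^3 / L)

#' Built-in synthetic specimens
#'
#' Deterministic phantom generator. The same `preset_name` and `seed` always
#' return an identical spec; different seeds perturb solid placement.
#'
#' Presets:
#' \describe{
#'   \item{two_sphere_test}{one bone sphere r = 500 um with a single vessel
#'     tube r = 25 um through its centre; the simplest end-to-end phantom.}
#'   \item{sphere_channel}{bone sphere r = 500 um with an axial channel sized
#'     so exactly 1.0 percent of the sphere volume is vessel (not calcified).}
#'   \item{offset_sphere}{a bone sphere r = 250 um close to fiducial A in a
#'     wide, shallow block — mimics the real situation of a small specimen
#'     (slow abrasion near the marks) inside a large resin block whose
#'     periphery grinds away faster; used for tilt-correction studies.}
#'   \item{y_branch}{a vessel that bifurcates inside a bone ellipsoid;
#'     exercises branching topology.}
#'   \item{malleus_like}{ellipsoidal head plus capsule neck with a dense
#'     vessel network in head and neck and one cartilage inclusion.}
#'   \item{incus_like}{ellipsoidal body with central cartilage inclusions,
#'     two crura and a sparse vessel network.}
#'   \item{stapes_like}{thin-walled arch: two crura of ~120 um thickness and
#'     a footplate, no internal vessels.}
#' }
#'
#' @param preset_name one of the documented presets
#' @param seed integer seed
#' @return a [phantom_spec()]
#' @export
make_ossicle_phantom <- function(preset_name, seed = 0L) {
  presets <- c("two_sphere_test", "sphere_channel", "offset_sphere",
               "y_branch", "malleus_like", "incus_like", "stapes_like")
  if (!preset_name %in% presets)
    stop("unknown preset '", preset_name, "'; available: ",
         paste(presets, collapse = ", "))
  seed <- as.integer(seed)
  with_local_seed(seed, {
    spec <- switch(preset_name,
      two_sphere_test = {
        bs <- c(1200, 1200, 1300)
        ctr <- c(600, 600, 650)
        phantom_spec(
          list(phantom_solid("bone", "sphere", center = ctr, r = 500),
               phantom_solid("vessel", "cylinder",
                             p1 = c(600, 600, 100), p2 = c(600, 600, 1200),
                             r = 25)),
          bs, default_fiducial_columns(bs), seed = seed)
      },
      sphere_channel = {
        bs <- c(1200, 1200, 1300)
        r <- .channel_radius(500, 900, 0.01)
        phantom_spec(
          list(phantom_solid("bone", "sphere", center = c(600, 600, 650), r = 500),
               phantom_solid("vessel", "cylinder",
                             p1 = c(600, 600, 200), p2 = c(600, 600, 1100),
                             r = r)),
          bs, default_fiducial_columns(bs), seed = seed)
      },
      offset_sphere = {
        bs <- c(2000, 2000, 1300)
        cols <- canonical_order_points(rbind(c(250, 250), c(1750, 330),
                                             c(380, 1750)))
        phantom_spec(
          list(phantom_solid("bone", "sphere", center = c(560, 560, 430),
                             r = 250)),
          bs, cols, seed = seed)
      },
      y_branch = {
        bs <- c(1700, 1300, 1500)
        phantom_spec(
          list(phantom_solid("bone", "ellipsoid", center = c(850, 650, 750),
                             semiaxes = c(620, 420, 660)),
               phantom_solid("vessel", "capsule",
                             p1 = c(850, 650, 250), p2 = c(850, 650, 700), r = 40),
               phantom_solid("vessel", "capsule",
                             p1 = c(850, 650, 700), p2 = c(680, 650, 1150), r = 40),
               phantom_solid("vessel", "capsule",
                             p1 = c(850, 650, 700), p2 = c(1020, 650, 1150), r = 40)),
          bs, default_fiducial_columns(bs), seed = seed)
      },
      malleus_like = {
        bs <- c(2000, 1800, 2200)
        head_c <- c(1000, 900, 700) + runif(3, -30, 30)
        solids <- list(
          phantom_solid("bone", "ellipsoid", center = head_c,
                        semiaxes = c(450, 400, 420) + runif(3, -20, 20)),
          phantom_solid("bone", "capsule",
                        p1 = head_c + c(0, 0, 300),
                        p2 = head_c + c(100, 50, 1100) + runif(3, -30, 30),
                        r = 150),
          phantom_solid("cartilage", "sphere",
                        center = head_c + c(150, 100, -100) + runif(3, -20, 20),
                        r = 70 + runif(1, -10, 10)))
        # dense vessel network in head and neck
        for (i in 1:6) {
          p1 <- head_c + runif(3, -220, 220)
          p2 <- p1 + runif(3, -280, 280)
          solids[[length(solids) + 1]] <-
            phantom_solid("vessel", "capsule", p1 = p1, p2 = p2,
                          r = runif(1, 10, 40))
        }
        phantom_spec(solids, bs, default_fiducial_columns(bs), seed = seed)
      },
      incus_like = {
        bs <- c(2000, 1800, 2200)
        body_c <- c(1000, 900, 800) + runif(3, -30, 30)
        solids <- list(
          phantom_solid("bone", "ellipsoid", center = body_c,
                        semiaxes = c(500, 420, 450) + runif(3, -20, 20)),
          phantom_solid("bone", "capsule",  # long crus
                        p1 = body_c + c(0, 0, 350),
                        p2 = body_c + c(-80, 40, 1150) + runif(3, -30, 30),
                        r = 120),
          phantom_solid("bone", "capsule",  # short crus
                        p1 = body_c + c(250, 0, 0),
                        p2 = body_c + c(750, 0, 100) + runif(3, -30, 30),
                        r = 130))
        for (i in 1:4)  # central cartilage inclusions
          solids[[length(solids) + 1]] <-
            phantom_solid("cartilage", "sphere",
                          center = body_c + runif(3, -180, 180),
                          r = runif(1, 40, 90))
        for (i in 1:4)
          solids[[length(solids) + 1]] <-
            phantom_solid("vessel", "capsule",
                          p1 = body_c + runif(3, -250, 250),
                          p2 = body_c + runif(3, -250, 250),
                          r = runif(1, 8, 30))
        phantom_spec(solids, bs, default_fiducial_columns(bs), seed = seed)
      },
      stapes_like = {
        bs <- c(1600, 1400, 1600)
        top <- c(800, 700, 400) + runif(3, -20, 20)
        foot <- c(800, 700, 1200)
        phantom_spec(
          list(phantom_solid("bone", "sphere", center = top, r = 90),  # head
               phantom_solid("bone", "capsule",  # anterior crus, ~120 um thick
                             p1 = top, p2 = foot + c(-260, 0, 0), r = 60),
               phantom_solid("bone", "capsule",  # posterior crus
                             p1 = top, p2 = foot + c(260, 0, 0), r = 60),
               phantom_solid("bone", "ellipsoid",  # footplate
                             center = foot, semiaxes = c(340, 160, 45))),
          bs, default_fiducial_columns(bs), seed = seed)
      })
    spec
  })
}
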