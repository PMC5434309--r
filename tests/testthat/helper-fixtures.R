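# Shared, memoized fixtures: virtual-grinding simulations are the expensive
# part of the suite, so each named fixture is built once per test session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder)
  .fx[[name]]
}

# two_sphere phantom, flat noise-free grinding (10 runs)
fx_flat10_clean <- function() fixture("flat10_clean", {
  spec <- make_ossicle_phantom("two_sphere_test", 0)
  sim <- simulate_grinding(spec, grinding_schedule(10, 35),
                           default_stain_model(0), seed = 1)
  list(spec = spec, sim = sim)
})

# two_sphere phantom, flat grinding through the whole sphere, default noise
fx_flat33 <- function() fixture("flat33", {
  spec <- make_ossicle_phantom("two_sphere_test", 0)
  sim <- simulate_grinding(spec, grinding_schedule(33, 35),
                           default_stain_model(5), seed = 11)
  poses <- build_pose_stack(sim$images, sim$csv, spec$fiducial_columns,
                            spec$block_size[3], 5, 8)
  list(spec = spec, sim = sim, poses = poses)
})

# jittered stack for pose-recovery checks (50 slices)
fx_jitter50 <- function() fixture("jitter50", {
  spec <- make_ossicle_phantom("two_sphere_test", 0)
  sim <- simulate_grinding(spec,
                           grinding_schedule(50, 25, jitter_trans_sd_px = 2,
                                             jitter_rot_sd_deg = 0.5),
                           default_stain_model(5), seed = 3)
  poses <- build_pose_stack(sim$images, sim$csv, spec$fiducial_columns,
                            spec$block_size[3], 5, 8)
  list(spec = spec, sim = sim, poses = poses)
})

# full pipeline on the bundled demo config, memoized per tag
fx_pipeline <- function(tag) fixture(paste0("pipeline_", tag), {
  cfg <- yaml::read_yaml(system.file("extdata", "config_two_sphere.yaml",
                                     package = "microgrindr"))
  out <- file.path(tempdir(), paste0("mgr_pipeline_", tag))
  cfg$out_dir <- out
  report <- suppressMessages(run_pipeline(cfg))
  list(cfg = cfg, out = out, report = report)
})

# direct voxelization of a binary solid on a grid (for morphometry tests)
fx_solid_volume <- function(fun, voxel, n, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(n[1]) - 0.5) * voxel
  ys <- origin[2] + (seq_len(n[2]) - 0.5) * voxel
  zs <- origin[3] + (seq_len(n[3]) - 0.5) * voxel
  xg <- rep(xs, times = n[2] * n[3])
  yg <- rep(rep(ys, each = n[1]), times = n[3])
  zg <- rep(zs, each = n[1] * n[2])
  label_volume(array(as.integer(fun(xg, yg, zg)), dim = n), voxel, origin)
}

identity_pose <- function(z = 0)
  list(angle_deg = 0, tx_um = 0, ty_um = 0, scale = 1, gx = 0, gy = 0,
       c_um = z)

ring_set <- function(rings, z, class = "bone") {
  structure(lapply(seq_along(rings), function(i) {
    xy <- rings[[i]]
    a <- sum(xy[, 1] * xy[c(2:nrow(xy), 1), 2] -
             xy[c(2:nrow(xy), 1), 1] * xy[, 2]) / 2
    list(xy = xy, area_um2 = abs(a), hole = FALSE, polygon_id = i,
         ring_id = 1L)
  }), class = "contour_set", tissue = class, pose = identity_pose(z))
}

circle_ring <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
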