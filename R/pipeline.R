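## Five-stage pipeline orchestration: simulate (optional) -> register ->
## segment -> reconstruct -> measure, with artifacts and a checksum log.

#' Load and validate a pipeline configuration
#'
#' Configurations are YAML files (or equivalent lists). Recognized fields:
#' `seed`; optional `simulate` block (`preset`, `n_runs`,
#' `nominal_abrasion`, `tilt`, `abrasion_noise_sd`, `jitter_trans_sd_px`,
#' `jitter_rot_sd_deg`); `pixel_size_um`; `image_dir` / `abrasion_csv` (for
#' real data); `anchors_um` (3x2), `block_size_um`, `fiducial_radius_um`;
#' `out_dir`; `voxel_size_um` (null = automatic: the smaller of the pixel
#' size and a third of the median plane gap); `smoothing_iters`;
#' `min_area_um2`; `diffusion_limit_um`. All numeric parameters must be
#' positive; referenced paths must exist at load time. Every applied
#' default is recorded so the run log shows the full effective
#' configuration.
#'
#' @param config path to a YAML file, or a named list
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, pixel_size_um = 5, voxel_size_um = NULL,
                   smoothing_iters = 10, min_area_um2 = 200,
                   diffusion_limit_um = 150, fiducial_radius_um = 40,
                   out_dir = "microgrindr_out")
  for (n in names(defaults))
    if (is.null(config[[n]])) config[[n]] <- defaults[[n]]
  for (n in c("pixel_size_um", "smoothing_iters", "min_area_um2",
              "diffusion_limit_um", "fiducial_radius_um"))
    if (!is.numeric(config[[n]]) || config[[n]] <= 0)
      stop("config field '", n, "' must be a positive number")
  if (!is.null(config$voxel_size_um) && config$voxel_size_um <= 0)
    stop("config field 'voxel_size_um' must be positive")
  if (is.null(config$simulate)) {
    for (p in c("image_dir", "abrasion_csv"))
      if (is.null(config[[p]]) || !file.exists(config[[p]]))
        stop("config path '", p, "' missing or does not exist: ",
             if (is.null(config[[p]])) "(unset)" else config[[p]])
    if (is.null(config$anchors_um) || is.null(config$block_size_um))
      stop("real-data configs need 'anchors_um' and 'block_size_um'")
  }
  structure(config, class = "pipeline_config")
}

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

checksum <- function(path) unname(tools::md5sum(path))

#' Run the reconstruction pipeline
#'
#' Executes simulate (if configured) -> register -> segment -> reconstruct
#' -> measure. Every stage writes its artifact under `out_dir` and logs a
#' line with input/output checksums to `run.log`; rerunning with an
#' identical configuration reproduces identical artifacts. Any stage error
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one)
#' @param stages subset of stages to run (later stages reload earlier
#'   artifacts from `out_dir`)
#' @return the final `morphometry_report` (invisibly for partial runs)
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "register", "segment",
                                    "reconstruct", "measure")) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  if (identical(stages[1], "simulate") || length(stages) == 5)
    cat("", file = log_path)  # fresh log on a full run
  log_line(log_path, "config: ",
           jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
  in_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  stain <- default_stain_model()

  # ---- stage: simulate -----------------------------------------------------
  slices_dir <- file.path(out, "slices")
  if ("simulate" %in% stages && !is.null(cfg$simulate)) {
    in_stage("simulate", {
      sm <- cfg$simulate
      spec <- make_ossicle_phantom(sm$preset, cfg$seed)
      tilt <- if (is.null(sm$tilt)) c(0, 0)
              else if (identical(sm$tilt, "calibrated_spread"))
                tilt_for_spread(spec) else as.numeric(sm$tilt)
      sched <- grinding_schedule(
        n_runs = sm$n_runs %||% 30L,
        nominal_abrasion = sm$nominal_abrasion %||% 35,
        tilt = tilt,
        abrasion_noise_sd = sm$abrasion_noise_sd %||% 0,
        jitter_trans_sd_px = sm$jitter_trans_sd_px %||% 0,
        jitter_rot_sd_deg = sm$jitter_rot_sd_deg %||% 0,
        pixel_size = cfg$pixel_size_um)
      sim <- simulate_grinding(spec, sched, stain, seed = cfg$seed,
                               out_dir = slices_dir)
      cfg$anchors_um <- spec$fiducial_columns
      cfg$block_size_um <- spec$block_size
      log_line(log_path, "simulate: ", length(sim$images), " runs -> ",
               slices_dir, " csv ", checksum(file.path(slices_dir, "abrasion.csv")))
    })
  }
  if (!is.null(cfg$simulate)) {
    cfg$image_dir <- slices_dir
    cfg$abrasion_csv <- file.path(slices_dir, "abrasion.csv")
    if (is.null(cfg$anchors_um)) {
      spec <- make_ossicle_phantom(cfg$simulate$preset, cfg$seed)
      cfg$anchors_um <- spec$fiducial_columns
      cfg$block_size_um <- spec$block_size
    }
  }
  anchors <- canonical_order_points(as.matrix(cfg$anchors_um))
  block <- as.numeric(cfg$block_size_um)

  # ---- stage: register -----------------------------------------------------
  poses_path <- file.path(out, "poses.json")
  images <- NULL
  if ("register" %in% stages) {
    in_stage("register", {
      images <- read_image_dir(cfg$image_dir)
      poses <- build_pose_stack(images, cfg$abrasion_csv, anchors, block[3],
                                cfg$pixel_size_um,
                                cfg$fiducial_radius_um / cfg$pixel_size_um,
                                stain)
      write_pose_stack(poses, poses_path)
      log_line(log_path, "register: ", length(poses), " poses, mean gap ",
               round(mean(attr(poses, "gaps_um")), 2), " um -> ",
               checksum(poses_path))
    })
  }

  # ---- stage: segment ------------------------------------------------------
  labels_dir <- file.path(out, "labels")
  if ("segment" %in% stages) {
    in_stage("segment", {
      if (is.null(images)) images <- read_image_dir(cfg$image_dir)
      dir.create(labels_dir, showWarnings = FALSE)
      poses <- read_pose_stack(poses_path)
      for (i in seq_along(images)) {
        lm <- classify_pixels(images[[i]], stain,
                              pixel_size = cfg$pixel_size_um, run = i)
        write_label_png(lm$labels, file.path(labels_dir,
                                             sprintf("run_%04d.png", i)))
        for (cl in c("bone", "vessel", "cartilage", "soft_tissue")) {
          cs <- extract_contours(lm, cl, poses[[i]],
                                 min_area_um2 = cfg$min_area_um2)
          if (length(cs) > 0)
            write_contours(cs, file.path(labels_dir,
                                         sprintf("contours_%s_%04d.csv", cl, i)))
        }
      }
      log_line(log_path, "segment: ", length(images), " label maps -> ",
               labels_dir)
    })
  }

  # ---- stage: reconstruct --------------------------------------------------
  volume_path <- file.path(out, "volume.nrrd")
  mesh_cache <- list()
  if ("reconstruct" %in% stages) {
    in_stage("reconstruct", {
      poses <- read_pose_stack(poses_path)
      lab_files <- sort(list.files(labels_dir, pattern = "^run_\\d+\\.png$",
                                   full.names = TRUE))
      labelmaps <- lapply(lab_files, read_label_png)
      gaps <- diff(vapply(poses, function(p) p$c_um +
                            p$gx * block[1] / 2 + p$gy * block[2] / 2,
                          numeric(1)))
      voxel <- cfg$voxel_size_um %||%
        max(min(cfg$pixel_size_um, median(gaps) / 3), 1)
      vol <- rasterize_stack(labelmaps, poses, voxel, block,
                             cfg$pixel_size_um)
      write_nrrd(vol, volume_path)
      log_line(log_path, "reconstruct: voxel ", round(voxel, 3), " um, ",
               paste(dim(vol$labels), collapse = "x"), " -> ",
               checksum(volume_path))
      for (cl in c("bone", "vessel", "cartilage", "soft_tissue")) {
        if (!any(vol$labels == tissue_code(cl))) next
        mesh <- surface_from_volume(vol, cl,
                                    smoothing_iters = cfg$smoothing_iters)
        mesh_cache[[cl]] <- mesh
        write_stl(mesh, file.path(out, paste0("surface_", cl, ".stl")))
        write_ply(mesh, file.path(out, paste0("surface_", cl, ".ply")))
        log_line(log_path, "surface ", cl, ": ", nrow(mesh$triangles),
                 " triangles, watertight ", mesh$watertight, " -> ",
                 checksum(file.path(out, paste0("surface_", cl, ".stl"))))
      }
    })
  }

  # ---- stage: measure ------------------------------------------------------
  report <- NULL
  if ("measure" %in% stages) {
    in_stage("measure", {
      vol <- read_nrrd(volume_path)
      meshes <- mesh_cache
      for (cl in c("bone", "vessel", "cartilage", "soft_tissue")) {
        if (is.null(meshes[[cl]]) && any(vol$labels == tissue_code(cl)))
          meshes[[cl]] <- surface_from_volume(vol, cl,
                                              smoothing_iters = cfg$smoothing_iters)
      }
      report <- morphometry_report(vol, structure_name =
                                      cfg$simulate$preset %||% "specimen",
                                    meshes = meshes,
                                    diffusion_limit_um = cfg$diffusion_limit_um)
      write_morphometry_report(report, file.path(out, "report.json"),
                               file.path(out, "report.csv"))
      log_line(log_path, "measure: -> ",
               checksum(file.path(out, "report.json")))
    })
  }
  if (is.null(report)) invisible(NULL) else report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a morphometry report as JSON and CSV
#' @param report a `morphometry_report`
#' @param json_path,csv_path output paths (NULL to skip either)
#' @export
write_morphometry_report <- function(report, json_path, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  if (!is.null(csv_path)) {
    vv <- unlist(report$volumes_um3$voxel_count)
    df <- data.frame(class = names(vv), volume_um3 = unname(vv),
                     volume_mm3 = unname(vv) / 1e9)
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Read a morphometry report written by [write_morphometry_report()]
#' @param path JSON report path
#' @export
read_morphometry_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "morphometry_report")
}
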