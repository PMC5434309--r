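## File formats: NRRD label volumes, STL/PLY meshes, label PNG rasters.

#' Write a label volume as NRRD
#'
#' Minimal NRRD (format 4) writer: uint8 data, gzip encoding, voxel size in
#' the `spacings` field and the block-coordinate origin in `space origin`.
#'
#' @param vol a [label_volume()]
#' @param path output file (.nrrd)
#' @return `path`, invisibly
#' @export
write_nrrd <- function(vol, path) {
  d <- dim(vol$labels)
  stopifnot(all(vol$labels >= 0), all(vol$labels <= 255))
  header <- paste0(
    "NRRD0004\n",
    "# label volume written by microgrindr\n",
    "type: uint8\n",
    "dimension: 3\n",
    "sizes: ", paste(d, collapse = " "), "\n",
    "encoding: gzip\n",
    "endian: little\n",
    "spacings: ", paste(rep(vol$voxel_um, 3), collapse = " "), "\n",
    "space origin: (", paste(vol$origin, collapse = ","), ")\n",
    "units_um:=1\n",
    "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(memCompress(as.raw(as.integer(vol$labels)), "gzip"), con)
  invisible(path)
}

#' Read an NRRD label volume
#'
#' Reads NRRD files written by [write_nrrd()] (and simple uint8/int gzip or
#' raw NRRDs generally). A file without voxel-size metadata (`spacings` or
#' `space directions`) is an error: physical scale is never guessed.
#'
#' @param path NRRD file
#' @return a [label_volume()]
#' @export
read_nrrd <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  hdr_end <- NA
  for (i in seq_len(length(raw) - 1))
    if (raw[i] == as.raw(10) && raw[i + 1] == as.raw(10)) { hdr_end <- i + 1; break }
  if (is.na(hdr_end)) stop("malformed NRRD: no end of header found")
  lines <- strsplit(rawToChar(raw[seq_len(hdr_end - 2)]), "\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  type <- field("type")
  enc <- field("encoding")
  spac <- field("spacings")
  sdir <- field("space directions")
  if (is.null(spac) && is.null(sdir))
    stop("NRRD file has no voxel-size metadata (spacings/space directions); ",
         "refusing to guess physical scale")
  voxel <- if (!is.null(spac)) as.numeric(strsplit(spac, " +")[[1]])[1]
  else {
    v <- as.numeric(regmatches(sdir, gregexpr("[-0-9.eE+]+", sdir))[[1]])
    max(abs(v))
  }
  origin <- c(0, 0, 0)
  so <- field("space origin")
  if (!is.null(so))
    origin <- as.numeric(regmatches(so, gregexpr("[-0-9.eE+]+", so))[[1]])
  payload <- raw[(hdr_end + 1):length(raw)]
  if (identical(enc, "gzip")) payload <- memDecompress(payload, "gzip")
  else if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  if (!type %in% c("uint8", "uchar", "unsigned char"))
    stop("unsupported NRRD type: ", type)
  vals <- as.integer(payload)
  if (length(vals) != prod(sizes)) stop("NRRD payload size mismatch")
  label_volume(array(vals, dim = sizes), voxel, origin)
}

#' Import an externally produced label volume
#'
#' Accepts an NRRD file or a directory containing a TIFF stack
#' (`*.tif`, slices in filename order) with a `voxel_size.json` sidecar
#' (`{"voxel_um": ..., "origin_um": [x,y,z]}`). Missing voxel-size metadata
#' is an error; the physical scale is never guessed. Use this to bring e.g.
#' a binarized micro-CT segmentation into [compare_modalities()].
#'
#' @param path NRRD file or TIFF stack directory
#' @return a [label_volume()]
#' @export
import_external_label_volume <- function(path) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "voxel_size.json")
    if (!file.exists(meta_path))
      stop("TIFF stack at ", path, " has no voxel_size.json sidecar; ",
           "voxel-size metadata is required")
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(meta$voxel_um)) stop("voxel_size.json lacks 'voxel_um'")
    files <- sort(list.files(path, pattern = "\\.tif$", full.names = TRUE))
    if (length(files) == 0) stop("no .tif slices in ", path)
    slices <- lapply(files, function(f) {
      m <- tiff::readTIFF(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      t(m)  # rows = y in TIFF; volume axis 1 = x
    })
    arr <- array(as.integer(round(unlist(slices) * 255)),
                 dim = c(nrow(slices[[1]]), ncol(slices[[1]]), length(slices)))
    origin <- if (!is.null(meta$origin_um)) as.numeric(meta$origin_um)
              else c(0, 0, 0)
    return(label_volume(arr, meta$voxel_um, origin))
  }
  read_nrrd(path)
}

#' Write a mesh as binary STL
#' @param mesh a `surface_mesh`
#' @param path output .stl path
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices; T <- mesh$triangles
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "microgrindr binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(T)), con, size = 4, endian = "little")
  v1 <- V[T[, 1], , drop = FALSE]
  v2 <- V[T[, 2], , drop = FALSE]
  v3 <- V[T[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  block <- t(cbind(n, v1, v2, v3))  # 12 floats per triangle
  for (i in seq_len(nrow(T))) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`
#' @param path output .ply path
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices; T <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(T)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(V, trim = TRUE, digits = 9), 1, paste,
                   collapse = " "), con)
  writeLines(paste(3, T[, 1] - 1, T[, 2] - 1, T[, 3] - 1), con)
  invisible(path)
}

#' Read / write tissue label rasters as 8-bit PNG
#'
#' Pixel value equals the tissue class code (0-5, see [tissue_classes()]).
#'
#' @param labels H x W integer matrix of class codes
#' @param path PNG file path
#' @export
write_label_png <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
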