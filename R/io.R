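#' OCT volume container
#'
#' A 3D SD-OCT intensity volume with explicit physical voxel geometry.
#' Axis order is (A-scan x, B-scan y, axial z); the axial index increases
#' with depth (vitreous towards choroid). Indices are 1-based throughout.
#'
#' @param intensities numeric 3D array on the 0-255 scale.
#' @param voxel_pitch_um numeric length-3 physical pitch (x, y, z) in
#'   micrometres. The canonical macular cube, 6 x 6 x 2 mm sampled at
#'   512 x 128 x 1024 voxels, has pitch (11.719, 46.875, 1.953) um.
#' @param eye_id identifier string.
#' @param fovea optional (ascan, bscan) index pair of the foveal center.
#' @param label optional severity label, "NPDR" or "PDR".
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(intensities, voxel_pitch_um, eye_id = "",
                       fovea = NULL, label = NULL) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (length(voxel_pitch_um) != 3L || any(voxel_pitch_um <= 0))
    stop("voxel_pitch_um must be 3 positive values")
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie within [0, 255]")
  structure(list(intensities = intensities,
                 voxel_pitch_um = as.numeric(voxel_pitch_um),
                 eye_id = as.character(eye_id),
                 fovea = fovea, label = label),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("oct_volume '%s': %d x %d x %d voxels, pitch (%.3f, %.3f, %.3f) um\n",
              x$eye_id, d[1], d[2], d[3],
              x$voxel_pitch_um[1], x$voxel_pitch_um[2], x$voxel_pitch_um[3]))
  invisible(x)
}

#' Fundus image container
#'
#' @param rgb numeric array (nx, ny, 3) on the 0-255 scale. First axis is
#'   horizontal (x), matching the en-face A-scan axis after registration.
#' @param pixel_pitch_um scalar or length-2 pixel pitch, um.
#' @param eye_id identifier string.
#' @export
fundus_image <- function(rgb, pixel_pitch_um = NA_real_, eye_id = "") {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be an (nx, ny, 3) array")
  if (any(rgb < 0)) stop("rgb values must be nonnegative")
  structure(list(rgb = rgb, pixel_pitch_um = pixel_pitch_um,
                 eye_id = as.character(eye_id)),
            class = "fundus_image")
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Write / read an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' Pages are B-scans, each stored as an (axial x A-scan) 8-bit grayscale
#' image. Geometry and identity metadata travel in a JSON sidecar next to
#' the TIFF (same path with a .json extension); the round trip is exact for
#' integer-valued volumes.
#'
#' @param vol an [oct_volume].
#' @param path TIFF file path (.tif/.tiff).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an [oct_volume].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensities)
  pages <- lapply(seq_len(d[2]), function(y) t(vol$intensities[, y, ]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(dims = d, voxel_pitch_um = vol$voxel_pitch_um,
               eye_id = vol$eye_id)
  if (!is.null(vol$fovea)) meta$fovea <- vol$fovea
  if (!is.null(vol$label)) meta$label <- vol$label
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar: expected '", sc, "' next to '", path, "'")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  d <- as.integer(meta$dims)
  if (length(pages) != d[2])
    stop("TIFF has ", length(pages), " pages but sidecar declares ", d[2],
         " B-scans")
  if (!all(vapply(pages, function(p) identical(dim(p), c(d[3], d[1])),
                  logical(1))))
    stop("page shape mismatch: sidecar declares ", d[3], " x ", d[1],
         " (axial x A-scan) pages")
  arr <- array(0, dim = d)
  for (y in seq_len(d[2])) arr[, y, ] <- t(round(pages[[y]] * 255))
  oct_volume(arr, meta$voxel_pitch_um, meta$eye_id,
             fovea = if (!is.null(meta$fovea)) as.numeric(meta$fovea),
             label = meta$label)
}

#' Write / read binary masks
#'
#' 2D masks are stored as 8-bit PNG, 3D masks as multi-page TIFF (pages =
#' B-scans). On disk foreground is 255 and background 0; in memory masks
#' are numeric/logical arrays with values in \{0, 1\}. Reading a file with
#' any other gray level is an error.
#'
#' @param mask 2D or 3D array with values in \{0, 1\} (logical accepted).
#' @param path output path: .png for 2D, .tif/.tiff for 3D.
#' @export
write_mask <- function(mask, path) {
  m <- mask * 1
  if (!is_binary(m)) stop("mask values must be in {0, 1}")
  nd <- length(dim(m))
  if (nd == 2L) {
    png::writePNG(t(m), path)  # store as (row = y) image
  } else if (nd == 3L) {
    pages <- lapply(seq_len(dim(m)[2]), function(y) t(m[, y, ]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  } else stop("mask must be 2D or 3D")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    m <- t(round(img * 255))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    d2 <- dim(pages[[1]])
    m <- array(0, dim = c(d2[2], length(pages), d2[1]))
    for (y in seq_along(pages)) m[, y, ] <- t(round(pages[[y]] * 255))
  } else stop("unsupported mask extension: ", ext)
  bad <- setdiff(unique(as.vector(m)), c(0, 255))
  if (length(bad))
    stop("non-binary pixel values in mask: ", paste(bad, collapse = ", "))
  m / 255
}

feature_table_header <- c("eye_id", "label", "avg_area_mm2", "amount",
                          "avg_distance_um", "avg_altitude_um",
                          "avg_reflectivity")

#' Write / read the per-eye feature table
#'
#' CSV with the fixed header
#' `eye_id,label,avg_area_mm2,amount,avg_distance_um,avg_altitude_um,avg_reflectivity`.
#'
#' @param rows data.frame carrying exactly those columns (any order).
#' @param path CSV path.
#' @export
write_feature_table <- function(rows, path) {
  if (nrow(rows) > 0 || ncol(rows) > 0) {
    missing_cols <- setdiff(feature_table_header, names(rows))
    if (length(missing_cols))
      stop("feature table is missing field(s): ",
           paste(missing_cols, collapse = ", "))
  }
  if (nrow(rows) == 0) {
    writeLines(paste(feature_table_header, collapse = ","), path)
  } else {
    write.csv(rows[, feature_table_header, drop = FALSE], path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(feature_table_header, names(df))
  if (length(missing_cols))
    stop("feature table is missing field(s): ",
         paste(missing_cols, collapse = ", "))
  df
}
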