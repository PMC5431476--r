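#' Adaptive seed detection within the narrow band
#'
#' Seeds are band pixels whose intensity exceeds the band mean plus `k`
#' standard deviations, computed per B-scan so the threshold adapts to
#' local brightness and noise level.
#'
#' @param bscan 2D matrix (A-scan x axial), ideally denoised.
#' @param band_mask logical matrix of the narrow band in this B-scan.
#' @param k threshold offset in band standard deviations.
#' @return logical seed mask.
#' @export
adaptive_seeds <- function(bscan, band_mask, k = 2) {
  stopifnot(identical(dim(bscan), dim(band_mask)))
  vals <- bscan[band_mask]
  if (length(vals) == 0L) stop("narrow band is empty in this B-scan")
  thr <- mean(vals) + k * sd(vals)
  if (is.na(thr)) thr <- mean(vals)  # single-pixel band
  band_mask & bscan > thr
}

#' Seeded region growing inside the narrow band
#'
#' Seeds are grouped into 8-connected components; each component grows over
#' 8-neighbours, admitting a pixel iff it lies in the band and its
#' intensity is at least the seed-component mean minus `delta`. Growth can
#' therefore never leave the band.
#'
#' @param bscan 2D matrix (A-scan x axial).
#' @param seeds logical seed mask (must be contained in `band_mask`).
#' @param band_mask logical narrow-band mask.
#' @param delta growth tolerance, gray levels.
#' @return logical lesion mask for this B-scan.
#' @export
region_grow <- function(bscan, seeds, band_mask, delta = 10) {
  stopifnot(identical(dim(bscan), dim(seeds)),
            identical(dim(bscan), dim(band_mask)))
  if (any(seeds & !band_mask)) stop("seeds must lie inside the band")
  m <- cpp_region_grow(bscan, seeds, band_mask, delta)
  dim(m) <- dim(bscan)
  m
}

#' Link per-B-scan lesion masks into 3D lesions
#'
#' Stacks the masks into a volume and labels 26-connected components, so a
#' focus spanning neighbouring B-scans is a single lesion. Components
#' smaller than `min_voxels` are discarded as speckle residue.
#'
#' @param per_bscan_masks list of logical (A-scan x axial) masks, one per
#'   B-scan.
#' @param min_voxels minimum component size kept, voxels.
#' @param bridge_gap if positive, fragments separated by up to this many
#'   empty voxels are merged into one lesion (labels are computed on the
#'   mask dilated by `bridge_gap`, then restricted to the original
#'   voxels). 0 gives plain 26-connectivity.
#' @return a `lesion_set`: list with the integer label volume `labels`
#'   (n_ascan x n_bscan x n_axial), the grid `dims`, and `lesions`, a list
#'   of per-lesion records `id`, `voxels` (n x 3 index matrix), `centroid`
#'   (x, y, z voxel units), `footprint` (unique (x, y) pixels) and
#'   `extents` (lesion voxel count per footprint column).
#' @export
link_3d <- function(per_bscan_masks, min_voxels = 3L, bridge_gap = 0L) {
  d2 <- dim(per_bscan_masks[[1]])
  if (!all(vapply(per_bscan_masks, function(m) identical(dim(m), d2),
                  logical(1))))
    stop("per-B-scan masks have inconsistent shapes")
  ny <- length(per_bscan_masks)
  vol <- array(FALSE, dim = c(d2[1], ny, d2[2]))
  for (y in seq_len(ny)) vol[, y, ] <- per_bscan_masks[[y]] > 0
  src <- vol
  for (g in seq_len(bridge_gap)) src <- dilate26(src)
  lab <- cpp_label3d(as.logical(src), dim(src))
  dim(lab) <- dim(src)
  lab[!vol] <- 0L
  lesion_set_from_labels(lab, min_voxels)
}

# one-voxel 26-connectivity dilation of a 3D logical array
dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- clamp(seq_len(d[1]) + dx, 1L, d[1])
    ys <- clamp(seq_len(d[2]) + dy, 1L, d[2])
    zs <- clamp(seq_len(d[3]) + dz, 1L, d[3])
    out <- out | m[xs, ys, zs, drop = FALSE]
  }
  out
}

lesion_set_from_labels <- function(lab, min_voxels = 1L) {
  counts <- tabulate(lab)
  keep <- which(counts >= min_voxels)
  lesions <- vector("list", length(keep))
  relab <- array(0L, dim = dim(lab))
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i], arr.ind = TRUE)
    colnames(vox) <- c("x", "y", "z")
    relab[vox] <- i
    fp_key <- paste(vox[, 1], vox[, 2])
    ext <- table(fp_key)
    fp <- unique(vox[, 1:2, drop = FALSE])
    # order extents to match footprint rows
    ext <- as.integer(ext[paste(fp[, 1], fp[, 2])])
    lesions[[i]] <- list(id = i, voxels = vox,
                         centroid = colMeans(vox),
                         footprint = fp, extents = ext)
  }
  structure(list(labels = relab, dims = dim(lab), lesions = lesions),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("lesion_set: %d lesions, %d voxels total on a %s grid\n",
              length(x$lesions),
              sum(vapply(x$lesions, function(l) nrow(l$voxels), integer(1))),
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Detect hyper-reflective foci in a volume
#'
#' Full HRF detection: adaptive seeding and region growing
#' ([region_grow]) inside the narrow band per B-scan, then 3D linking
#' ([link_3d]). By default the seed threshold statistics (mean + k SD of
#' band intensities) are pooled over the whole volume, which keeps the
#' threshold stable when individual B-scans contain large bright lesions;
#' `threshold_scope = "bscan"` recomputes them per B-scan
#' ([adaptive_seeds]). Pass a denoised volume (see [denoise_volume]; the
#' pipeline applies a second, range-selective bilateral pass before
#' detection to suppress residual speckle clusters).
#'
#' @param vol an [oct_volume], typically denoised.
#' @param band logical 3D narrow-band mask from [build_narrow_band].
#' @param k adaptive threshold offset, band SDs.
#' @param delta region-growing tolerance, gray levels.
#' @param min_voxels minimum lesion size, voxels.
#' @param bridge_gap fragment-merging gap passed to [link_3d].
#' @param threshold_scope "volume" (pooled band statistics) or "bscan".
#' @param add_mask,remove_mask optional 3D correction masks applied as
#'   (detections ∪ add) \ remove before linking.
#' @return a `lesion_set`.
#' @export
detect_hrf <- function(vol, band, k = 2, delta = 10, min_voxels = 1L,
                       bridge_gap = 1L,
                       threshold_scope = c("volume", "bscan"),
                       add_mask = NULL, remove_mask = NULL) {
  threshold_scope <- match.arg(threshold_scope)
  d <- dim(vol$intensities)
  stopifnot(identical(dim(band), d))
  if (threshold_scope == "volume") {
    vals <- vol$intensities[band]
    if (!length(vals)) stop("narrow band is empty")
    thr <- mean(vals) + k * sd(vals)
  }
  masks <- vector("list", d[2])
  for (y in seq_len(d[2])) {
    b <- vol$intensities[, y, ]
    bm <- band[, y, ]
    if (!any(bm)) { masks[[y]] <- bm; next }
    seeds <- if (threshold_scope == "volume") bm & b > thr
             else adaptive_seeds(b, bm, k)
    masks[[y]] <- region_grow(b, seeds, bm, delta)
  }
  if (!is.null(add_mask) || !is.null(remove_mask)) {
    for (y in seq_len(d[2])) {
      m <- masks[[y]]
      if (!is.null(add_mask)) m <- m | (add_mask[, y, ] > 0)
      if (!is.null(remove_mask)) m <- m & !(remove_mask[, y, ] > 0)
      masks[[y]] <- m
    }
  }
  link_3d(masks, min_voxels, bridge_gap)
}

#' Topographic lesion height map
#'
#' En-face map of axial lesion thickness: number of lesion voxels per
#' (A-scan, B-scan) column times the axial pitch.
#'
#' @param lesions a `lesion_set`.
#' @param pitch_z_um axial voxel pitch, micrometres.
#' @return numeric matrix (n_ascan x n_bscan), micrometres.
#' @export
height_map <- function(lesions, pitch_z_um) {
  hm <- matrix(0, lesions$dims[1], lesions$dims[2])
  for (l in lesions$lesions)
    hm[l$footprint] <- hm[l$footprint] + l$extents * pitch_z_um
  hm
}

#' Split lesions into hard exudates and plain foci by fundus evidence
#'
#' A lesion counts as a hard exudate iff at least `min_overlap_frac` of its
#' en-face footprint lies inside the registered fundus HE mask; the split
#' is exhaustive and disjoint.
#'
#' @param lesions a `lesion_set`.
#' @param he_mask_enface binary (n_ascan x n_bscan) HE mask in the en-face
#'   frame.
#' @param min_overlap_frac footprint overlap fraction required.
#' @return list with `lesion_set`s `he` and `focus`.
#' @export
split_by_he <- function(lesions, he_mask_enface, min_overlap_frac = 0.5) {
  if (!identical(dim(he_mask_enface), lesions$dims[1:2]))
    stop("HE mask frame (", paste(dim(he_mask_enface), collapse = "x"),
         ") does not match the lesion en-face frame (",
         paste(lesions$dims[1:2], collapse = "x"), ")")
  is_he <- vapply(lesions$lesions, function(l) {
    mean(he_mask_enface[l$footprint] > 0) >= min_overlap_frac
  }, logical(1))
  list(he = subset_lesions(lesions, which(is_he)),
       focus = subset_lesions(lesions, which(!is_he)))
}

subset_lesions <- function(lesions, idx) {
  relab <- array(0L, dim = lesions$dims)
  kept <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    l <- lesions$lesions[[idx[i]]]
    l$id <- i
    relab[l$voxels] <- i
    kept[[i]] <- l
  }
  structure(list(labels = relab, dims = lesions$dims, lesions = kept),
            class = "lesion_set")
}
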