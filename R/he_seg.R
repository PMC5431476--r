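#' Convert an RGB image to CIELab
#'
#' Standard sRGB (D65) to CIELab conversion; black maps to L = 0 and white
#' to L = 100 with a = b = 0.
#'
#' @param image numeric array (nx, ny, 3) with values in [0, 255].
#' @return numeric array (nx, ny, 3) of L, a, b planes.
#' @export
rgb_to_lab <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must have 3 channels")
  m <- matrix(image, ncol = 3L) / 255
  lab <- convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' Saliency configuration
#'
#' @param scales inner-region half-widths, pixels; strictly increasing.
#' @param neighborhood_width annulus width, pixels; `NULL` means equal to
#'   each scale's half-width.
#' @param threshold_method "otsu" or "fixed".
#' @param fixed_threshold threshold used when `threshold_method = "fixed"`.
#' @param min_area_px minimum connected-component area kept after
#'   thresholding.
#' @export
saliency_config <- function(scales = c(3L, 7L, 15L), neighborhood_width = NULL,
                            threshold_method = c("otsu", "fixed"),
                            fixed_threshold = NULL, min_area_px = 5L) {
  threshold_method <- match.arg(threshold_method)
  if (length(scales) == 0L || any(diff(scales) <= 0) || any(scales < 1))
    stop("scales must be a nonempty strictly increasing set of widths >= 1")
  if (!is.null(neighborhood_width) && any(neighborhood_width < 1))
    stop("neighborhood_width must be >= 1")
  list(scales = as.integer(scales), neighborhood_width = neighborhood_width,
       threshold_method = threshold_method,
       fixed_threshold = fixed_threshold,
       min_area_px = as.integer(min_area_px))
}

#' Local color-contrast saliency at one scale
#'
#' For every pixel, the mean CIELab vector of the centered
#' (2 half_width + 1)^2 inner square is compared with the mean vector of
#' the square annulus of the given width around it; the saliency is the
#' Euclidean distance between the two mean vectors. Borders are handled by
#' mirror padding. A uniform image is therefore everywhere zero-salient,
#' and hard exudates — compact regions whose color departs from the
#' retinal background — score high at scales near their size.
#'
#' @param lab_image CIELab array (nx, ny, 3) from [rgb_to_lab].
#' @param half_width inner-region half-width, pixels.
#' @param neighborhood_width annulus width, pixels.
#' @return nonnegative saliency matrix (nx, ny).
#' @export
saliency_at_scale <- function(lab_image, half_width,
                              neighborhood_width = half_width) {
  h <- as.integer(half_width); w <- as.integer(neighborhood_width)
  if (h < 1L || w < 1L) stop("half_width and neighborhood_width must be >= 1")
  d <- dim(lab_image)
  p <- h + w
  if (p > d[1] || p > d[2])
    stop("outer window (", 2 * p + 1, " px) exceeds the padded image")
  n_in <- (2 * h + 1)^2
  n_out <- (2 * p + 1)^2
  sq <- matrix(0, d[1], d[2])
  for (ch in 1:3) {
    padded <- pad_reflect(lab_image[, , ch], p)
    inner <- box_mean(padded, h)[(w + 1):(w + d[1]), (w + 1):(w + d[2]),
                                 drop = FALSE]
    outer_mean <- box_mean(padded, p)
    annulus <- (outer_mean * n_out - inner * n_in) / (n_out - n_in)
    sq <- sq + (inner - annulus)^2
  }
  sqrt(sq)
}

#' Multiscale saliency map
#'
#' Sums [saliency_at_scale] over the configured scales; the per-scale maps
#' are retained alongside the total.
#'
#' @param lab_image CIELab array (nx, ny, 3).
#' @param config a [saliency_config].
#' @return list with `per_scale` (list of matrices) and `total`.
#' @export
saliency_multiscale <- function(lab_image, config = saliency_config()) {
  per_scale <- lapply(config$scales, function(h) {
    w <- if (is.null(config$neighborhood_width)) h else config$neighborhood_width
    saliency_at_scale(lab_image, h, w)
  })
  total <- Reduce(`+`, per_scale)
  list(per_scale = per_scale, total = total, scales = config$scales)
}

#' Threshold the saliency map into a hard-exudate mask
#'
#' Applies Otsu's threshold on the total saliency map (or a fixed value)
#' and drops connected components below `min_area_px`.
#'
#' @param smap result of [saliency_multiscale] (or a plain matrix).
#' @param config a [saliency_config].
#' @return binary (0/1) matrix.
#' @export
segment_he <- function(smap, config = saliency_config()) {
  total <- if (is.list(smap)) smap$total else smap
  if (any(!is.finite(total))) stop("saliency map contains non-finite values")
  if (config$threshold_method == "otsu") {
    rng <- range(total)
    if (diff(rng) < .Machine$double.eps)
      stop("saliency map is constant; Otsu is undefined - use a fixed threshold")
    thr <- EBImage::otsu(total, range = rng)
  } else {
    if (is.null(config$fixed_threshold))
      stop("fixed_threshold must be set for threshold_method = 'fixed'")
    thr <- config$fixed_threshold
  }
  mask <- (total >= thr) * 1
  if (config$min_area_px > 1L && any(mask > 0)) {
    lab <- EBImage::bwlabel(mask)
    counts <- tabulate(lab)
    small <- which(counts < config$min_area_px)
    if (length(small)) mask[lab %in% small] <- 0
  }
  mask
}

#' Apply add/remove correction masks
#'
#' Programmatic stand-in for expert correction of the automatic HE
#' segmentation: the result is (mask ∪ add) \\ remove.
#'
#' @param mask,add_mask,remove_mask binary arrays of identical shape.
#' @export
apply_correction <- function(mask, add_mask = NULL, remove_mask = NULL) {
  m <- mask > 0
  if (!is.null(add_mask)) {
    if (!identical(dim(add_mask), dim(mask))) stop("add_mask shape mismatch")
    m <- m | (add_mask > 0)
  }
  if (!is.null(remove_mask)) {
    if (!identical(dim(remove_mask), dim(mask))) stop("remove_mask shape mismatch")
    m <- m & !(remove_mask > 0)
  }
  m * 1
}
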