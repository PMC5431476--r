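#' Retinal layer surfaces
#'
#' Per-(A-scan, B-scan) axial voxel indices (1-based) of the three surfaces
#' the pipeline needs: the lower boundary of the nerve fiber layer
#' (`nfl_lower`), the photoreceptor inner/outer segment junction (`isos`)
#' and Bruch's membrane (`bm`). Every column must satisfy
#' `1 <= nfl_lower < isos < bm <= n_axial`.
#'
#' @param nfl_lower,isos,bm integer matrices (n_ascan x n_bscan).
#' @export
layer_surfaces <- function(nfl_lower, isos, bm) {
  stopifnot(identical(dim(nfl_lower), dim(isos)),
            identical(dim(isos), dim(bm)))
  bad <- which(!(nfl_lower >= 1 & nfl_lower < isos & isos < bm),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("surface ordering violated at column (ascan=", bad[1, 1],
         ", bscan=", bad[1, 2], "): need nfl_lower < isos < bm")
  structure(list(nfl_lower = nfl_lower, isos = isos, bm = bm),
            class = "layer_surfaces")
}

#' Bilateral denoising of a B-scan
#'
#' Edge-preserving smoothing applied before layer segmentation and focus
#' detection: a Gaussian spatial kernel weighted by a Gaussian penalty on
#' intensity difference, so speckle is averaged out inside layers while
#' layer boundaries stay sharp.
#'
#' @param bscan 2D matrix (A-scan x axial), 0-255 scale.
#' @param sigma_spatial spatial kernel sd, voxels.
#' @param sigma_range range kernel sd, gray levels.
#' @return denoised matrix, same shape; output values stay within the
#'   input intensity range.
#' @export
bilateral_denoise <- function(bscan, sigma_spatial = 2, sigma_range = 35) {
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop("sigma_spatial and sigma_range must be positive")
  radius <- max(1L, as.integer(ceiling(2.5 * sigma_spatial)))
  cpp_bilateral(bscan, sigma_spatial, sigma_range, radius)
}

#' Denoise a whole volume B-scan by B-scan
#' @param vol an [oct_volume].
#' @inheritParams bilateral_denoise
#' @export
denoise_volume <- function(vol, sigma_spatial = 2, sigma_range = 35) {
  out <- vol
  for (y in seq_len(dim(vol$intensities)[2]))
    out$intensities[, y, ] <- bilateral_denoise(vol$intensities[, y, ],
                                                sigma_spatial, sigma_range)
  out
}

#' Segment one layer boundary in a B-scan by dynamic programming
#'
#' The boundary is the minimum-cost left-to-right path through a per-pixel
#' cost equal to the negative signed vertical (axial) intensity gradient:
#' `polarity = "dark_to_bright"` rewards transitions from low to high
#' intensity with depth (e.g. ONL to IS/OS), `"bright_to_dark"` the
#' opposite (e.g. NFL to inner plexiform, RPE to choroid). Consecutive
#' A-scans may differ by at most `max_jump` voxels; ties break toward the
#' smallest axial index.
#'
#' @param bscan 2D matrix (A-scan x axial), ideally denoised.
#' @param polarity gradient sign selecting the boundary type.
#' @param search_band (z_min, z_max) axial window restricting the path.
#' @param max_jump per-step vertical jump limit, voxels.
#' @return integer vector of axial indices, one per A-scan.
#' @export
segment_boundary <- function(bscan,
                             polarity = c("dark_to_bright", "bright_to_dark"),
                             search_band, max_jump = 2L) {
  polarity <- match.arg(polarity)
  nz <- ncol(bscan)
  z0 <- max(1L, as.integer(search_band[1]))
  z1 <- min(nz, as.integer(search_band[2]))
  if (z1 < z0) stop("empty search band")
  if (z1 - z0 + 1L <= max_jump)
    stop("search band narrower than max_jump")
  grad <- boundary_cost_gradient(bscan)
  cost <- grad[, z0:z1, drop = FALSE]
  if (polarity == "dark_to_bright") cost <- -cost
  if (max(abs(cost)) < 1e-9)
    stop("no gradient evidence in search band (constant image?)")
  dp <- cpp_dp_boundary(cost, as.integer(max_jump))
  dp$path + z0 - 1L
}

# Central-difference axial gradient (one-sided at the ends).
boundary_cost_gradient <- function(bscan) {
  nz <- ncol(bscan)
  g <- matrix(0, nrow(bscan), nz)
  g[, 2:(nz - 1)] <- (bscan[, 3:nz] - bscan[, 1:(nz - 2)]) / 2
  g[, 1] <- bscan[, 2] - bscan[, 1]
  g[, nz] <- bscan[, nz] - bscan[, nz - 1]
  g
}

#' Default layer-segmentation parameters
#'
#' Search bands are fractions of the axial extent; each later surface is
#' searched strictly below the previous one. Surfaces are median-filtered
#' across (A-scan, B-scan) with a 5 x 5 window.
#'
#' @param nfl_band_frac axial fraction window for the NFL lower boundary.
#' @param isos_max_frac,bm_max_frac lower limits (as axial fractions) of
#'   the IS/OS and BM search bands; their upper starts track the previous
#'   surface plus `gap_vox`.
#' @param gap_vox minimum voxel gap between stacked search bands.
#' @param max_jump DP per-step jump limit, voxels.
#' @param median_window surface smoothing window (odd), pixels.
#' @param denoise apply [bilateral_denoise] per B-scan first.
#' @param sigma_spatial,sigma_range bilateral filter parameters.
#' @export
layer_params <- function(nfl_band_frac = c(0.05, 0.30), isos_max_frac = 0.45,
                         bm_max_frac = 0.60, gap_vox = 3L, max_jump = 2L,
                         median_window = 5L, denoise = TRUE,
                         sigma_spatial = 2, sigma_range = 35) {
  list(nfl_band_frac = nfl_band_frac, isos_max_frac = isos_max_frac,
       bm_max_frac = bm_max_frac, gap_vox = as.integer(gap_vox),
       max_jump = as.integer(max_jump),
       median_window = as.integer(median_window), denoise = denoise,
       sigma_spatial = sigma_spatial, sigma_range = sigma_range)
}

#' Segment the NFL-lower, IS/OS and BM surfaces of a volume
#'
#' Runs [segment_boundary] per B-scan with stacked search bands: the NFL
#' lower boundary (bright-to-dark) in the upper retina, then IS/OS
#' (dark-to-bright) below it, then BM (bright-to-dark) below IS/OS. Each
#' surface is then median-filtered across the (A-scan, B-scan) grid and
#' the ordering invariant is enforced.
#'
#' @param vol an [oct_volume].
#' @param params a [layer_params] list.
#' @return a [layer_surfaces].
#' @export
build_surfaces <- function(vol, params = layer_params()) {
  d <- dim(vol$intensities)
  nz <- d[3]
  nfl <- matrix(0L, d[1], d[2]); isos <- nfl; bm <- nfl
  for (y in seq_len(d[2])) {
    b <- vol$intensities[, y, ]
    if (params$denoise)
      b <- bilateral_denoise(b, params$sigma_spatial, params$sigma_range)
    p_nfl <- segment_boundary(b, "bright_to_dark",
                              round(params$nfl_band_frac * nz),
                              params$max_jump)
    p_isos <- segment_boundary(b, "dark_to_bright",
                               c(max(p_nfl) + params$gap_vox,
                                 round(params$isos_max_frac * nz)),
                               params$max_jump)
    p_bm <- segment_boundary(b, "bright_to_dark",
                             c(max(p_isos) + params$gap_vox,
                               round(params$bm_max_frac * nz)),
                             params$max_jump)
    nfl[, y] <- p_nfl; isos[, y] <- p_isos; bm[, y] <- p_bm
  }
  w <- params$median_window
  if (w > 1L) {
    nfl <- round(med2d(nfl, w)); isos <- round(med2d(isos, w))
    bm <- round(med2d(bm, w))
  }
  bad <- which(!(nfl >= 1 & nfl < isos & isos < bm & bm <= nz),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("surface ordering violated after smoothing in B-scan ", bad[1, 2])
  layer_surfaces(nfl, isos, bm)
}

#' Build the HRF narrow-band search region
#'
#' The 3D mask of voxels strictly between the NFL lower boundary and the
#' IS/OS junction, shrunk axially by `margin_vox` on both sides so residual
#' NFL/OS brightness stays out of the band.
#'
#' @param surfaces a [layer_surfaces].
#' @param margin_vox axial erosion margin, voxels.
#' @param n_axial axial extent of the volume.
#' @return logical 3D array (n_ascan x n_bscan x n_axial).
#' @export
build_narrow_band <- function(surfaces, margin_vox = 3L, n_axial) {
  lo <- surfaces$nfl_lower + margin_vox
  hi <- surfaces$isos - margin_vox
  bad <- which(lo > hi, arr.ind = TRUE)
  if (nrow(bad))
    stop("margin collapses the band at column (ascan=", bad[1, 1],
         ", bscan=", bad[1, 2], ")")
  d <- dim(lo)
  z <- array(rep(seq_len(n_axial), each = d[1] * d[2]),
             dim = c(d[1], d[2], n_axial))
  lo3 <- array(lo, dim = dim(z)); hi3 <- array(hi, dim = dim(z))
  z >= lo3 & z <= hi3
}
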