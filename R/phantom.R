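#' Phantom configuration
#'
#' Study conditions for the synthetic paired OCT/fundus generator. The
#' default geometry is the canonical macular cube (6 x 6 x 2 mm sampled at
#' 512 x 128 x 1024 voxels). The layered background carries five surfaces
#' (ILM, NFL lower boundary, OPL/ONL border, IS/OS, BM) with distinct mean
#' reflectivities; hyper-reflective foci are axis-aligned ellipsoids
#' concentrated around the OPL/ONL border, where such foci are found in
#' diabetic retinopathy. A subset of foci ("HE-destined") is larger and
#' axially taller, and becomes visible as hard-exudate blobs in the paired
#' fundus image.
#'
#' @param grid_dims voxel counts (n_ascan, n_bscan, n_axial).
#' @param extent_mm physical extent (x, y, z), millimetres.
#' @param n_foci number of foci (>= 0).
#' @param foci_radius_range_um lateral semi-axis range of plain foci, um.
#' @param foci_axial_range_um axial semi-axis range of plain foci, um
#'   (default gives altitudes around 30 um).
#' @param he_radius_range_um lateral semi-axis range of HE-destined foci.
#' @param he_axial_range_um axial semi-axis range of HE-destined foci
#'   (altitudes around 60 um, taller than plain foci).
#' @param foci_intensity focus gray level before speckle (0-255).
#' @param layer_depths_um named nominal depths of the five surfaces,
#'   strictly increasing.
#' @param layer_intensities mean gray level of the six compartments
#'   (vitreous, NFL, inner retina, ONL, IS/OS-RPE complex, choroid).
#' @param speckle_sigma relative sd of the multiplicative Gamma speckle;
#'   0 disables noise.
#' @param n_exudates number of HE-destined foci (<= n_foci); each becomes
#'   a fundus exudate blob.
#' @param fundus_scale fundus image size relative to the en-face grid.
#' @param transform_params list(theta_deg, scale, tx, ty) of the
#'   fundus-to-en-face similarity; `scale = NULL` fits the fundus onto the
#'   en-face frame (1 / fundus_scale).
#' @param rng_seed integer seed; identical config + seed gives
#'   bit-identical phantoms.
#' @export
phantom_config <- function(grid_dims = c(512L, 128L, 1024L),
                           extent_mm = c(6, 6, 2),
                           n_foci = 8L,
                           foci_radius_range_um = c(40, 80),
                           foci_axial_range_um = c(12, 20),
                           he_radius_range_um = c(120, 250),
                           he_axial_range_um = c(25, 40),
                           foci_intensity = 150,
                           layer_depths_um = c(ilm = 200, nfl_lower = 260,
                                               opl_onl = 500, isos = 700,
                                               bm = 800),
                           layer_intensities = c(vitreous = 10, nfl = 120,
                                                 inner = 60, onl = 40,
                                                 osrpe = 140, choroid = 50),
                           speckle_sigma = 0.15,
                           n_exudates = 2L,
                           fundus_scale = 1.4,
                           transform_params = list(theta_deg = 4,
                                                   scale = NULL,
                                                   tx = 0, ty = 0),
                           rng_seed = 1L) {
  cfg <- list(grid_dims = as.integer(grid_dims), extent_mm = extent_mm,
              n_foci = as.integer(n_foci),
              foci_radius_range_um = foci_radius_range_um,
              foci_axial_range_um = foci_axial_range_um,
              he_radius_range_um = he_radius_range_um,
              he_axial_range_um = he_axial_range_um,
              foci_intensity = foci_intensity,
              layer_depths_um = layer_depths_um,
              layer_intensities = layer_intensities,
              speckle_sigma = speckle_sigma,
              n_exudates = as.integer(n_exudates),
              fundus_scale = fundus_scale,
              transform_params = transform_params,
              rng_seed = as.integer(rng_seed))
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$grid_dims <= 0)) stop("grid_dims must be positive")
  if (any(cfg$extent_mm <= 0)) stop("extent_mm must be positive")
  if (cfg$n_foci < 0 || cfg$n_exudates < 0)
    stop("n_foci and n_exudates must be >= 0")
  if (cfg$n_exudates > cfg$n_foci)
    stop("n_exudates cannot exceed n_foci")
  if (any(diff(cfg$layer_depths_um) <= 0))
    stop("layer_depths_um must be strictly increasing")
  if (cfg$speckle_sigma < 0) stop("speckle_sigma must be >= 0")
  band_um <- cfg$layer_depths_um[["isos"]] - cfg$layer_depths_um[["nfl_lower"]]
  max_axial <- max(cfg$foci_axial_range_um[2], cfg$he_axial_range_um[2])
  if (2 * max_axial >= band_um - 40)
    stop("focus axial radius exceeds the NFL-to-IS/OS band thickness")
  invisible(cfg)
}

voxel_pitch <- function(cfg) cfg$extent_mm * 1000 / cfg$grid_dims

#' Fundus-to-en-face truth transform for a phantom configuration
#'
#' Similarity that rotates about the fundus center, scales by
#' `transform_params$scale` (default 1/fundus_scale) and moves the fundus
#' center onto the en-face center, plus the configured pixel offset.
#'
#' @param cfg a [phantom_config].
#' @export
phantom_truth_transform <- function(cfg) {
  fd <- round(cfg$fundus_scale * cfg$grid_dims[1:2])
  s <- cfg$transform_params$scale
  if (is.null(s)) s <- 1 / cfg$fundus_scale
  th <- cfg$transform_params$theta_deg * pi / 180
  A <- s * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  c_f <- (fd + 1) / 2
  c_e <- (cfg$grid_dims[1:2] + 1) / 2
  tvec <- c_e - as.vector(A %*% c_f) +
    c(cfg$transform_params$tx, cfg$transform_params$ty)
  transform_model(rbind(cbind(A, tvec), c(0, 0, 1)), "similarity")
}

# Smooth surface undulation field (um), deterministic under the active RNG.
surface_undulation <- function(nx, ny, amp_um = 15) {
  phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
  tilt <- runif(1, -10, 10)
  x <- seq_len(nx); y <- seq_len(ny)
  outer(sin(2 * pi * x / nx + phx), cos(2 * pi * y / ny + phy)) * amp_um +
    matrix(tilt * (x - nx / 2) / nx, nx, ny)
}

#' Generate a synthetic SD-OCT volume with ground truth
#'
#' Builds a smoothly undulating layered background, inserts ellipsoidal
#' bright foci centered near the OPL/ONL border (HE-destined foci larger
#' and taller), applies multiplicative Gamma speckle, and quantizes to the
#' 8-bit scale. Foci are placed with disjoint 1-voxel-separated bounding
#' boxes, so the truth mask has exactly `n_foci` 26-connected components.
#'
#' @param config a [phantom_config].
#' @param eye_id identifier stored in the volume.
#' @return list with `oct` ([oct_volume]), `layers` ([layer_surfaces]
#'   truth for NFL-lower/IS/OS/BM), `aux_surfaces` (ILM and OPL/ONL depth
#'   maps, voxels), `foci_mask` (logical 3D truth), `foci` (data.frame:
#'   id, he, centers in voxels, semi-axes in um) and `fovea`.
#' @export
generate_oct_phantom <- function(config, eye_id = "phantom") {
  set.seed(config$rng_seed)
  d <- config$grid_dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  pitch <- voxel_pitch(config)
  und <- surface_undulation(nx, ny)
  depth_vox <- function(nominal) {
    clamp(round((nominal + und) / pitch[3]), 2L, nz - 1L)
  }
  s_ilm <- depth_vox(config$layer_depths_um[["ilm"]])
  s_nfl <- depth_vox(config$layer_depths_um[["nfl_lower"]])
  s_opl <- depth_vox(config$layer_depths_um[["opl_onl"]])
  s_isos <- depth_vox(config$layer_depths_um[["isos"]])
  s_bm <- depth_vox(config$layer_depths_um[["bm"]])

  li <- config$layer_intensities
  arr <- array(0, dim = d)
  zrow <- seq_len(nz)
  for (y in seq_len(ny)) {
    Zm <- matrix(zrow, nx, nz, byrow = TRUE)
    layer <- 1L + (Zm > s_ilm[, y]) + (Zm > s_nfl[, y]) + (Zm > s_opl[, y]) +
      (Zm > s_isos[, y]) + (Zm > s_bm[, y])
    arr[, y, ] <- li[layer]
  }

  foci <- place_foci(config, s_nfl, s_opl, s_isos, pitch)
  foci_mask <- array(FALSE, dim = d)
  for (i in seq_len(nrow(foci))) {
    vox <- rasterize_ellipsoid(foci[i, ], pitch, d)
    arr[vox] <- config$foci_intensity
    foci_mask[vox] <- TRUE
  }

  if (config$speckle_sigma > 0) {
    shape <- 1 / config$speckle_sigma^2
    arr <- arr * rgamma(length(arr), shape = shape, rate = shape)
  }
  arr <- clamp(round(arr), 0, 255)
  fovea <- round(c(nx, ny) / 2 + runif(2, -0.05, 0.05) * c(nx, ny))
  list(oct = oct_volume(arr, pitch, eye_id, fovea = fovea),
       layers = layer_surfaces(s_nfl, s_isos, s_bm),
       aux_surfaces = list(ilm = s_ilm, opl_onl = s_opl),
       foci_mask = foci_mask, foci = foci, fovea = fovea)
}

# Sample focus centers/semi-axes; bounding boxes (with 1-voxel gap) must be
# pairwise disjoint so truth components equal n_foci exactly.
place_foci <- function(config, s_nfl, s_opl, s_isos, pitch) {
  n <- config$n_foci
  n_he <- config$n_exudates
  cols <- c("id", "he", "cx", "cy", "cz", "ax_um", "ay_um", "az_um")
  if (n == 0L)
    return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(cols))),
                           cols))
  d <- config$grid_dims
  boxes <- matrix(0, 0, 6)  # x0 x1 y0 y1 z0 z1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    he <- i <= n_he
    lat_rng <- if (he) config$he_radius_range_um else config$foci_radius_range_um
    ax_rng <- if (he) config$he_axial_range_um else config$foci_axial_range_um
    placed <- FALSE
    for (try in 1:500) {
      a_lat <- runif(1, lat_rng[1], lat_rng[2])
      a_z <- runif(1, ax_rng[1], ax_rng[2])
      rx <- a_lat / pitch[1]; ry <- a_lat / pitch[2]; rz <- a_z / pitch[3]
      cx <- runif(1, 1 + rx + 1, d[1] - rx - 1)
      cy <- runif(1, 1 + max(ry, 0.5) + 0.5, d[2] - max(ry, 0.5) - 0.5)
      zc_opl <- s_opl[round(cx), round(cy)]
      cz <- zc_opl + runif(1, -30, 30) / pitch[3]
      z_lo <- s_nfl[round(cx), round(cy)] + 3 + rz
      z_hi <- s_isos[round(cx), round(cy)] - 3 - rz
      if (z_lo >= z_hi) next
      cz <- clamp(cz, z_lo, z_hi)
      # +/-2 guard keeps a >= 4 voxel gap between foci on every axis, so
      # truth components never touch and remain individually resolvable
      box <- c(floor(cx - rx) - 2, ceiling(cx + rx) + 2,
               floor(cy - max(ry, 0.5)) - 2, ceiling(cy + max(ry, 0.5)) + 2,
               floor(cz - rz) - 2, ceiling(cz + rz) + 2)
      overlaps <- nrow(boxes) > 0 &&
        any(boxes[, 1] <= box[2] & boxes[, 2] >= box[1] &
              boxes[, 3] <= box[4] & boxes[, 4] >= box[3] &
              boxes[, 5] <= box[6] & boxes[, 6] >= box[5])
      if (!overlaps) {
        boxes <- rbind(boxes, box)
        out[[i]] <- data.frame(id = i, he = he, cx = cx, cy = cy, cz = cz,
                               ax_um = a_lat, ay_um = a_lat, az_um = a_z)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place focus ", i, " without overlap; ",
           "reduce n_foci or focus size")
  }
  do.call(rbind, out)
}

rasterize_ellipsoid <- function(f, pitch, d) {
  # effective minimum half-footprint of one voxel per axis: each B-scan
  # integrates a finite slab, so a focus narrower than the voxel pitch
  # still marks the voxel it falls in
  rx <- max(f$ax_um / pitch[1], 0.55)
  ry <- max(f$ay_um / pitch[2], 0.55)
  rz <- max(f$az_um / pitch[3], 0.55)
  xs <- max(1L, floor(f$cx - rx)):min(d[1], ceiling(f$cx + rx))
  ys <- max(1L, floor(f$cy - ry)):min(d[2], ceiling(f$cy + ry))
  zs <- max(1L, floor(f$cz - rz)):min(d[3], ceiling(f$cz + rz))
  g <- expand.grid(x = xs, y = ys, z = zs)
  inside <- ((g$x - f$cx) / rx)^2 + ((g$y - f$cy) / ry)^2 +
    ((g$z - f$cz) / rz)^2 <= 1
  # a physically sub-voxel focus still lights the voxel it falls in
  # (partial-volume): fall back to the nearest voxel center
  if (!any(inside)) {
    r2 <- ((g$x - f$cx) / rx)^2 + ((g$y - f$cy) / ry)^2 +
      ((g$z - f$cz) / rz)^2
    inside <- rank(r2, ties.method = "first") <= 1L
  }
  vox <- as.matrix(g[inside, , drop = FALSE])
  dimnames(vox) <- NULL
  vox
}

#' Generate the paired fundus photograph with ground truth
#'
#' The fundus image carries a smoothly varying orange background, four
#' dark curvilinear vessels (two roughly vertical, two roughly horizontal)
#' whose crossing points are emitted as exact landmark pairs, and one
#' bright yellowish exudate blob per HE-destined focus. Each blob is the
#' transform-preimage of the focus's en-face footprint ellipse, so the
#' fundus truth maps exactly onto the OCT truth under `truth_transform`.
#'
#' @param config a [phantom_config].
#' @param truth_transform fundus-to-en-face [transform_model].
#' @param he_foci data.frame of HE-destined foci (columns cx, cy in
#'   en-face voxels and ax_um, ay_um), e.g. the `he = TRUE` rows of
#'   [generate_oct_phantom]'s `foci`.
#' @return list with `fundus` ([fundus_image]), `he_mask` (fundus frame),
#'   `he_mask_enface` (truth rasterized on the en-face grid),
#'   `landmarks` (data.frame fundus_x/fundus_y/enface_x/enface_y) and
#'   `clipped` (per-blob flag: blob touches the fundus border).
#' @export
generate_fundus_phantom <- function(config, truth_transform, he_foci) {
  set.seed(config$rng_seed + 1L)
  fd <- round(config$fundus_scale * config$grid_dims[1:2])
  fx <- fd[1]; fy <- fd[2]
  pitch <- voxel_pitch(config)
  rgb <- array(0, dim = c(fx, fy, 3))
  xg <- matrix(seq_len(fx), fx, fy); yg <- matrix(seq_len(fy), fx, fy,
                                                  byrow = TRUE)
  # orange background with gentle radial vignetting (illumination falls
  # off toward the field edge); the quadratic has constant curvature, so
  # it adds only a uniform offset to local-contrast saliency
  vc <- c(fx, fy) / 2 + runif(2, -0.05, 0.05) * c(fx, fy)
  r2 <- ((xg - vc[1]) / (fx / 2))^2 + ((yg - vc[2]) / (fy / 2))^2
  vign <- 1 - 0.12 * r2 / max(r2)
  rgb[, , 1] <- 180 * vign
  rgb[, , 2] <- 95 * vign
  rgb[, , 3] <- 40

  # vessels: 2 vertical (x = f(y)) and 2 horizontal (y = f(x)) sinusoids;
  # moderate contrast, well below the exudate-to-background contrast
  vw <- max(1.2, 0.008 * min(fd))
  v_cx <- c(0.32, 0.68) * fx + runif(2, -0.02, 0.02) * fx
  h_cy <- c(0.32, 0.68) * fy + runif(2, -0.02, 0.02) * fy
  v_amp <- 0.03 * fx; h_amp <- 0.03 * fy
  v_ph <- runif(2, 0, 2 * pi); h_ph <- runif(2, 0, 2 * pi)
  vessel <- matrix(FALSE, fx, fy)
  for (k in 1:2) {
    cxs <- v_cx[k] + v_amp * sin(2 * pi * seq_len(fy) / fy + v_ph[k])
    vessel <- vessel | abs(xg - matrix(cxs, fx, fy, byrow = TRUE)) <= vw
    cys <- h_cy[k] + h_amp * sin(2 * pi * seq_len(fx) / fx + h_ph[k])
    vessel <- vessel | abs(yg - matrix(cys, fx, fy)) <= vw
  }
  vcol <- c(150, 75, 40)
  for (ch in 1:3) {
    pl <- rgb[, , ch]; pl[vessel] <- vcol[ch]; rgb[, , ch] <- pl
  }

  # vessel crossings (fixed-point solve), the registration landmarks
  lms <- list()
  for (i in 1:2) for (j in 1:2) {
    x <- v_cx[i]; y <- h_cy[j]
    for (it in 1:40) {
      y <- h_cy[j] + h_amp * sin(2 * pi * x / fx + h_ph[j])
      x <- v_cx[i] + v_amp * sin(2 * pi * y / fy + v_ph[i])
    }
    lms[[length(lms) + 1L]] <- c(x, y)
  }
  lm_f <- do.call(rbind, lms)
  lm_e <- apply_transform(truth_transform, lm_f)
  landmarks <- data.frame(fundus_x = lm_f[, 1], fundus_y = lm_f[, 2],
                          enface_x = lm_e[, 1], enface_y = lm_e[, 2])

  he_mask <- matrix(0, fx, fy)
  he_mask_enface <- matrix(0, config$grid_dims[1], config$grid_dims[2])
  clipped <- logical(nrow(he_foci))
  ti <- invert_transform(truth_transform)
  ex <- matrix(seq_len(config$grid_dims[1]), config$grid_dims[1],
               config$grid_dims[2])
  ey <- matrix(seq_len(config$grid_dims[2]), config$grid_dims[1],
               config$grid_dims[2], byrow = TRUE)
  for (i in seq_len(nrow(he_foci))) {
    f <- he_foci[i, ]
    apx <- f$ax_um / pitch[1]; apy <- f$ay_um / pitch[2]
    he_mask_enface[((ex - f$cx) / apx)^2 + ((ey - f$cy) / apy)^2 <= 1] <- 1
    # bounding box of the preimage in the fundus frame
    corners <- cbind(f$cx + c(-1, -1, 1, 1) * (apx + 1),
                     f$cy + c(-1, 1, -1, 1) * (apy + 1))
    pre <- apply_transform(ti, corners)
    x0 <- floor(min(pre[, 1])); x1 <- ceiling(max(pre[, 1]))
    y0 <- floor(min(pre[, 2])); y1 <- ceiling(max(pre[, 2]))
    clipped[i] <- x0 < 1 || y0 < 1 || x1 > fx || y1 > fy
    xs <- max(1, x0):min(fx, x1); ys <- max(1, y0):min(fy, y1)
    g <- expand.grid(x = xs, y = ys)
    m <- apply_transform(truth_transform, as.matrix(g))
    inside <- ((m[, 1] - f$cx) / apx)^2 + ((m[, 2] - f$cy) / apy)^2 <= 1
    he_mask[as.matrix(g[inside, ])] <- 1
  }
  ecol <- c(250, 240, 150)
  for (ch in 1:3) {
    pl <- rgb[, , ch]; pl[he_mask > 0] <- ecol[ch]; rgb[, , ch] <- pl
  }
  s <- sqrt(abs(det(truth_transform$matrix[1:2, 1:2])))
  list(fundus = fundus_image(rgb, pitch[1:2] * s, eye_id = ""),
       he_mask = he_mask, he_mask_enface = he_mask_enface,
       landmarks = landmarks, clipped = clipped)
}

#' Generate one complete phantom case
#'
#' @param config a [phantom_config].
#' @param eye_id identifier.
#' @param label severity label ("NPDR" or "PDR").
#' @return a `phantom_case` list: `oct`, `fundus`, `truth_layers`,
#'   `aux_surfaces`, `truth_foci_mask`, `truth_he_mask_fundus`,
#'   `truth_he_mask_enface`, `truth_transform`, `landmarks`, `foci`,
#'   `fovea`, `severity_label`.
#' @export
generate_phantom_case <- function(config, eye_id = "phantom",
                                  label = "NPDR") {
  oct_part <- generate_oct_phantom(config, eye_id)
  tt <- phantom_truth_transform(config)
  fundus_part <- generate_fundus_phantom(config, tt,
                                         oct_part$foci[oct_part$foci$he, ,
                                                       drop = FALSE])
  fundus_part$fundus$eye_id <- eye_id
  oct_part$oct$label <- label
  structure(list(oct = oct_part$oct, fundus = fundus_part$fundus,
                 truth_layers = oct_part$layers,
                 aux_surfaces = oct_part$aux_surfaces,
                 truth_foci_mask = oct_part$foci_mask,
                 truth_he_mask_fundus = fundus_part$he_mask,
                 truth_he_mask_enface = fundus_part$he_mask_enface,
                 truth_transform = tt,
                 landmarks = fundus_part$landmarks,
                 foci = oct_part$foci,
                 fovea = oct_part$fovea,
                 severity_label = label),
            class = "phantom_case")
}

#' Generate a phantom cohort
#'
#' PDR-labeled cases draw more foci and more exudates than NPDR cases, the
#' direction of difference reported between the two severity stages, so
#' area and amount separate the classes. Per-case seeds derive
#' reproducibly from `rng_seed`.
#'
#' @param n_npdr,n_pdr eye counts per class (the study cohort had 14 NPDR
#'   and 19 PDR eyes).
#' @param config_ranges list with `npdr` and `pdr` sublists giving
#'   `n_foci` and `n_exudates` inclusive integer ranges.
#' @param rng_seed master seed.
#' @param base_config a [phantom_config] providing all other conditions
#'   (including grid dims).
#' @return list of `phantom_case`s, NPDR cases first.
#' @export
generate_cohort <- function(n_npdr, n_pdr,
                            config_ranges = list(
                              npdr = list(n_foci = c(4L, 10L),
                                          n_exudates = c(1L, 3L)),
                              pdr = list(n_foci = c(12L, 24L),
                                         n_exudates = c(3L, 8L))),
                            rng_seed = 1L,
                            base_config = phantom_config()) {
  stopifnot(n_npdr >= 0, n_pdr >= 0)
  n <- n_npdr + n_pdr
  if (n == 0L) return(list())
  seeds <- derive_seeds(rng_seed, n)
  labels <- c(rep("NPDR", n_npdr), rep("PDR", n_pdr))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    rng <- if (labels[i] == "NPDR") config_ranges$npdr else config_ranges$pdr
    set.seed(seeds[i])
    nf <- sample(rng$n_foci[1]:rng$n_foci[2], 1L)
    ne <- sample(rng$n_exudates[1]:rng$n_exudates[2], 1L)
    ne <- min(ne, nf)
    cfg <- base_config
    cfg$n_foci <- nf
    cfg$n_exudates <- ne
    cfg$rng_seed <- seeds[i]
    validate_phantom_config(cfg)
    id <- sprintf("%s_%02d", tolower(labels[i]),
                  if (labels[i] == "NPDR") i else i - n_npdr)
    cases[[i]] <- generate_phantom_case(cfg, id, labels[i])
  }
  cases
}

#' Write a phantom case to disk
#'
#' Volume as multi-page TIFF + JSON sidecar, fundus as PNG, truth masks as
#' TIFF/PNG, landmarks as CSV, transform as JSON.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- case$oct$eye_id
  paths <- c(
    volume = file.path(dir, paste0(id, "_oct.tif")),
    fundus = file.path(dir, paste0(id, "_fundus.png")),
    foci_mask = file.path(dir, paste0(id, "_foci_mask.tif")),
    he_mask = file.path(dir, paste0(id, "_he_mask.png")),
    landmarks = file.path(dir, paste0(id, "_landmarks.csv")),
    transform = file.path(dir, paste0(id, "_transform.json")))
  write_volume(case$oct, paths[["volume"]])
  png::writePNG(aperm(case$fundus$rgb / 255, c(2, 1, 3)), paths[["fundus"]])
  write_mask(case$truth_foci_mask, paths[["foci_mask"]])
  write_mask(case$truth_he_mask_fundus, paths[["he_mask"]])
  write.csv(case$landmarks, paths[["landmarks"]], row.names = FALSE)
  jsonlite::write_json(list(matrix = case$truth_transform$matrix,
                            kind = case$truth_transform$kind),
                       paths[["transform"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
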