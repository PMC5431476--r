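#' Compute the five per-eye lesion features
#'
#' For each lesion: en-face footprint area (pixels times lateral pixel
#' area, mm^2), mean per-column axial extent times the axial pitch
#' ("altitude", um), en-face Euclidean distance from the lesion centroid
#' to the foveal center (um), and mean raw intensity over the lesion
#' voxels (0-255 "reflectivity"). Eye-level values are means over lesions;
#' `amount` is the lesion count. With no lesions the means are undefined
#' and reported as `NA`.
#'
#' @param lesions a `lesion_set`.
#' @param vol the [oct_volume] the lesions were detected in (reflectivity
#'   is read from it).
#' @param fovea (ascan, bscan) index pair of the foveal center.
#' @param eye_id,label carried into the output row.
#' @return one-row data.frame with columns eye_id, label, avg_area_mm2,
#'   amount, avg_distance_um, avg_altitude_um, avg_reflectivity.
#' @export
compute_eye_features <- function(lesions, vol, fovea, eye_id = vol$eye_id,
                                 label = ifelse(is.null(vol$label), NA,
                                                vol$label)) {
  d <- lesions$dims
  if (fovea[1] < 1 || fovea[1] > d[1] || fovea[2] < 1 || fovea[2] > d[2])
    stop("fovea (", fovea[1], ", ", fovea[2], ") outside the en-face grid")
  pitch <- vol$voxel_pitch_um
  k <- length(lesions$lesions)
  if (k == 0L) {
    return(data.frame(eye_id = eye_id, label = label, avg_area_mm2 = NA_real_,
                      amount = 0L, avg_distance_um = NA_real_,
                      avg_altitude_um = NA_real_,
                      avg_reflectivity = NA_real_,
                      stringsAsFactors = FALSE))
  }
  area <- altitude <- dist <- refl <- numeric(k)
  for (i in seq_len(k)) {
    l <- lesions$lesions[[i]]
    area[i] <- nrow(l$footprint) * pitch[1] * pitch[2] / 1e6  # mm^2
    altitude[i] <- mean(l$extents) * pitch[3]
    dist[i] <- sqrt(((l$centroid[1] - fovea[1]) * pitch[1])^2 +
                      ((l$centroid[2] - fovea[2]) * pitch[2])^2)
    refl[i] <- mean(vol$intensities[l$voxels])
  }
  data.frame(eye_id = eye_id, label = label,
             avg_area_mm2 = mean(area), amount = k,
             avg_distance_um = mean(dist), avg_altitude_um = mean(altitude),
             avg_reflectivity = mean(refl), stringsAsFactors = FALSE)
}

#' Min-max normalize a cohort feature matrix to [0, 1]
#'
#' Per-feature scaling (v - min) / (max - min) across the cohort, the
#' scale on which the feature combinations are fed to the classifier.
#'
#' @param m numeric matrix or data.frame of features, eyes in rows.
#' @return matrix of the same shape with each column spanning [0, 1].
#' @export
normalize_features <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 eyes to normalize")
  rng <- apply(m, 2L, range, na.rm = TRUE)
  zero <- which(rng[2, ] - rng[1, ] <= 0)
  if (length(zero))
    stop("zero range in feature(s): ",
         paste(colnames(m)[zero] %||% zero, collapse = ", "))
  sweep(sweep(m, 2L, rng[1, ]), 2L, rng[2, ] - rng[1, ], `/`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation with p-value and least-squares line
#'
#' Two-sided p from the t statistic r * sqrt((n-2)/(1-r^2)) on n-2 df;
#' slope and intercept from the ordinary least-squares fit of y on x.
#'
#' @param x,y numeric vectors, n >= 3, both with nonzero variance.
#' @return list(r, p, slope, intercept, n).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' Cross-modality agreement of hard-exudate measurements
#'
#' Compares per-eye HE areas measured on the fundus photograph against the
#' matching en-face OCT measurement: Pearson r, its p-value and the
#' regression slope/intercept per severity group (and pooled), plus the
#' per-eye scatter table. Groups with fewer than 3 eyes are skipped with a
#' warning.
#'
#' @param he_from_cfp,he_from_oct paired per-eye measurements.
#' @param group severity label per eye (e.g. "NPDR"/"PDR"); `NULL` pools
#'   all eyes.
#' @param eye_id optional identifiers for the scatter table.
#' @return list with `stats` (data.frame group/n/r/p/slope/intercept) and
#'   `pairs` (the per-eye table).
#' @export
agreement_report <- function(he_from_cfp, he_from_oct, group = NULL,
                             eye_id = NULL) {
  n <- length(he_from_cfp)
  stopifnot(length(he_from_oct) == n)
  if (n == 0L) {
    return(list(stats = data.frame(group = character(), n = integer(),
                                   r = numeric(), p = numeric(),
                                   slope = numeric(), intercept = numeric()),
                pairs = data.frame(eye_id = character(), group = character(),
                                   area_cfp = numeric(),
                                   area_oct = numeric())))
  }
  if (is.null(group)) group <- rep("all", n)
  if (is.null(eye_id)) eye_id <- sprintf("eye_%02d", seq_len(n))
  pairs <- data.frame(eye_id = eye_id, group = group,
                      area_cfp = he_from_cfp, area_oct = he_from_oct,
                      stringsAsFactors = FALSE)
  groups <- unique(group)
  if (length(groups) > 1L) groups <- c(groups, "all")
  rows <- list()
  for (g in groups) {
    idx <- if (g == "all") seq_len(n) else which(group == g)
    if (length(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 eyes; skipped")
      next
    }
    st <- tryCatch(pearson_with_p(he_from_cfp[idx], he_from_oct[idx]),
                   error = function(e) NULL)
    if (is.null(st)) {
      warning("group '", g, "' is degenerate (zero variance); skipped")
      next
    }
    rows[[g]] <- data.frame(group = g, n = st$n, r = st$r, p = st$p,
                            slope = st$slope, intercept = st$intercept,
                            stringsAsFactors = FALSE)
  }
  stats <- if (length(rows)) {
    do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(), n = integer(), r = numeric(),
               p = numeric(), slope = numeric(), intercept = numeric())
  }
  list(stats = stats, pairs = pairs)
}
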