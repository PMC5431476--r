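#' Planar transform model
#'
#' Homogeneous 3x3 mapping from fundus pixel coordinates to OCT en-face
#' pixel coordinates. `kind = "similarity"` constrains the linear part to
#' scaled rotation (equal scale on both axes); `"affine"` is unconstrained.
#'
#' @param matrix 3x3 homogeneous matrix (last row 0 0 1).
#' @param kind "similarity" or "affine".
#' @param residual_rms_px fit residual (0 for constructed transforms).
#' @export
transform_model <- function(matrix, kind = c("similarity", "affine"),
                            residual_rms_px = 0) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(matrix), c(3L, 3L)))
  dimnames(matrix) <- NULL
  if (abs(det(matrix[1:2, 1:2])) < 1e-12)
    stop("transform is not invertible")
  structure(list(matrix = matrix, kind = kind,
                 residual_rms_px = residual_rms_px),
            class = "transform_model")
}

#' Build a similarity transform from rotation, scale and translation
#'
#' @param theta_deg counter-clockwise rotation, degrees.
#' @param scale isotropic scale factor.
#' @param tx,ty translation, pixels.
#' @export
transform_similarity <- function(theta_deg = 0, scale = 1, tx = 0, ty = 0) {
  th <- theta_deg * pi / 180
  m <- rbind(c(scale * cos(th), -scale * sin(th), tx),
             c(scale * sin(th),  scale * cos(th), ty),
             c(0, 0, 1))
  transform_model(m, "similarity")
}

#' Apply or invert a planar transform
#'
#' @param t a [transform_model].
#' @param xy n x 2 matrix of (x, y) points.
#' @export
apply_transform <- function(t, xy) {
  xy <- rbind(NULL, xy)  # coerce vector to 1-row matrix
  p <- cbind(xy[, 1], xy[, 2], 1) %*% t(t$matrix)
  p[, 1:2, drop = FALSE]
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  transform_model(solve(t$matrix), t$kind, t$residual_rms_px)
}

as_landmark_matrices <- function(landmarks) {
  if (is.data.frame(landmarks)) {
    need <- c("fundus_x", "fundus_y", "enface_x", "enface_y")
    if (!all(need %in% names(landmarks)))
      stop("landmark data.frame needs columns ", paste(need, collapse = ", "))
    list(src = cbind(landmarks$fundus_x, landmarks$fundus_y),
         dst = cbind(landmarks$enface_x, landmarks$enface_y))
  } else if (is.list(landmarks) && !is.null(landmarks$src)) {
    list(src = landmarks$src, dst = landmarks$dst)
  } else stop("unrecognized landmark format")
}

#' Estimate the fundus-to-en-face transform from landmark pairs
#'
#' Vessel-crossing landmarks picked in both modalities determine the
#' transform by least squares: the closed-form orthogonal-Procrustes
#' (Umeyama) solution for a similarity, or the normal equations for a full
#' affine. Similarity needs at least 2 distinct pairs, affine at least 3
#' non-collinear pairs.
#'
#' @param landmarks data.frame with columns fundus_x, fundus_y, enface_x,
#'   enface_y, or a list with n x 2 matrices `src` and `dst`.
#' @param kind "similarity" (default) or "affine".
#' @return a [transform_model] with `residual_rms_px` filled in.
#' @export
estimate_transform <- function(landmarks, kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  lm_ <- as_landmark_matrices(landmarks)
  src <- lm_$src; dst <- lm_$dst
  n <- nrow(src)
  if (anyDuplicated(src)) stop("duplicate source landmark points")
  if (kind == "similarity") {
    if (n < 2L) stop("similarity needs at least 2 landmark pairs")
    mu_s <- colMeans(src); mu_d <- colMeans(dst)
    cs <- sweep(src, 2, mu_s); cd <- sweep(dst, 2, mu_d)
    var_s <- sum(cs^2) / n
    if (var_s < 1e-12) stop("degenerate landmarks: source points coincide")
    S <- crossprod(cd, cs) / n            # 2x2 cross-covariance
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    D <- diag(c(1, d))
    R <- sv$u %*% D %*% t(sv$v)
    s <- sum(diag(D) * sv$d) / var_s
    tvec <- mu_d - s * as.vector(R %*% mu_s)
    A <- s * R
  } else {
    if (n < 3L) stop("affine needs at least 3 landmark pairs")
    X <- cbind(src, 1)
    if (qr(X)$rank < 3L) stop("degenerate landmarks: points are collinear")
    B <- qr.solve(X, dst)                 # 3x2, least squares
    A <- t(B[1:2, ])
    tvec <- B[3, ]
  }
  m <- rbind(cbind(A, tvec), c(0, 0, 1))
  tm <- transform_model(m, kind)
  res <- apply_transform(tm, src) - dst
  tm$residual_rms_px <- sqrt(mean(rowSums(res^2)))
  tm
}

#' En-face projection between the IS/OS and BM surfaces
#'
#' Each en-face pixel (x, y) is the mean axial intensity of its column over
#' the inclusive band [isos(x, y), bm(x, y)], the standard en-face view
#' that highlights the vasculature shadow pattern.
#'
#' @param vol an [oct_volume].
#' @param surfaces a [layer_surfaces] with `isos` and `bm` defined.
#' @return numeric matrix (n_ascan x n_bscan).
#' @export
project_enface <- function(vol, surfaces) {
  d <- dim(vol$intensities)
  isos <- surfaces$isos; bm <- surfaces$bm
  bad <- which(isos < 1 | bm > d[3] | isos > bm, arr.ind = TRUE)
  if (nrow(bad))
    stop("surface outside axial range at column (ascan=", bad[1, 1],
         ", bscan=", bad[1, 2], ")")
  out <- matrix(0, d[1], d[2])
  for (y in seq_len(d[2])) {
    slab <- vol$intensities[, y, ]
    cs <- cbind(0, t(apply(slab, 1L, cumsum)))
    i0 <- isos[, y]; i1 <- bm[, y]
    sums <- cs[cbind(seq_len(d[1]), i1 + 1L)] - cs[cbind(seq_len(d[1]), i0)]
    out[, y] <- sums / (i1 - i0 + 1L)
  }
  out
}

# Bilinear sampling of a 2D matrix at fractional (x, y) positions.
# Out-of-bounds positions return 0 and FALSE validity.
bilinear_sample <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  valid <- x >= 1 & x <= nx & y >= 1 & y <= ny
  x0 <- clamp(floor(x), 1, nx); y0 <- clamp(floor(y), 1, ny)
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny)
  fx <- x - x0; fy <- y - y0
  v <- (1 - fx) * (1 - fy) * m[cbind(x0, y0)] +
       fx * (1 - fy) * m[cbind(x1, y0)] +
       (1 - fx) * fy * m[cbind(x0, y1)] +
       fx * fy * m[cbind(x1, y1)]
  v[!valid] <- 0
  list(values = v, valid = valid)
}

#' Warp and crop a fundus image onto the OCT en-face grid
#'
#' Inverse-maps every target pixel through the transform and samples the
#' fundus bilinearly; pixels falling outside the fundus are zero-filled and
#' flagged in the validity mask.
#'
#' @param f a [fundus_image], or a 2D matrix (e.g. a mask).
#' @param t fundus-to-en-face [transform_model].
#' @param target_dims en-face grid size (nx, ny).
#' @return list with `rgb` (or `image` for matrix input) and `valid` mask.
#' @export
warp_crop_fundus <- function(f, t, target_dims) {
  ti <- invert_transform(t)
  nx <- target_dims[1]; ny <- target_dims[2]
  grid <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  src <- apply_transform(ti, grid)
  if (inherits(f, "fundus_image")) {
    out <- array(0, dim = c(nx, ny, 3))
    valid <- NULL
    for (ch in 1:3) {
      bs <- bilinear_sample(f$rgb[, , ch], src[, 1], src[, 2])
      out[, , ch] <- matrix(bs$values, nx, ny)
      valid <- matrix(bs$valid, nx, ny)
    }
    list(rgb = out, valid = valid)
  } else {
    bs <- bilinear_sample(f, src[, 1], src[, 2])
    list(image = matrix(bs$values, nx, ny), valid = matrix(bs$valid, nx, ny))
  }
}

#' Warp a binary fundus-frame mask into the en-face frame
#'
#' Bilinear interpolation followed by a 0.5 threshold.
#' @inheritParams warp_crop_fundus
#' @param mask binary matrix in the fundus frame.
#' @export
warp_mask <- function(mask, t, target_dims) {
  w <- warp_crop_fundus(mask * 1, t, target_dims)
  (w$image >= 0.5) * 1
}
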