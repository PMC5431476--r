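# Internal helpers shared across modules.

# Symmetric (mirror) padding of a matrix by p rows/cols on every side.
# Requires p <= dim on both axes.
pad_reflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p > nr || p > nc) {
    stop("padding (", p, ") exceeds image extent (", nr, "x", nc, ")")
  }
  ri <- c(p:1, seq_len(nr), nr:(nr - p + 1))
  ci <- c(p:1, seq_len(nc), nc:(nc - p + 1))
  m[ri, ci, drop = FALSE]
}

# Summed-area table with a zero first row/column, so that the sum of
# m[i0:i1, j0:j1] is S[i1+1,j1+1] - S[i0,j1+1] - S[i1+1,j0] + S[i0,j0].
sat2d <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Mean over all (2k+1)^2 windows fully inside m; result dims shrink by 2k.
box_mean <- function(m, k) {
  s <- sat2d(m)
  w <- 2L * k + 1L
  nr <- nrow(m) - 2L * k
  nc <- ncol(m) - 2L * k
  i1 <- seq_len(nr) + 2L * k
  j1 <- seq_len(nc) + 2L * k
  (s[i1 + 1L, j1 + 1L, drop = FALSE] - s[i1 + 1L - w, j1 + 1L, drop = FALSE] -
     s[i1 + 1L, j1 + 1L - w, drop = FALSE] +
     s[i1 + 1L - w, j1 + 1L - w, drop = FALSE]) / (w * w)
}

# 2D median filter with odd window `win`, replicate borders.
med2d <- function(m, win = 5L) {
  stopifnot(win %% 2L == 1L)
  k <- (win - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  vals <- matrix(NA_real_, nr * nc, win * win)
  idx <- 1L
  for (di in -k:k) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    for (dj in -k:k) {
      ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
      vals[, idx] <- m[ri, ci]
      idx <- idx + 1L
    }
  }
  matrix(apply(vals, 1L, median), nr, nc)
}

# Dice coefficient between two logical arrays of identical shape.
dice_coef <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary <- function(x) all(x %in% c(0, 1))

# Deterministic per-item seeds below 2^31 derived from a master seed.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
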