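# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Naive per-pixel multiscale saliency: symmetric mirror padding, explicit
# double loop over pixels, mean Lab vectors of inner square and annulus.
oracle_saliency <- function(lab, half_width, neigh_width) {
  d <- dim(lab)
  p <- half_width + neigh_width
  ri <- c(p:1, seq_len(d[1]), d[1]:(d[1] - p + 1))
  ci <- c(p:1, seq_len(d[2]), d[2]:(d[2] - p + 1))
  padded <- lab[ri, ci, , drop = FALSE]
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      pi <- i + p; pj <- j + p
      s2 <- 0
      for (ch in 1:3) {
        inner <- padded[(pi - half_width):(pi + half_width),
                        (pj - half_width):(pj + half_width), ch]
        outer <- padded[(pi - p):(pi + p), (pj - p):(pj + p), ch]
        v1 <- mean(inner)
        v2 <- (sum(outer) - sum(inner)) / (length(outer) - length(inner))
        s2 <- s2 + (v1 - v2)^2
      }
      out[i, j] <- sqrt(s2)
    }
  }
  out
}

# 26-connectivity flood fill on a 3D logical array; returns the label array.
oracle_flood3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nextlab <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    lab[s] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- ci + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nextlab
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Exhaustive enumeration of all feasible left-to-right paths through a
# cost matrix (rows = positions, cols = states, |step| <= max_jump);
# returns the minimum total cost. Grows the full path set column by
# column, so only usable on small grids.
oracle_min_path_cost <- function(cost, max_jump) {
  n <- nrow(cost); m <- ncol(cost)
  paths <- matrix(seq_len(m), ncol = 1)
  for (i in 2:n) {
    prev <- paths[, i - 1]
    reps <- lapply(seq_len(m), function(z) {
      keep <- abs(prev - z) <= max_jump
      if (!any(keep)) return(NULL)
      cbind(paths[keep, , drop = FALSE], z)
    })
    paths <- do.call(rbind, reps)
  }
  costs <- rowSums(matrix(cost[cbind(rep(seq_len(n), each = nrow(paths)),
                                     as.vector(paths))],
                          nrow(paths), n))
  min(costs)
}

# Textbook Pearson r, two-sided t-test p-value and OLS line.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my))
  r <- sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  slope <- sxy / sum((x - mx)^2)
  list(r = r, p = p, slope = slope, intercept = my - slope * mx)
}

dice2 <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Small default phantom configuration used across tests.
test_phantom_config <- function(...) {
  phantom_config(grid_dims = c(128L, 32L, 256L), ...)
}
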