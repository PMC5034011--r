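# Independent oracles used to validate the package's own algorithms.
# They share no code with the implementation paths they check.

# Exhaustive search over all admissible contour paths of a small cost
# grid: every combination of per-column steps in [-max_step, max_step],
# every starting radius. Returns the optimal total objective
# (sum of costs + lambda * sum |step|); closed paths additionally satisfy
# |r_last - r_first| <= max_step.
brute_force_path_cost <- function(cost, lambda, max_step, closed = FALSE) {
  n <- nrow(cost)
  R <- ncol(cost)
  steps <- as.matrix(expand.grid(rep(list(seq.int(-max_step, max_step)),
                                     n - 1)))
  cum <- steps
  if (ncol(cum) > 1)
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + steps[, j]
  pen <- lambda * rowSums(abs(steps))
  best <- Inf
  for (r0 in seq_len(R)) {
    radii <- cbind(r0, r0 + cum)
    ok <- rowSums(radii < 1 | radii > R) == 0
    if (closed) ok <- ok & abs(radii[, n] - r0) <= max_step
    if (!any(ok)) next
    rad <- radii[ok, , drop = FALSE]
    tot <- pen[ok]
    for (t in seq_len(n)) tot <- tot + cost[t, rad[, t]]
    best <- min(best, min(tot))
  }
  best
}

# Recompute a path's objective directly from the cost grid.
path_objective <- function(cost, path, lambda) {
  n <- length(path)
  sum(cost[cbind(seq_len(n), path)]) + lambda * sum(abs(diff(path)))
}

# Finite-difference oracle for fully developed laminar flow through an
# elliptical duct: solves -laplace(v) = 1 on the ellipse x^2/a^2 +
# y^2/b^2 < 1 with v = 0 on the boundary (Shortley-Weller boundary
# treatment on an n x n grid), rescales v so the flow matches Q, and
# extracts the boundary shear mu * dv/dn at the requested ellipse
# parameter angles by quadratic extrapolation along the inward normal.
# Units are SI (metres); returns shear in Pa.
poisson_duct_wss <- function(a, b, mu, Q, phi, n = 200) {
  requireNamespace("Matrix", quietly = TRUE)
  x <- seq(-a, a, length.out = n)
  y <- seq(-b, b, length.out = n)
  hx <- x[2] - x[1]
  hy <- y[2] - y[1]
  inside <- outer(x, y, function(xx, yy) xx^2 / a^2 + yy^2 / b^2 < 1)
  idx <- matrix(0L, n, n)
  idx[inside] <- seq_len(sum(inside))
  N <- sum(inside)

  ii <- jj <- integer(5 * N)
  vv <- numeric(5 * N)
  m <- 0L
  rhs <- rep(1, N)
  cross_x <- function(yy, sgn) sgn * a * sqrt(max(0, 1 - yy^2 / b^2))
  cross_y <- function(xx, sgn) sgn * b * sqrt(max(0, 1 - xx^2 / a^2))
  add <- function(r, c, v) {
    m <<- m + 1L
    ii[m] <<- r; jj[m] <<- c; vv[m] <<- v
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!inside[i, j]) next
    p <- idx[i, j]
    # x direction: fractional distances to the east/west neighbour or wall
    aE <- if (i < n && inside[i + 1, j]) 1 else (cross_x(y[j], 1) - x[i]) / hx
    aW <- if (i > 1 && inside[i - 1, j]) 1 else (x[i] - cross_x(y[j], -1)) / hx
    aN <- if (j < n && inside[i, j + 1]) 1 else (cross_y(x[i], 1) - y[j]) / hy
    aS <- if (j > 1 && inside[i, j - 1]) 1 else (y[j] - cross_y(x[i], -1)) / hy
    aE <- max(aE, 1e-6); aW <- max(aW, 1e-6)
    aN <- max(aN, 1e-6); aS <- max(aS, 1e-6)
    # -u_xx - u_yy = 1, Shortley-Weller weights; wall values are zero.
    add(p, p, 2 / (hx^2 * aE * aW) + 2 / (hy^2 * aN * aS))
    if (aE == 1) add(p, idx[i + 1, j], -2 / (hx^2 * aE * (aE + aW)))
    if (aW == 1) add(p, idx[i - 1, j], -2 / (hx^2 * aW * (aE + aW)))
    if (aN == 1) add(p, idx[i, j + 1], -2 / (hy^2 * aN * (aN + aS)))
    if (aS == 1) add(p, idx[i, j - 1], -2 / (hy^2 * aS * (aN + aS)))
  }
  A <- Matrix::sparseMatrix(i = ii[seq_len(m)], j = jj[seq_len(m)],
                            x = vv[seq_len(m)], dims = c(N, N))
  v <- as.numeric(Matrix::solve(A, rhs))
  V <- matrix(0, n, n)
  V[inside] <- v
  Qv <- sum(v) * hx * hy
  scale <- Q / Qv

  interp <- function(px, py) {
    fx <- (px - x[1]) / hx + 1
    fy <- (py - y[1]) / hy + 1
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    V[i0, j0] * (1 - wx) * (1 - wy) + V[i0 + 1, j0] * wx * (1 - wy) +
      V[i0, j0 + 1] * (1 - wx) * wy + V[i0 + 1, j0 + 1] * wx * wy
  }
  h <- max(hx, hy)
  vapply(phi, function(p) {
    bx <- a * cos(p); by <- b * sin(p)
    nrm <- c(cos(p) / a, sin(p) / b)
    nrm <- nrm / sqrt(sum(nrm^2))
    d1 <- 2 * h; d2 <- 4 * h
    w1 <- interp(bx - d1 * nrm[1], by - d1 * nrm[2])
    w2 <- interp(bx - d2 * nrm[1], by - d2 * nrm[2])
    mu * scale * (w1 * d2^2 - w2 * d1^2) / (d1 * d2 * (d2 - d1))
  }, numeric(1))
}
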