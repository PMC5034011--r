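# Shared small helpers: angle arithmetic, ellipse geometry, smoothing,
# seeded evaluation. Internal only.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
wrap_360 <- function(x) x %% 360

# Wrap to (-180, 180].
#' @noRd
wrap_180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' @noRd
stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# Polar radius of an ellipse (semi-axes a >= b, major axis at `psi_deg`)
# as seen from its centre, at polar angle `theta_deg`. Units follow a, b.
#' @noRd
ellipse_polar_radius <- function(theta_deg, a, b, psi_deg = 0) {
  t <- (theta_deg - psi_deg) * pi / 180
  a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

# Half support width of an ellipse measured along the axis at angle
# `view_deg` in the cross-sectional plane (projection silhouette half-width).
#' @noRd
ellipse_support_halfwidth <- function(view_deg, a, b, psi_deg = 0) {
  t <- (view_deg - psi_deg) * pi / 180
  sqrt((a * cos(t))^2 + (b * sin(t))^2)
}

# Shoelace polygon area (absolute value).
#' @noRd
polygon_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# Circular (wrap-around) moving average, odd window.
#' @noRd
moving_average_circular <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  h <- (window - 1) %/% 2
  xx <- c(x[(n - h + 1):n], x, x[1:h])
  stats::filter(xx, rep(1 / window, window), sides = 2)[(h + 1):(h + n)]
}

# Open moving average; window shrinks symmetrically near the ends.
#' @noRd
moving_average_open <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Is angle `theta` inside the (possibly wrapping) range [from, to] (degrees)?
#' @noRd
angle_in_range <- function(theta, from, to) {
  theta <- wrap_360(theta)
  from <- wrap_360(from)
  to <- wrap_360(to)
  if (from <= to) theta >= from & theta <= to
  else theta >= from | theta <= to
}
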