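# Fibrous-cap quantification in polar OCT frames.
#
# The contour model is the classical minimal-path formulation: a cost image
# derived from the signed radial intensity gradient, and the path through
# one radius per A-line that minimises
#     sum_theta cost(theta, r_theta) + lambda * sum |r_theta - r_{theta-1}|
# subject to |r_theta - r_{theta-1}| <= max_step. The front-propagation /
# back-tracking scheme is realised as the exactly equivalent first-order
# dynamic program over A-line columns.

#' Segmentation parameters
#'
#' @param lambda Smoothness weight (cost units per radial pixel of
#'   displacement). Default 0.5.
#' @param max_step Maximum radial displacement between neighbouring A-lines
#'   (pixels). Default 2.
#' @param smooth_alines Boxcar width (A-lines) applied to the intensity
#'   before the radial gradient; suppresses speckle without blurring the
#'   radial edge. Default 5.
#' @param smooth_radial Boxcar width (radial pixels) applied before the
#'   gradient. Default 1 (off), keeping step edges single-pixel sharp.
#' @param min_offset_um Minimum luminal-to-abluminal separation enforced
#'   during cap segmentation (um). Default 40, below the axial
#'   resolvability of two OCT interfaces.
#' @param subpixel Parabolic sub-pixel refinement of the extracted path.
#' @return A list of class `oct_seg_params`.
#' @export
oct_seg_params <- function(lambda = 0.5, max_step = 2, smooth_alines = 5,
                           smooth_radial = 1, min_offset_um = 40,
                           subpixel = TRUE) {
  stopifnot(lambda >= 0, is.finite(lambda), max_step >= 1,
            smooth_alines >= 1, smooth_radial >= 1, min_offset_um >= 0)
  structure(list(lambda = lambda, max_step = as.integer(max_step),
                 smooth_alines = as.integer(smooth_alines),
                 smooth_radial = as.integer(smooth_radial),
                 min_offset_um = min_offset_um, subpixel = subpixel),
            class = "oct_seg_params")
}

#' Gradient-based cost image of a polar OCT frame
#'
#' The cost is derived from the signed radial intensity gradient (backward
#' difference along the radial direction): with `dark_to_bright` polarity
#' rising edges are cheap, with `bright_to_dark` falling edges are. The
#' signed gradient is clamped at zero, divided by its robust maximum (99th
#' percentile of the positive part) and clamped at one, giving
#' `cost = 1 - g` in `[0, 1]`. A constant frame yields uniform cost 1.
#'
#' @param frame Numeric matrix, A-line index x radial index.
#' @param polarity `"dark_to_bright"` (luminal interface) or
#'   `"bright_to_dark"` (cap abluminal interface).
#' @param smooth_alines,smooth_radial Optional boxcar pre-smoothing.
#' @return Cost matrix of the same dimension, values in `[0, 1]`.
#' @export
polar_cost_image <- function(frame,
                             polarity = c("dark_to_bright", "bright_to_dark"),
                             smooth_alines = 1, smooth_radial = 1) {
  polarity <- match.arg(polarity)
  if (!is.matrix(frame) || ncol(frame) < 2)
    stop("frame must be a matrix with at least 2 radial samples",
         call. = FALSE)
  img <- frame
  if (smooth_alines > 1)
    img <- apply(img, 2, moving_average_circular, window = smooth_alines)
  if (smooth_radial > 1)
    img <- t(apply(img, 1, moving_average_open, window = smooth_radial))
  g <- img - cbind(img[, 1, drop = FALSE], img[, -ncol(img), drop = FALSE])
  g[, 1] <- 0
  if (polarity == "bright_to_dark") g <- -g
  g[g < 0] <- 0
  gpos <- g[g > 0]
  if (!length(gpos)) return(matrix(1, nrow(frame), ncol(frame)))
  gmax <- stats::quantile(gpos, 0.99, names = FALSE, type = 7)
  if (!is.finite(gmax) || gmax <= 0)
    return(matrix(1, nrow(frame), ncol(frame)))
  g <- pmin(g / gmax, 1)
  1 - g
}

# One forward pass of the column DP. cost: n x R (rows = path steps).
# start_radius: NULL for a free start, else the fixed first-step radius.
# Returns list(acc = final accumulated costs, bp = n x R backpointer
# matrix of predecessor offsets d, meaning r_prev = r + d).
#' @noRd
dp_forward <- function(cost, lambda, max_step, start_radius = NULL) {
  n <- nrow(cost)
  R <- ncol(cost)
  bp <- matrix(NA_integer_, n, R)
  acc <- cost[1, ]
  if (!is.null(start_radius)) {
    masked <- rep(Inf, R)
    masked[start_radius] <- acc[start_radius]
    acc <- masked
  }
  offs <- seq.int(-max_step, max_step)
  for (t in 2:n) {
    best <- rep(Inf, R)
    bestd <- rep(NA_integer_, R)
    for (d in offs) {
      # predecessor radius r + d
      cand <- if (d == 0) acc
      else if (d > 0) c(acc[-seq_len(d)], rep(Inf, d))
      else c(rep(Inf, -d), acc[seq_len(R + d)])
      cand <- cand + lambda * abs(d)
      better <- cand < best
      best[better] <- cand[better]
      bestd[better] <- d
    }
    acc <- best + cost[t, ]
    bp[t, ] <- bestd
  }
  list(acc = acc, bp = bp)
}

#' @noRd
dp_backtrack <- function(bp, r_end) {
  n <- nrow(bp)
  path <- integer(n)
  path[n] <- r_end
  if (n > 1) for (t in n:2) path[t - 1] <- path[t] + bp[t, path[t]]
  path
}

# Best path with the first-column radius fixed at r0 and the last-column
# radius constrained to within max_step of r0. Returns NULL when no
# admissible path exists.
#' @noRd
dp_closed_from_start <- function(cost, lambda, max_step, r0) {
  R <- ncol(cost)
  fw <- dp_forward(cost, lambda, max_step, start_radius = r0)
  win <- max(1, r0 - max_step):min(R, r0 + max_step)
  if (!any(is.finite(fw$acc[win]))) return(NULL)
  r_end <- win[which.min(fw$acc[win])]
  list(path = dp_backtrack(fw$bp, r_end), cost = fw$acc[r_end])
}

# Exact closed-path solve by branch and bound over the first-column
# starting radii: each start's cost is bounded below by its first-column
# cost plus the per-column minima of the remaining columns, so most
# starts are never expanded.
#' @noRd
dp_closed_exact <- function(cost, lambda, max_step, first_try = NULL) {
  n <- nrow(cost)
  lb_rest <- sum(apply(cost[-1, , drop = FALSE], 1, min))
  lbound <- cost[1, ] + lb_rest
  best <- NULL
  if (!is.null(first_try) && is.finite(lbound[first_try]))
    best <- dp_closed_from_start(cost, lambda, max_step, first_try)
  ord <- order(lbound)
  for (r0 in ord) {
    if (!is.finite(lbound[r0])) break
    if (!is.null(best) && lbound[r0] >= best$cost) break
    cand <- dp_closed_from_start(cost, lambda, max_step, r0)
    if (!is.null(cand) &&
        (is.null(best) || cand$cost < best$cost ||
           (cand$cost == best$cost && cand$path[1] < best$path[1])))
      best <- cand
  }
  if (is.null(best))
    stop("segmentation error: no admissible closed path", call. = FALSE)
  best
}

#' Extract the optimal contour path from a cost image
#'
#' Finds the path (one radial position per column of `cost`, restricted to
#' `span`) minimising the data-attachment plus smoothness objective, by
#' accumulate-then-backtrack dynamic programming. For closed contours the
#' endpoint constraint `|r_last - r_first| <= max_step` is enforced in
#' addition; the solution is exact (the free-endpoint optimum is accepted
#' when it already satisfies the closure constraint, otherwise the
#' admissible first-column starting radii are searched exhaustively with
#' branch-and-bound pruning). Ties are broken toward the smaller radius.
#'
#' @param cost Cost matrix (A-lines x radial), e.g. [polar_cost_image()].
#' @param span Integer column indices forming the angular span (ordered;
#'   may wrap). Default: all columns.
#' @param lambda Smoothness weight per radial pixel.
#' @param max_step Maximum radial step between neighbouring columns.
#' @param closed Close the contour across the span ends?
#' @return Integer vector of radial indices along `span`, with attributes
#'   `span` and `cost` (total objective value).
#' @export
extract_contour <- function(cost, span = NULL, lambda = 0.5, max_step = 2,
                            closed = FALSE) {
  stopifnot(is.matrix(cost), is.finite(lambda), lambda >= 0, max_step >= 1)
  span <- span %||% seq_len(nrow(cost))
  if (!length(span)) stop("segmentation error: empty span", call. = FALSE)
  sub <- cost[span, , drop = FALSE]
  if (!any(is.finite(sub)))
    stop("segmentation error: no admissible path (all costs infinite)",
         call. = FALSE)
  n <- nrow(sub)
  if (n == 1) {
    r <- which.min(sub[1, ])
    return(structure(r, span = span, cost = sub[1, r]))
  }
  if (!closed) {
    fw <- dp_forward(sub, lambda, max_step)
    if (!any(is.finite(fw$acc)))
      stop("segmentation error: no admissible path under max_step",
           call. = FALSE)
    r_end <- which.min(fw$acc)
    path <- dp_backtrack(fw$bp, r_end)
    return(structure(path, span = span, cost = fw$acc[r_end]))
  }
  # Closed: same objective as the open path (the wrap transition is
  # constrained, not penalised), solved on the span order directly.
  fw <- dp_forward(sub, lambda, max_step)
  r_end <- which.min(fw$acc)
  open_path <- if (is.finite(fw$acc[r_end])) dp_backtrack(fw$bp, r_end)
  if (!is.null(open_path) &&
      abs(open_path[n] - open_path[1]) <= max_step) {
    # The free-endpoint optimum already satisfies the closure constraint;
    # it bounds the closed optimum from below, hence is the closed optimum.
    path <- open_path
    total <- fw$acc[r_end]
  } else {
    sol <- dp_closed_exact(sub, lambda, max_step,
                           first_try = open_path[1])
    path <- sol$path
    total <- sol$cost
  }
  structure(path, span = span, cost = total)
}

# Sub-pixel refinement of a path on its cost image: per column, re-centre
# on the local cost minimum within +/- `window` pixels of the DP path
# (the smoothness penalty lags the path by up to a pixel or two on
# monotone interface slopes), then fit a parabola through the minimum and
# its neighbours. Ties go to the smaller radius.
#' @noRd
refine_subpixel <- function(cost, span, path, window = 2) {
  r <- as.numeric(path)
  n_r <- ncol(cost)
  for (k in seq_along(path)) {
    i <- span[k]
    win <- max(1, path[k] - window):min(n_r, path[k] + window)
    j <- win[which.min(cost[i, win])]
    if (!is.finite(cost[i, j])) next
    r[k] <- j
    if (j > 1 && j < n_r) {
      c0 <- cost[i, j]; cm <- cost[i, j - 1]; cp <- cost[i, j + 1]
      den <- cm - 2 * c0 + cp
      if (is.finite(den) && den > 0) {
        d <- 0.5 * (cm - cp) / den
        r[k] <- j + max(-0.5, min(0.5, d))
      }
    }
  }
  r
}

# Pixel-to-physical conversion: the backward radial difference at pixel j
# measures the gradient at the inter-pixel position (j - 1) * pixel, i.e.
# half a pixel proximal to the pixel centre at (j - 0.5) * pixel. Contour
# radii index the gradient position.
#' @noRd
new_contour <- function(alines, radius_px, radial_pixel_um, n_alines,
                        closed, frame_index = NA_integer_, z_mm = NA_real_) {
  structure(
    list(alines = as.integer(alines), radius_px = radius_px,
         radius_um = (radius_px - 1) * radial_pixel_um,
         radial_pixel_um = radial_pixel_um, n_alines = as.integer(n_alines),
         closed = closed, frame_index = frame_index, z_mm = z_mm),
    class = "oct_contour")
}

#' @export
print.oct_contour <- function(x, ...) {
  cat(sprintf("<oct_contour> %s, %d A-lines, radius %.0f-%.0f um\n",
              if (x$closed) "closed" else "open", length(x$alines),
              min(x$radius_um), max(x$radius_um)))
  invisible(x)
}

#' @noRd
pullback_frame <- function(pullback, frame) {
  k <- match(frame, pullback$frame_index)
  if (is.na(k)) stop("frame ", frame, " was not rendered in this pullback",
                     call. = FALSE)
  pullback$frames[[k]]
}

#' Segment the luminal interface of one polar OCT frame
#'
#' Closed contour over the entire circumference, via the dark-to-bright
#' radial cost image and the closed dynamic-programming path.
#'
#' @param pullback An `oct_pullback`.
#' @param frame Frame index within the pullback.
#' @param params An [oct_seg_params()].
#' @return An `oct_contour` (closed, one radius per A-line).
#' @export
segment_lumen <- function(pullback, frame, params = oct_seg_params()) {
  img <- pullback_frame(pullback, frame)
  cost <- polar_cost_image(img, "dark_to_bright",
                           smooth_alines = params$smooth_alines,
                           smooth_radial = params$smooth_radial)
  path <- extract_contour(cost, lambda = params$lambda,
                          max_step = params$max_step, closed = TRUE)
  r <- if (params$subpixel) refine_subpixel(cost, seq_len(nrow(cost)), path)
  else as.numeric(path)
  new_contour(seq_len(pullback$n_alines), r, pullback$radial_pixel_um,
              pullback$n_alines, closed = TRUE, frame_index = frame,
              z_mm = (frame - 1) * pullback$inter_frame_um / 1000)
}

# Integer A-line sequence of a (possibly wrapping) ROI span.
#' @noRd
roi_aline_span <- function(alines, n_alines) {
  a0 <- alines[1]; a1 <- alines[2]
  if (a0 <= a1) seq.int(a0, a1)
  else c(seq.int(a0, n_alines), seq.int(1, a1))
}

#' Segment the cap abluminal interface within a region of interest
#'
#' Open contour over the ROI's A-line span, restricted to radii strictly
#' deeper than the luminal contour plus a minimum offset, via the
#' bright-to-dark radial cost image.
#'
#' @param pullback An `oct_pullback`.
#' @param frame Frame index.
#' @param roi List with `alines = c(first, last)` (may wrap).
#' @param lumen The frame's luminal `oct_contour`.
#' @param params An [oct_seg_params()].
#' @return An `oct_contour` (open, on the ROI span).
#' @export
segment_cap_abluminal <- function(pullback, frame, roi, lumen,
                                  params = oct_seg_params()) {
  img <- pullback_frame(pullback, frame)
  span <- roi_aline_span(roi$alines, pullback$n_alines)
  cost <- polar_cost_image(img, "bright_to_dark",
                           smooth_alines = params$smooth_alines,
                           smooth_radial = params$smooth_radial)
  off_px <- params$min_offset_um / pullback$radial_pixel_um
  floor_px <- lumen$radius_px + off_px
  min_r <- floor(floor_px)   # admissible radii are strictly deeper
  for (i in span) {
    lo <- min(min_r[i], ncol(cost))
    if (lo >= 1) cost[i, seq_len(lo)] <- Inf
  }
  if (all(!is.finite(cost[span, ])))
    stop("segmentation error: no admissible abluminal path below the ",
         "scan depth", call. = FALSE)
  path <- extract_contour(cost, span = span, lambda = params$lambda,
                          max_step = params$max_step, closed = FALSE)
  r <- if (params$subpixel) refine_subpixel(cost, span, path)
  else as.numeric(path)
  r <- pmax(r, floor_px[span])   # hard ordering constraint survives refinement
  new_contour(span, r, pullback$radial_pixel_um, pullback$n_alines,
              closed = FALSE, frame_index = frame,
              z_mm = (frame - 1) * pullback$inter_frame_um / 1000)
}

#' Cap thickness along luminal normals
#'
#' Converts both contours to Cartesian millimetres, estimates the luminal
#' tangent from centred differences after an 11-A-line circular moving
#' average of the luminal radius, and measures for each ROI A-line the
#' distance from the luminal point to the abluminal polyline along the
#' inward (into-the-wall) normal ray. Rays that miss the abluminal
#' polyline are flagged missing and excluded from the summary.
#'
#' @param lumen Closed luminal `oct_contour`.
#' @param abluminal Open abluminal `oct_contour` (on the ROI span).
#' @param smooth_window Circular moving-average window for the tangent
#'   estimate (A-lines). Default 11.
#' @return A `thickness_profile`: data frame `samples` (aline,
#'   thickness_um, missing) plus `min_um`, `mean_um`, `sd_um`, `degenerate`.
#' @export
thickness_profile <- function(lumen, abluminal, smooth_window = 11) {
  stopifnot(inherits(lumen, "oct_contour"), inherits(abluminal, "oct_contour"))
  if (!lumen$closed) stop("luminal contour must be closed", call. = FALSE)
  n <- lumen$n_alines
  phi <- (lumen$alines - 1) * 2 * pi / n
  r_mm <- lumen$radius_um / 1000
  px <- r_mm * cos(phi)
  py <- r_mm * sin(phi)
  rs <- moving_average_circular(r_mm, smooth_window)
  sx <- rs * cos(phi)
  sy <- rs * sin(phi)
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  tx <- sx[ip] - sx[im]
  ty <- sy[ip] - sy[im]
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl
  ny <- tx / tl
  flip <- (nx * px + ny * py) < 0   # orient into the wall (outward)
  nx[flip] <- -nx[flip]
  ny[flip] <- -ny[flip]

  aphi <- (abluminal$alines - 1) * 2 * pi / n
  ar <- abluminal$radius_um / 1000
  qx <- ar * cos(aphi)
  qy <- ar * sin(aphi)

  span <- abluminal$alines
  thick <- rep(NA_real_, length(span))
  nseg <- length(qx) - 1
  for (k in seq_along(span)) {
    i <- span[k]
    t_hit <- ray_polyline_distance(px[i], py[i], nx[i], ny[i], qx, qy)
    if (is.finite(t_hit)) thick[k] <- t_hit * 1000
  }
  ok <- is.finite(thick)
  degenerate <- any(ok & thick <= 1e-6)
  samples <- data.frame(aline = span, thickness_um = thick, missing = !ok)
  structure(
    list(samples = samples,
         min_um = if (any(ok)) min(thick[ok]) else NA_real_,
         mean_um = if (any(ok)) mean(thick[ok]) else NA_real_,
         sd_um = if (sum(ok) > 1) stats::sd(thick[ok]) else NA_real_,
         degenerate = degenerate,
         frame_index = abluminal$frame_index, z_mm = abluminal$z_mm,
         n_alines = n),
    class = "thickness_profile")
}

# Smallest positive ray parameter t with P + t*d on the polyline Q;
# Inf if the ray misses. Handles single-point polylines by projecting
# onto the ray within a small transverse tolerance.
#' @noRd
ray_polyline_distance <- function(px, py, dx, dy, qx, qy) {
  m <- length(qx)
  if (m == 1) {
    t <- (qx - px) * dx + (qy - py) * dy
    perp <- abs(-(qx - px) * dy + (qy - py) * dx)
    return(if (t > -1e-9 && perp < 1e-6) max(t, 0) else Inf)
  }
  ax <- qx[-m]; ay <- qy[-m]
  bx <- qx[-1]; by <- qy[-1]
  ex <- bx - ax; ey <- by - ay
  den <- dx * ey - dy * ex
  t <- ((ax - px) * ey - (ay - py) * ex) / den
  u <- ((ax - px) * dy - (ay - py) * dx) / den
  hit <- is.finite(t) & abs(den) > 1e-15 & u >= -1e-9 & u <= 1 + 1e-9 &
    t >= -1e-9
  if (!any(hit)) return(Inf)
  max(min(t[hit]), 0)
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf(
    "<thickness_profile> frame %s: min %.0f um, mean %.0f um (sd %.0f), %d/%d samples\n",
    as.character(x$frame_index), x$min_um, x$mean_um, x$sd_um,
    sum(!x$samples$missing), nrow(x$samples)))
  invisible(x)
}

#' Representative cap thickness
#'
#' The average of a collection of cross-sectional measurements taken at a
#' fixed number of randomly selected sites per frame, on frames spaced
#' every `spacing_mm` along the pullback direction throughout the plaque.
#'
#' @param profiles List of `thickness_profile` objects (one per frame).
#' @param spacing_mm Longitudinal sampling interval (mm). Default 0.5.
#' @param sites Measurement sites drawn per selected frame, uniformly
#'   without replacement among valid ROI A-lines. Default 5.
#' @param seed Integer seed for the site draw.
#' @return Representative thickness (um, grand mean over all drawn sites).
#' @export
representative_thickness <- function(profiles, spacing_mm = 0.5, sites = 5,
                                     seed = 1) {
  stopifnot(spacing_mm > 0, sites >= 1, length(profiles) >= 1)
  z <- vapply(profiles, function(p) p$z_mm, numeric(1))
  o <- order(z)
  profiles <- profiles[o]
  z <- z[o]
  targets <- seq(z[1], z[length(z)], by = spacing_mm)
  sel <- unique(vapply(targets, function(t) which.min(abs(z - t)),
                       integer(1)))
  vals <- with_seed(seed, {
    unlist(lapply(profiles[sel], function(p) {
      ok <- which(!p$samples$missing)
      if (!length(ok)) return(numeric(0))
      if (length(ok) < sites)
        warning("ROI narrower than the requested number of sites; using all ",
                length(ok), " available A-lines", call. = FALSE)
      take <- if (length(ok) <= sites) ok else sample(ok, sites)
      p$samples$thickness_um[take]
    }))
  })
  mean(vals)
}

#' Lumen area of a closed contour
#'
#' Shoelace polygon area of the Cartesian-converted contour.
#'
#' @param contour Closed `oct_contour`.
#' @return Area in mm^2.
#' @export
lumen_area <- function(contour) {
  stopifnot(inherits(contour, "oct_contour"))
  if (!contour$closed)
    stop("lumen_area requires a closed contour", call. = FALSE)
  phi <- (contour$alines - 1) * 2 * pi / contour$n_alines
  r <- contour$radius_um / 1000
  polygon_area(r * cos(phi), r * sin(phi))
}
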