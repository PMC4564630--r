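#' Interpolating Catmull-Rom spline through digitized points
#'
#' Reconstructs an ordered sequence of digitized 3D points (medial attachment
#' first, lateral last) as an interpolating C1 piecewise-cubic Catmull-Rom
#' curve. Endpoint segments use phantom points obtained by reflection
#' (`2*P1 - P2`), which preserves the direction of the terminal chord. Knots
#' follow the centripetal convention by default (squared-chord exponent 0.5),
#' which avoids cusps and self-intersections on unevenly spaced digitized
#' points; the explicit arc-length reparameterization applied downstream makes
#' fiber bundle length and pennation angles insensitive to this choice.
#'
#' @param points An n x 3 numeric matrix (or data frame with columns
#'   `x`,`y`,`z` or `x_cm`,`y_cm`,`z_cm`) of ordered digitized coordinates in
#'   cm; n >= 4, consecutive points distinct.
#' @param parameterization Knot spacing rule: `"centripetal"` (default),
#'   `"chordal"` or `"uniform"`.
#' @return An object of class `catmull_rom` with the control points, knot
#'   vector and parameterization. Use [fiber_bundle_length()],
#'   [arclength_resample()], [end_tangent()] and [spline_points()] on it.
#' @examples
#' pts <- cbind(x = 0:4, y = c(0, 0.3, 0.5, 0.3, 0), z = 0)
#' crv <- catmull_rom(pts)
#' fiber_bundle_length(crv)
#' @export
catmull_rom <- function(points,
                        parameterization = c("centripetal", "chordal", "uniform")) {
  parameterization <- match.arg(parameterization)
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 4) {
    abort(sprintf("A fiber bundle needs at least 4 digitized points, got %d.", n))
  }
  seg <- diff(pts)
  seg_len <- row_norms(seg)
  dup <- which(seg_len < 1e-12)
  if (length(dup) > 0) {
    abort(sprintf(
      "Consecutive digitized points %d and %d coincide; remove the duplicate.",
      dup[1], dup[1] + 1
    ))
  }
  alpha <- switch(parameterization,
    uniform = 0, centripetal = 0.5, chordal = 1
  )
  knots <- c(0, cumsum(seg_len^alpha))

  # phantom points by reflection about each terminal control point
  p_head <- 2 * pts[1, ] - pts[2, ]
  p_tail <- 2 * pts[n, ] - pts[n - 1, ]
  ext_pts <- rbind(p_head, pts, p_tail)
  ext_knots <- c(
    knots[1] - vnorm(pts[1, ] - p_head)^alpha,
    knots,
    knots[n] + vnorm(p_tail - pts[n, ])^alpha
  )

  structure(
    list(
      control_points = pts,
      knots = knots,
      parameterization = parameterization,
      alpha = alpha,
      ext_points = unname(ext_pts),
      ext_knots = ext_knots
    ),
    class = "catmull_rom"
  )
}

#' @export
print.catmull_rom <- function(x, ...) {
  cat(sprintf(
    "<catmull_rom> %d control points, %s knots, span %.3f cm (chord)\n",
    nrow(x$control_points), x$parameterization,
    vnorm(x$control_points[nrow(x$control_points), ] - x$control_points[1, ])
  ))
  invisible(x)
}

# Barry-Goldman evaluation of one Catmull-Rom segment, vectorized over t.
# P is 4 x 3 (P0..P3), tk the 4 knots, t within [tk[2], tk[3]].
cr_segment_eval <- function(P, tk, t) {
  lerp <- function(a, b, ta, tb) {
    w <- (t - ta) / (tb - ta)
    (1 - w) %o% a + w %o% b
  }
  A1 <- lerp(P[1, ], P[2, ], tk[1], tk[2])
  A2 <- lerp(P[2, ], P[3, ], tk[2], tk[3])
  A3 <- lerp(P[3, ], P[4, ], tk[3], tk[4])
  mix <- function(Ma, Mb, ta, tb) {
    w <- (t - ta) / (tb - ta)
    Ma * (1 - w) + Mb * w
  }
  B1 <- mix(A1, A2, tk[1], tk[3])
  B2 <- mix(A2, A3, tk[2], tk[4])
  mix(B1, B2, tk[2], tk[3])
}

# Evaluate the curve at arbitrary knot-parameter values (clamped to the
# digitized span). Vectorized; segments are processed in batches.
cr_eval <- function(curve, t) {
  kn <- curve$knots
  n <- length(kn)
  t <- pmin(pmax(t, kn[1]), kn[n])
  seg <- findInterval(t, kn, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), n - 1L)
  out <- matrix(0, length(t), 3)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    P <- curve$ext_points[s:(s + 3), , drop = FALSE]
    tk <- curve$ext_knots[s:(s + 3)]
    out[idx, ] <- cr_segment_eval(P, tk, t[idx])
  }
  colnames(out) <- c("x", "y", "z")
  out
}

# Unit tangents at knot-parameter values via central differences.
cr_tangent <- function(curve, t) {
  kn <- curve$knots
  span <- kn[length(kn)] - kn[1]
  h <- span * 1e-6
  tp <- pmin(t + h, kn[length(kn)])
  tm <- pmax(t - h, kn[1])
  d <- cr_eval(curve, tp) - cr_eval(curve, tm)
  d / row_norms(d)
}

# Dense arc-length table: per-segment uniform parameter sampling with
# cumulative chord summation. Shared by length, resampling and tangents.
cr_dense <- function(curve, subdivisions = 200) {
  kn <- curve$knots
  n_seg <- length(kn) - 1L
  t_dense <- unlist(lapply(seq_len(n_seg), function(s) {
    tt <- seq(kn[s], kn[s + 1], length.out = subdivisions + 1L)
    if (s < n_seg) tt[-length(tt)] else tt
  }))
  pts <- cr_eval(curve, t_dense)
  s_cum <- c(0, cumsum(row_norms(diff(pts))))
  list(t = t_dense, points = pts, s = s_cum)
}

# Map target arc positions to knot parameters through the dense table.
cr_param_at_arclength <- function(dense, s_target) {
  stats::approx(dense$s, dense$t, xout = s_target, ties = "ordered")$y
}

#' Fiber bundle length: total arc length of the reconstructed spline
#'
#' The length of a digitized fascicle is the entire arc length of its
#' interpolating spline, computed by dense per-segment sampling with
#' cumulative chord summation. It is bounded below by the endpoint chord and
#' is invariant under rigid motion of the digitized points.
#'
#' @param curve A [catmull_rom()] curve.
#' @param subdivisions Per-segment quadrature subdivisions (default 200).
#' @return Arc length in cm.
#' @export
fiber_bundle_length <- function(curve, subdivisions = 200) {
  stopifnot(inherits(curve, "catmull_rom"))
  dense <- cr_dense(curve, subdivisions)
  unname(tail(dense$s, 1))
}

#' Resample a spline uniformly in arc length
#'
#' Populates `n_samples` points equally spaced along the curve's arc length,
#' the first and last coinciding with the digitized endpoints. The points are
#' exact curve evaluations at parameters found by inverting a dense
#' arc-length table.
#'
#' @inheritParams fiber_bundle_length
#' @param n_samples Number of uniformly spaced samples (>= 2; default 100).
#' @return The curve with components `uniform_samples` (n_samples x 3 matrix),
#'   `sample_arclengths` and `total_arc_length` filled in.
#' @export
arclength_resample <- function(curve, n_samples = 100, subdivisions = 200) {
  stopifnot(inherits(curve, "catmull_rom"))
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  dense <- cr_dense(curve, subdivisions)
  total <- tail(dense$s, 1)
  s_target <- seq(0, total, length.out = n_samples)
  t_target <- cr_param_at_arclength(dense, s_target)
  samples <- cr_eval(curve, t_target)
  npts <- nrow(curve$control_points)
  samples[1, ] <- curve$control_points[1, ]
  samples[n_samples, ] <- curve$control_points[npts, ]
  curve$uniform_samples <- samples
  curve$sample_arclengths <- s_target
  curve$total_arc_length <- unname(total)
  curve
}

#' Average end tangent of a fascicle spline
#'
#' The fascicle orientation at an attachment site is estimated as the
#' normalized average of unit tangent vectors sampled over the terminal
#' fraction of the curve's arc length (default 10%, 20 evenly spaced arc
#' positions), which is stable against digitization noise near the
#' attachment. The tangent is oriented in the medial-to-lateral direction of
#' traversal at both ends.
#'
#' @inheritParams fiber_bundle_length
#' @param end `"medial"` (start of the digitized order) or `"lateral"`.
#' @param region_fraction Fraction of total arc length averaged over, in
#'   (0, 0.5] (default 0.10).
#' @param tangent_samples Number of arc positions averaged (default 20).
#' @return A unit 3-vector.
#' @export
end_tangent <- function(curve, end = c("medial", "lateral"),
                        region_fraction = 0.10, tangent_samples = 20,
                        subdivisions = 200) {
  stopifnot(inherits(curve, "catmull_rom"))
  end <- match.arg(end)
  if (!is.numeric(region_fraction) || region_fraction <= 0 || region_fraction > 0.5) {
    abort("`region_fraction` must lie in (0, 0.5].")
  }
  dense <- cr_dense(curve, subdivisions)
  end_tangent_dense(curve, dense, end, region_fraction, tangent_samples)
}

# Shared fast path: tangent averaging against a precomputed dense table.
end_tangent_dense <- function(curve, dense, end, region_fraction, tangent_samples) {
  total <- tail(dense$s, 1)
  s_window <- if (end == "medial") {
    seq(0, region_fraction * total, length.out = tangent_samples)
  } else {
    seq((1 - region_fraction) * total, total, length.out = tangent_samples)
  }
  t_window <- cr_param_at_arclength(dense, s_window)
  tangents <- cr_tangent(curve, t_window)
  unitize(colMeans(tangents), "average end tangent")
}

#' Evaluate spline points
#'
#' Convenience evaluation of a fitted curve at parameters spaced uniformly in
#' the knot domain (not in arc length; see [arclength_resample()] for that).
#'
#' @inheritParams fiber_bundle_length
#' @param n Number of evaluation points.
#' @return An n x 3 matrix of coordinates.
#' @export
spline_points <- function(curve, n = 200) {
  stopifnot(inherits(curve, "catmull_rom"))
  kn <- curve$knots
  cr_eval(curve, seq(kn[1], kn[length(kn)], length.out = n))
}
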