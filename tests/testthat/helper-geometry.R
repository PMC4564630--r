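# Geometric fixtures built in code: analytic curves with known arc length
# and tangents, and random rigid motions.

# n points on a circular arc of radius r spanning `angle` radians in the
# xy-plane, starting at (r, 0, 0).
circle_arc_points <- function(n, r = 10, angle = pi / 2) {
  th <- seq(0, angle, length.out = n)
  cbind(x = r * cos(th), y = r * sin(th), z = 0)
}

# n points on a helix of radius r and pitch (rise per turn), `turns` turns.
helix_points <- function(n, r = 1, pitch = 0.5, turns = 1) {
  th <- seq(0, 2 * pi * turns, length.out = n)
  cbind(x = r * cos(th), y = r * sin(th), z = pitch * th / (2 * pi))
}

helix_arc_length <- function(r = 1, pitch = 0.5, turns = 1) {
  2 * pi * turns * sqrt(r^2 + (pitch / (2 * pi))^2)
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(points, R, t) {
  sweep(points %*% t(R), 2, -t)
}

# straight fascicle of given length at `angle_deg` to the x-axis (in-plane)
straight_bundle <- function(length_cm = 5, angle_deg = 20, n = 12) {
  d <- c(cos(fascicle3d_deg2rad(angle_deg)), sin(fascicle3d_deg2rad(angle_deg)), 0)
  s <- seq(0, length_cm, length.out = n)
  outer(s, d)
}

fascicle3d_deg2rad <- function(x) x * pi / 180

# minimal long-format point rows for constructed bundles
points_row_block <- function(specimen_id, record_type, record_id, region,
                             part, pts, layer_depth_mm = 0) {
  tibble::tibble(
    specimen_id = specimen_id, record_type = record_type,
    record_id = record_id, region = region, part = part,
    layer_depth_mm = layer_depth_mm, point_index = seq_len(nrow(pts)),
    x_cm = pts[, 1], y_cm = pts[, 2], z_cm = pts[, 3]
  )
}

test_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
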