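test_that("the spline interpolates every digitized point", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    pts <- cbind(sort(runif(n, 0, 8)), cumsum(rnorm(n, 0, 0.4)),
                 cumsum(rnorm(n, 0, 0.2)))
    crv <- catmull_rom(pts)
    at_knots <- fascicle3d:::cr_eval(crv, crv$knots)
    expect_lt(max(sqrt(rowSums((at_knots - pts)^2))), 1e-9)
  }
})

test_that("collinear digitized points reconstruct to the straight segment", {
  pts <- cbind(c(0, 1, 2, 3), 0, 0)
  crv <- catmull_rom(pts)
  dense <- fascicle3d:::cr_eval(crv, seq(0, max(crv$knots), length.out = 500))
  expect_lt(max(abs(dense[, 2:3])), 1e-9)
  expect_equal(fiber_bundle_length(crv), 3, tolerance = 1e-6)
})

test_that("fit rejects short or degenerate inputs, naming the offender", {
  expect_error(catmull_rom(cbind(0:2, 0, 0)), "at least 4")
  pts <- cbind(c(0, 1, 1, 2, 3), 0, 0)
  expect_error(catmull_rom(pts), "points 2 and 3")
})

test_that("a digitized helix is reconstructed close to the analytic curve", {
  dig <- helix_points(12, r = 1, pitch = 0.5, turns = 1)
  crv <- catmull_rom(dig)
  fitted <- spline_points(crv, 400)
  # oracle: dense analytic helix; distance of each fitted point to it.
  # Deviation concentrates in the terminal segments, whose shape is set by
  # the reflected phantom points; the interior tracks the helix closely.
  ref <- helix_points(5000, r = 1, pitch = 0.5, turns = 1)
  dmin <- apply(fitted, 1, function(p) {
    min(sqrt(colSums((t(ref) - p)^2)))
  })
  expect_lt(max(dmin), 0.03)
  interior <- dmin[seq_len(400) > 40 & seq_len(400) <= 360]
  expect_lt(max(interior), 0.02)
})

test_that("arc-length resampling yields uniformly spaced samples", {
  # straight 3 cm fiber, 4 samples at 0,1,2,3 cm
  crv <- catmull_rom(cbind(c(0, 1, 2, 3), 0, 0))
  rs <- arclength_resample(crv, 4)
  expect_equal(rs$uniform_samples[, 1], c(0, 1, 2, 3), tolerance = 1e-6)

  # n = 2 gives the endpoints only
  rs2 <- arclength_resample(crv, 2)
  expect_equal(rs2$uniform_samples, crv$control_points[c(1, 4), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(arclength_resample(crv, 1), "at least 2")

  # quarter circle r = 10 digitized at 15 points, 50 samples:
  # spacings within 0.5% of arc/49 (oracle: analytic arc positions)
  crv3 <- catmull_rom(circle_arc_points(15, r = 10, angle = pi / 2))
  rs3 <- arclength_resample(crv3, 50)
  gaps <- sqrt(rowSums(diff(rs3$uniform_samples)^2))
  expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 0.005)
  expect_equal(rs3$total_arc_length / 49, mean(gaps), tolerance = 0.001)
})

test_that("fiber bundle length matches analytic arc lengths and rigid invariance", {
  # quarter circle r = 10: analytic length 5*pi
  crv <- catmull_rom(circle_arc_points(15, r = 10, angle = pi / 2))
  L <- fiber_bundle_length(crv)
  expect_lt(abs(L - 5 * pi) / (5 * pi), 0.005)

  set.seed(53)
  pts <- circle_arc_points(15, r = 10, angle = pi / 2)
  for (i in 1:25) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    L2 <- fiber_bundle_length(catmull_rom(sweep(pts %*% t(R), 2, -t)))
    expect_lt(abs(L2 - L), 1e-6)
  }
})

test_that("arc-length error shrinks with digitization density", {
  true_L <- helix_arc_length(r = 1, pitch = 0.5, turns = 1)
  errs <- sapply(c(5, 10, 15, 25, 50), function(n) {
    abs(fiber_bundle_length(catmull_rom(helix_points(n))) - true_L) / true_L
  })
  expect_lt(errs[3], 0.005)
  # convergence trend toward the analytic value
  expect_true(all(diff(errs) < 1e-4))
  expect_lt(errs[5], errs[1] / 10)
})

test_that("length is bounded below by the endpoint chord", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(4:15, 1)
    pts <- cbind(seq(0, 5, length.out = n), rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
    crv <- catmull_rom(pts)
    chord <- sqrt(sum((pts[n, ] - pts[1, ])^2))
    expect_gte(fiber_bundle_length(crv) + 1e-9, chord)
  }
  # equality for a straight fiber
  straight <- catmull_rom(cbind(seq(0, 5, length.out = 8), 0, 0))
  expect_equal(fiber_bundle_length(straight), 5, tolerance = 1e-6)
})

test_that("end tangents recover analytic directions and orientation", {
  crv <- catmull_rom(cbind(seq(0, 5, length.out = 10), 0, 0))
  expect_equal(end_tangent(crv, "medial"), c(1, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(end_tangent(crv, "lateral"), c(1, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(end_tangent(crv, "medial", region_fraction = 0.6), "0, 0.5")
  expect_error(end_tangent(crv, "medial", region_fraction = 0))

  # circular arc: as the averaging region shrinks the tangent approaches the
  # analytic endpoint tangent (here (0,1,0) at theta = 0 traversed forward)
  arc <- catmull_rom(circle_arc_points(60, r = 10, angle = pi / 2))
  tg <- end_tangent(arc, "medial", region_fraction = 0.02)
  ang <- acos(min(1, sum(tg * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("line of force is the principal axis oriented medial to lateral", {
  pts <- cbind(seq(0, 6, length.out = 10), 0, 0)
  lof <- estimate_line_of_force(pts)
  expect_equal(lof$direction, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(lof$anchor, colMeans(pts), tolerance = 1e-12, ignore_attr = TRUE)

  # two points: normalized difference
  lof2 <- estimate_line_of_force(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(lof2$direction, c(0.6, 0.8, 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # noisy axis: within 1 degree of x; cross-check against the eigenvector of
  # the 3x3 scatter matrix
  set.seed(71)
  noisy <- cbind(seq(0, 6, length.out = 40), runif(40, -0.05, 0.05), 0)
  lof3 <- estimate_line_of_force(noisy)
  ang <- acos(min(1, abs(lof3$direction[1]))) * 180 / pi
  expect_lt(ang, 1)
  centered <- scale(noisy, scale = FALSE)
  ev <- eigen(t(centered) %*% centered)$vectors[, 1]
  expect_lt(1 - abs(sum(ev * lof3$direction)), 1e-9)

  expect_error(estimate_line_of_force(matrix(1, 5, 3)), "coincident")
})

test_that("pennation angle is the folded acute angle and well-behaved", {
  lof <- estimate_line_of_force(cbind(0:5, 0, 0))
  expect_equal(pennation_angle(c(1, 0, 0), lof), 0)
  expect_equal(pennation_angle(c(0, 1, 0), lof), 90)
  expect_equal(pennation_angle(c(1, 1, 0) / sqrt(2), lof), 45, tolerance = 1e-9)
  expect_equal(pennation_angle(c(-1, 1, 0) / sqrt(2), lof), 45, tolerance = 1e-9)
  expect_error(pennation_angle(c(0, 0, 0), lof), "zero")

  set.seed(81)
  for (i in 1:50) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    expect_equal(pennation_angle(v, v), 0, tolerance = 1e-6)
    w <- rnorm(3)
    a <- pennation_angle(v, w)
    expect_gte(a, 0)
    expect_lte(a, 90)
    expect_equal(a, pennation_angle(w, v), tolerance = 1e-9)
  }
})

test_that("measure_bundle composes to the constructed geometry", {
  lof <- estimate_line_of_force(cbind(0:5, 0, 0))
  m <- measure_bundle(straight_bundle(5, 20), lof)
  expect_equal(m$fbl_cm, 5, tolerance = 1e-3)
  expect_equal(m$lat_pa_deg, 20, tolerance = 1e-3)
  expect_equal(m$med_pa_deg, 20, tolerance = 1e-3)

  m0 <- measure_bundle(straight_bundle(5, 0), lof)
  expect_equal(m0$lat_pa_deg, 0, tolerance = 1e-9)
  expect_equal(m0$med_pa_deg, 0, tolerance = 1e-9)

  # point-symmetric S-shaped planar bundle: lateral PA equals medial PA
  x <- seq(-2, 2, length.out = 15)
  s_pts <- cbind(x, 0.5 * sin(pi * x / 2), 0)
  ms <- measure_bundle(s_pts, lof)
  expect_equal(ms$lat_pa_deg, ms$med_pa_deg, tolerance = 1e-6)
})

test_that("measurements are rigid-invariant and scale-equivariant", {
  set.seed(91)
  pts <- cbind(seq(0, 5, length.out = 14),
               0.4 * sin(seq(0, pi, length.out = 14)), 0)
  axis_pts <- cbind(seq(0, 6, length.out = 12), 0, 0)
  base <- measure_bundle(pts, estimate_line_of_force(axis_pts))
  for (i in 1:25) {
    R <- random_rotation()
    t <- rnorm(3, sd = 5)
    m <- measure_bundle(
      sweep(pts %*% t(R), 2, -t),
      estimate_line_of_force(sweep(axis_pts %*% t(R), 2, -t))
    )
    expect_lt(abs(m$fbl_cm - base$fbl_cm), 1e-6)
    expect_lt(abs(m$lat_pa_deg - base$lat_pa_deg), 1e-6)
    expect_lt(abs(m$med_pa_deg - base$med_pa_deg), 1e-6)
  }
  for (s in c(0.3, 2.5)) {
    m <- measure_bundle(pts * s, estimate_line_of_force(axis_pts * s))
    expect_equal(m$fbl_cm, base$fbl_cm * s, tolerance = 1e-6)
    expect_equal(m$lat_pa_deg, base$lat_pa_deg, tolerance = 1e-6)
    expect_equal(m$med_pa_deg, base$med_pa_deg, tolerance = 1e-6)
  }
})

test_that("reversing the digitized order leaves pennation angles unchanged", {
  lof <- estimate_line_of_force(cbind(0:5, 0, 0))
  pts <- cbind(seq(0, 5, length.out = 12),
               0.3 * seq(0, 5, length.out = 12)^0.8, 0)
  fwd <- measure_bundle(pts, lof)
  rev_pts <- pts[nrow(pts):1, ]
  bwd <- measure_bundle(rev_pts, lof)
  expect_equal(fwd$fbl_cm, bwd$fbl_cm, tolerance = 1e-9)
  # ends swap roles; folded angles are unchanged as a set
  expect_equal(sort(c(fwd$lat_pa_deg, fwd$med_pa_deg)),
               sort(c(bwd$lat_pa_deg, bwd$med_pa_deg)), tolerance = 1e-6)
})

test_that("measure_bundles handles tables, skips short bundles, fits per-region axes", {
  ant_axis <- points_row_block("s", "tendon_axis", "a_axis", "anterior", NA,
                               cbind(seq(0, 6, length.out = 10), 0, 0))
  post_axis <- points_row_block("s", "tendon_axis", "p_axis", "posterior", NA,
                                cbind(seq(0, 6, length.out = 10), 0, 1) %*%
                                  diag(3))
  b1 <- points_row_block("s", "fiber", "b1", "anterior", "superficial",
                         straight_bundle(5, 20))
  b2 <- points_row_block("s", "fiber", "b2", "posterior", "deep",
                         straight_bundle(4, 10))
  short <- points_row_block("s", "fiber", "b3", "anterior", "middle",
                            straight_bundle(2, 5, n = 3))
  tab <- dplyr::bind_rows(ant_axis, post_axis, b1, b2, short)
  expect_warning(m <- measure_bundles(tab), "skipped")
  expect_equal(nrow(m), 2)
  expect_equal(m$lat_pa_deg[m$bundle_id == "b1"], 20, tolerance = 1e-3)
  expect_equal(m$lat_pa_deg[m$bundle_id == "b2"], 10, tolerance = 1e-3)

  no_fiber <- dplyr::bind_rows(ant_axis)
  expect_warning(empty <- measure_bundles(no_fiber), "No fiber")
  expect_equal(nrow(empty), 0)
  expect_error(measure_bundles(b1), "tendon_axis")
})
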