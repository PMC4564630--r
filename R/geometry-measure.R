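#' Geometry configuration for fascicle measurement
#'
#' Collects the numerical knobs of the measurement pipeline. Defaults follow
#' the package's standard protocol: 100 uniform arc-length samples per
#' fascicle, end tangents averaged over the terminal 10% of arc length at 20
#' positions, centripetal knots, and 200 quadrature subdivisions per spline
#' segment.
#'
#' @param n_samples Uniform arc-length samples stored per fascicle.
#' @param region_fraction Terminal arc-length fraction used for tangent
#'   averaging, in (0, 0.5].
#' @param knot_parameterization `"centripetal"`, `"chordal"` or `"uniform"`.
#' @param quadrature_subdivisions Per-segment subdivisions for arc-length
#'   quadrature.
#' @param tangent_samples Arc positions averaged per end tangent.
#' @param lof_per_region Fit one line of force per muscle region (default)
#'   rather than a single global axis.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(n_samples = 100,
                            region_fraction = 0.10,
                            knot_parameterization = c("centripetal", "chordal", "uniform"),
                            quadrature_subdivisions = 200,
                            tangent_samples = 20,
                            lof_per_region = TRUE) {
  knot_parameterization <- match.arg(knot_parameterization)
  stopifnot(n_samples >= 2, quadrature_subdivisions >= 10, tangent_samples >= 2)
  if (region_fraction <= 0 || region_fraction > 0.5) {
    abort("`region_fraction` must lie in (0, 0.5].")
  }
  structure(
    list(
      n_samples = n_samples,
      region_fraction = region_fraction,
      knot_parameterization = knot_parameterization,
      quadrature_subdivisions = quadrature_subdivisions,
      tangent_samples = tangent_samples,
      lof_per_region = lof_per_region
    ),
    class = "geometry_config"
  )
}

#' Line of force from intramuscular tendon axis points
#'
#' The muscle's line of force is the axis best approximating the digitized
#' intramuscular tendon: the first principal axis of the centered axis points
#' (total least squares line). The direction is sign-oriented medial to
#' lateral according to the input point ordering; the anchor is the centroid.
#'
#' @param axis_points An n x 3 matrix (or x/y/z data frame) of ordered points
#'   along the intramuscular tendon, medial first; n >= 2, not all coincident.
#' @return An object of class `line_of_force` with unit `direction` and
#'   `anchor`.
#' @export
estimate_line_of_force <- function(axis_points) {
  pts <- as_point_matrix(axis_points, "axis_points")
  if (nrow(pts) < 2) abort("A line of force needs at least 2 tendon axis points.")
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  if (max(row_norms(centered)) < 1e-12) {
    abort("Tendon axis points are all coincident; line of force is undefined.")
  }
  if (nrow(pts) == 2) {
    dir <- unitize(pts[2, ] - pts[1, ], "tendon axis")
  } else {
    sv <- svd(centered, nu = 0, nv = 3)
    dir <- sv$v[, 1]
    # orient medial -> lateral per the input ordering
    span <- pts[nrow(pts), ] - pts[1, ]
    if (sum(dir * span) < 0) dir <- -dir
    dir <- dir / vnorm(dir)
  }
  structure(list(direction = unname(dir), anchor = unname(centroid)),
            class = "line_of_force")
}

#' @export
print.line_of_force <- function(x, ...) {
  cat(sprintf(
    "<line_of_force> direction (%.3f, %.3f, %.3f), anchor (%.2f, %.2f, %.2f) cm\n",
    x$direction[1], x$direction[2], x$direction[3],
    x$anchor[1], x$anchor[2], x$anchor[3]
  ))
  invisible(x)
}

#' Pennation angle between a fascicle tangent and the line of force
#'
#' The acute angle between the fascicle orientation and the line of force,
#' `acos(|t . d|)` in degrees, folded to \[0, 90\]. Symmetric in its
#' arguments and invariant under joint rotation.
#'
#' @param tangent A nonzero 3-vector (normalized internally).
#' @param lof A [estimate_line_of_force()] object, or a nonzero 3-vector.
#' @return Angle in degrees in \[0, 90\].
#' @export
pennation_angle <- function(tangent, lof) {
  t_u <- unitize(as.numeric(tangent), "tangent")
  d <- if (inherits(lof, "line_of_force")) lof$direction else as.numeric(lof)
  d_u <- unitize(d, "line of force direction")
  cosang <- min(abs(sum(t_u * d_u)), 1)
  rad2deg(acos(cosang))
}

#' Measure one digitized fiber bundle
#'
#' Composition of the measurement pipeline for a single fascicle: spline fit,
#' arc-length resampling, arc length (fiber bundle length), averaged end
#' tangents, and lateral/medial pennation angles against the line of force.
#' Deterministic given the configuration.
#'
#' @param points Ordered digitized points of the bundle (medial first), as for
#'   [catmull_rom()].
#' @param lof A [estimate_line_of_force()] object (or direction vector).
#' @param config A [geometry_config()].
#' @return A one-row tibble with `fbl_cm`, `lat_pa_deg`, `med_pa_deg`,
#'   `n_points`.
#' @export
measure_bundle <- function(points, lof, config = geometry_config()) {
  curve <- catmull_rom(points, config$knot_parameterization)
  dense <- cr_dense(curve, config$quadrature_subdivisions)
  fbl <- unname(tail(dense$s, 1))
  tan_med <- end_tangent_dense(curve, dense, "medial",
                               config$region_fraction, config$tangent_samples)
  tan_lat <- end_tangent_dense(curve, dense, "lateral",
                               config$region_fraction, config$tangent_samples)
  tibble::tibble(
    fbl_cm = fbl,
    lat_pa_deg = pennation_angle(tan_lat, lof),
    med_pa_deg = pennation_angle(tan_med, lof),
    n_points = nrow(curve$control_points)
  )
}

#' Measure all fiber bundles in a digitized point table
#'
#' Data-frame front end of the measurement pipeline. Takes the long point
#' table of one or more specimens (columns `specimen_id`, `record_type`,
#' `record_id`, `region`, `part`, `layer_depth_mm`, `point_index`, `x_cm`,
#' `y_cm`, `z_cm`), fits one line of force per specimen (per region when
#' `config$lof_per_region`, the default, since the anterior and posterior
#' regions attach to separate tendons) from the `tendon_axis` records, and
#' measures every `fiber` record. Bundles with fewer than 4 points are
#' skipped with a warning naming the bundle.
#'
#' @param points A data frame in the package's long point format.
#' @param config A [geometry_config()].
#' @return A tibble with one row per measured bundle: `specimen_id`,
#'   `bundle_id`, `region`, `part`, `layer_depth_mm`, `n_points`, `fbl_cm`,
#'   `lat_pa_deg`, `med_pa_deg`.
#' @export
measure_bundles <- function(points, config = geometry_config()) {
  req <- c("specimen_id", "record_type", "record_id", "region", "part",
           "layer_depth_mm", "point_index", "x_cm", "y_cm", "z_cm")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("Point table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  points <- dplyr::arrange(points, .data$specimen_id, .data$record_type,
                           .data$record_id, .data$point_index)

  axis_rows <- dplyr::filter(points, .data$record_type == "tendon_axis")
  if (nrow(axis_rows) == 0) {
    abort("No `tendon_axis` records found; a line of force cannot be fitted.")
  }
  lofs <- axis_rows |>
    dplyr::group_by(.data$specimen_id,
                    region = if (config$lof_per_region) .data$region else "all") |>
    dplyr::group_map(function(df, key) {
      tibble::tibble(
        specimen_id = key$specimen_id, region = key$region,
        lof = list(estimate_line_of_force(df))
      )
    }) |>
    dplyr::bind_rows()

  fibers <- dplyr::filter(points, .data$record_type == "fiber")
  if (nrow(fibers) == 0) {
    warn("No fiber records in the point table; returning an empty measurement table.")
    return(tibble::tibble(
      specimen_id = character(), bundle_id = character(), region = character(),
      part = character(), layer_depth_mm = double(), n_points = integer(),
      fbl_cm = double(), lat_pa_deg = double(), med_pa_deg = double()
    ))
  }

  lof_for <- function(spec, reg) {
    key <- if (config$lof_per_region) reg else "all"
    hit <- which(lofs$specimen_id == spec & lofs$region == key)
    if (length(hit) == 0 && config$lof_per_region) {
      # fall back to any axis of the specimen (e.g. posterior bundles in a
      # specimen digitized with a single tendon axis)
      hit <- which(lofs$specimen_id == spec)
    }
    if (length(hit) == 0) {
      abort(sprintf("No tendon axis available for specimen %s.", spec))
    }
    lofs$lof[[hit[1]]]
  }

  fibers |>
    dplyr::group_by(.data$specimen_id, .data$record_id, .data$region,
                    .data$part, .data$layer_depth_mm) |>
    dplyr::group_map(function(df, key) {
      pts <- as.matrix(df[, c("x_cm", "y_cm", "z_cm")])
      if (nrow(pts) < 4) {
        warn(sprintf("Bundle %s of specimen %s has %d < 4 points; skipped.",
                     key$record_id, key$specimen_id, nrow(pts)))
        return(NULL)
      }
      m <- measure_bundle(pts, lof_for(key$specimen_id, key$region), config)
      tibble::tibble(
        specimen_id = key$specimen_id,
        bundle_id = key$record_id,
        region = key$region,
        part = key$part,
        layer_depth_mm = key$layer_depth_mm,
        n_points = m$n_points,
        fbl_cm = m$fbl_cm,
        lat_pa_deg = m$lat_pa_deg,
        med_pa_deg = m$med_pa_deg
      )
    }) |>
    dplyr::bind_rows()
}
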