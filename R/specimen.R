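#' Classify tendon-tear severity
#'
#' Tear categories: `A` = partial-thickness tear; `B` = full-thickness tear
#' without tendon retraction; `C` = full-thickness tear with retraction. A
#' tear counts as retracted when it involves the entire width of the tendon
#' in the sagittal plane.
#'
#' @param thickness `"partial"` or `"full"` (vectorized).
#' @param spans_full_sagittal_width Logical: does the tear span the tendon's
#'   entire sagittal width?
#' @return Character vector of categories `"A"`, `"B"`, `"C"`.
#' @examples
#' classify_tear(c("partial", "full", "full"), c(FALSE, FALSE, TRUE))
#' @export
classify_tear <- function(thickness, spans_full_sagittal_width) {
  thickness <- match.arg(as.character(thickness), c("partial", "full"),
                         several.ok = TRUE)
  spans <- as.logical(spans_full_sagittal_width)
  if (length(spans) != length(thickness)) {
    abort("`thickness` and `spans_full_sagittal_width` must have equal length.")
  }
  if (anyNA(thickness) || anyNA(spans)) abort("Tear fields must not be missing.")
  bad <- thickness == "partial" & spans
  if (any(bad)) {
    abort("A partial-thickness tear cannot span the full sagittal width of the tendon.")
  }
  dplyr::case_when(
    thickness == "partial" ~ "A",
    !spans ~ "B",
    TRUE ~ "C"
  )
}

#' Anatomical coordinate frame from bony landmarks
#'
#' Builds a deterministic orthonormal right-handed specimen frame from the
#' three digitized bony reference points: lateral scapular spine, coracoid
#' process, and greater tubercle. The medial-lateral axis points from the
#' scapular spine toward the greater tubercle; the anterior-posterior axis is
#' the component of spine-to-coracoid orthogonal to it (the coracoid is
#' anterior); the superior-inferior axis completes the right-handed triad.
#' The frame is equivariant under rigid motion of the landmarks.
#'
#' @param scapular_spine,coracoid_process,greater_tubercle Numeric 3-vectors
#'   (cm).
#' @return An object of class `specimen_frame`: `origin` (the scapular spine
#'   landmark) and `axes`, a 3 x 3 matrix with rows `ml`, `ap`, `si`.
#' @export
build_specimen_frame <- function(scapular_spine, coracoid_process, greater_tubercle) {
  ss <- as.numeric(scapular_spine)
  cp <- as.numeric(coracoid_process)
  gt <- as.numeric(greater_tubercle)
  if (length(ss) != 3 || length(cp) != 3 || length(gt) != 3 ||
      !all(is.finite(c(ss, cp, gt)))) {
    abort("Landmarks must be finite numeric 3-vectors.")
  }
  v1 <- gt - ss
  v2 <- cp - ss
  if (vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9 || vnorm(cross3(v1, v2)) < 1e-9) {
    abort("Landmarks are collinear or coincident; the specimen frame is degenerate.")
  }
  ml <- v1 / vnorm(v1)
  ap_raw <- v2 - sum(v2 * ml) * ml
  ap <- ap_raw / vnorm(ap_raw)
  si <- cross3(ml, ap)
  axes <- rbind(ml = ml, ap = ap, si = si)
  colnames(axes) <- c("x", "y", "z")
  structure(list(origin = ss, axes = axes), class = "specimen_frame")
}

#' @export
print.specimen_frame <- function(x, ...) {
  cat("<specimen_frame>\n")
  print(round(x$axes, 4))
  invisible(x)
}

#' Largest tear diameters in the coronal and sagittal planes
#'
#' Emulates the caliper measurement of the largest tear diameters: the tear
#' boundary is orthogonally projected onto the coronal plane (spanned by the
#' medial-lateral and superior-inferior axes) and onto the sagittal plane
#' (anterior-posterior and superior-inferior axes) of the specimen frame, and
#' the diameter in each plane is the maximum pairwise distance between
#' projected boundary points. A boundary whose projection collapses to a
#' point yields 0 with a warning.
#'
#' @param boundary An n x 3 matrix (or x/y/z data frame) of ordered tear
#'   boundary points, n >= 3.
#' @param frame A [build_specimen_frame()] frame.
#' @return A one-row tibble with `coronal_cm` and `sagittal_cm`.
#' @export
measure_tear_dimensions <- function(boundary, frame) {
  stopifnot(inherits(frame, "specimen_frame"))
  pts <- as_point_matrix(boundary, "boundary")
  if (nrow(pts) < 3) abort("A tear boundary needs at least 3 points.")
  centered <- sweep(pts, 2, frame$origin)
  plane_diameter <- function(a1, a2, label) {
    uv <- cbind(centered %*% a1, centered %*% a2)
    d <- max(stats::dist(uv))
    if (d < 1e-9) {
      warn(sprintf("Tear boundary collapses to a point in the %s plane; diameter 0.", label))
      d <- 0
    }
    d
  }
  tibble::tibble(
    coronal_cm = plane_diameter(frame$axes["ml", ], frame$axes["si", ], "coronal"),
    sagittal_cm = plane_diameter(frame$axes["ap", ], frame$axes["si", ], "sagittal")
  )
}

#' Presence of a posterior muscle region per specimen
#'
#' A specimen has a posterior region when at least one of its digitized fiber
#' bundles is labelled `posterior`. In heavily retracted full-thickness tears
#' the posterior region can be absent altogether.
#'
#' @param points A long point table (see [measure_bundles()]).
#' @return A tibble with `specimen_id` and logical `posterior_present`, one
#'   row per specimen present in the table.
#' @export
posterior_region_present <- function(points) {
  stopifnot(all(c("specimen_id", "record_type", "region") %in% names(points)))
  points |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(
      posterior_present = any(.data$record_type == "fiber" &
                                .data$region == "posterior"),
      .groups = "drop"
    )
}

#' Validate a digitized point table
#'
#' Structural checks on the long point format: required columns, finite
#' coordinates, fiber bundles with at least 4 points (error) and typically
#' 10-20 points (warning outside that range, not rejection).
#'
#' @param points A long point table.
#' @return The table, invisibly, if valid.
#' @export
validate_digitized_points <- function(points) {
  req <- c("specimen_id", "record_type", "record_id", "region", "part",
           "layer_depth_mm", "point_index", "x_cm", "y_cm", "z_cm")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("Point table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(points$x_cm)) || !all(is.finite(points$y_cm)) ||
      !all(is.finite(points$z_cm))) {
    abort("Point table contains non-finite coordinates.")
  }
  counts <- points |>
    dplyr::filter(.data$record_type == "fiber") |>
    dplyr::count(.data$specimen_id, .data$record_id)
  if (any(counts$n < 4)) {
    bad <- counts[counts$n < 4, ]
    abort(sprintf("Fiber bundle %s of specimen %s has %d < 4 points.",
                  bad$record_id[1], bad$specimen_id[1], bad$n[1]))
  }
  atypical <- counts$n < 10 | counts$n > 20
  if (any(atypical)) {
    warn(sprintf(
      "%d fiber bundle(s) outside the typical 10-20 digitized points.",
      sum(atypical)
    ))
  }
  invisible(points)
}

#' Mirror left-side specimens into the canonical right-side frame
#'
#' Pooled statistics treat left and right shoulders together; left-side
#' specimens are reflected across the sagittal plane (the anterior-posterior
#' coordinate is negated) so all specimens share a right-side convention.
#'
#' @param points A long point table.
#' @param specimens Specimen manifest tibble with `specimen_id` and `side`.
#' @param enabled Set `FALSE` to leave coordinates untouched.
#' @return The point table with left-side `y_cm` negated.
#' @export
mirror_to_right <- function(points, specimens, enabled = TRUE) {
  if (!enabled) return(points)
  left_ids <- specimens$specimen_id[specimens$side == "left"]
  dplyr::mutate(
    points,
    y_cm = ifelse(.data$specimen_id %in% left_ids, -.data$y_cm, .data$y_cm)
  )
}

#' Reference cohort of cadaveric shoulder specimens
#'
#' The packaged summary table of the twelve cadaveric shoulder specimens
#' underlying the reference analysis: side, sex, age, tear category, tear
#' location, largest coronal and sagittal tear diameters (cm; `NA` where not
#' measured in partial-thickness tears), and whether a distinct posterior
#' region was present.
#'
#' @return A tibble with one row per specimen.
#' @examples
#' reference_specimens()
#' @export
reference_specimens <- function() {
  path <- system.file("extdata", "reference_specimens.csv", package = "fascicle3d",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(
      specimen_id = paste0(.data$specimen_number, "_", toupper(substr(.data$side, 1, 1))),
      .before = 1
    )
}
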