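# Reading and writing the package's on-disk formats: specimen manifest JSON,
# long point CSV, ground-truth CSV, pipeline config (YAML/JSON) and Wavefront
# OBJ models.

#' Write a cohort to disk
#'
#' Writes `manifest.json` (one record per specimen with tear fields and
#' landmarks nested), `points.csv` (the long point table) and, when present,
#' `ground_truth.csv`.
#'
#' @param cohort A `fascicle_cohort` (or a list with `specimens` and `points`
#'   tibbles).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create output directory %s.", dir))
  files <- character()

  manifest <- purrr::pmap(cohort$specimens, function(...) {
    row <- list(...)
    list(
      specimen_id = row$specimen_id, side = row$side, sex = row$sex,
      age = row$age, category = row$category,
      tear = list(
        thickness = row$thickness,
        spans_full_sagittal_width = row$spans_full_sagittal_width,
        coronal_cm = row$coronal_cm, sagittal_cm = row$sagittal_cm
      ),
      posterior_present = row$posterior_present,
      landmarks = list(
        scapular_spine = c(row$lm_ss_x, row$lm_ss_y, row$lm_ss_z),
        coracoid_process = c(row$lm_cp_x, row$lm_cp_y, row$lm_cp_z),
        greater_tubercle = c(row$lm_gt_x, row$lm_gt_y, row$lm_gt_z)
      )
    )
  })
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, mf)

  pf <- file.path(dir, "points.csv")
  readr::write_csv(cohort$points, pf)
  files <- c(files, pf)

  if (!is.null(cohort$ground_truth) && nrow(cohort$ground_truth) > 0) {
    gf <- file.path(dir, "ground_truth.csv")
    readr::write_csv(cohort$ground_truth, gf)
    files <- c(files, gf)
  }
  invisible(files)
}

#' Load a cohort from disk
#'
#' Reads the manifest and point table written by [write_cohort()] (or
#' assembled by hand in the same format). By default, left-side specimens are
#' mirrored across the sagittal plane into the canonical right-side frame
#' (points and landmarks), making pooled statistics side-agnostic.
#'
#' @param dir Directory holding `manifest.json` and `points.csv`.
#' @param mirror_left Mirror left-side specimens on load (default `TRUE`).
#' @return A `fascicle_cohort` list with `specimens`, `points` and (if
#'   present on disk) `ground_truth`.
#' @export
load_cohort <- function(dir, mirror_left = TRUE) {
  mf <- file.path(dir, "manifest.json")
  pf <- file.path(dir, "points.csv")
  if (!file.exists(mf) || !file.exists(pf)) {
    abort(sprintf("Directory %s lacks manifest.json/points.csv.", dir))
  }
  raw <- jsonlite::read_json(mf)
  specimens <- purrr::map_dfr(raw, function(r) {
    tibble::tibble(
      specimen_id = r$specimen_id, side = r$side, sex = r$sex,
      age = as.numeric(r$age), category = r$category,
      thickness = r$tear$thickness,
      spans_full_sagittal_width = isTRUE(r$tear$spans_full_sagittal_width),
      coronal_cm = as.numeric(r$tear$coronal_cm %||% NA),
      sagittal_cm = as.numeric(r$tear$sagittal_cm %||% NA),
      posterior_present = isTRUE(r$posterior_present),
      lm_ss_x = r$landmarks$scapular_spine[[1]],
      lm_ss_y = r$landmarks$scapular_spine[[2]],
      lm_ss_z = r$landmarks$scapular_spine[[3]],
      lm_cp_x = r$landmarks$coracoid_process[[1]],
      lm_cp_y = r$landmarks$coracoid_process[[2]],
      lm_cp_z = r$landmarks$coracoid_process[[3]],
      lm_gt_x = r$landmarks$greater_tubercle[[1]],
      lm_gt_y = r$landmarks$greater_tubercle[[2]],
      lm_gt_z = r$landmarks$greater_tubercle[[3]]
    )
  })
  points <- readr::read_csv(pf, show_col_types = FALSE,
                            col_types = readr::cols(
                              specimen_id = "c", record_type = "c",
                              record_id = "c", region = "c", part = "c"
                            ))
  if (mirror_left) {
    points <- mirror_to_right(points, specimens)
    left <- specimens$side == "left"
    specimens <- dplyr::mutate(
      specimens,
      lm_ss_y = ifelse(left, -.data$lm_ss_y, .data$lm_ss_y),
      lm_cp_y = ifelse(left, -.data$lm_cp_y, .data$lm_cp_y),
      lm_gt_y = ifelse(left, -.data$lm_gt_y, .data$lm_gt_y)
    )
  }
  out <- list(specimens = specimens, points = points)
  gf <- file.path(dir, "ground_truth.csv")
  if (file.exists(gf)) {
    out$ground_truth <- readr::read_csv(gf, show_col_types = FALSE)
  }
  class(out) <- "fascicle_cohort"
  out
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON file with optional top-level blocks
#' `geometry` (arguments of [geometry_config()]), `generator` (arguments of
#' [generator_config()] except `seed`) and `stats` (e.g. `alpha`,
#' `min_specimens`). Missing blocks fall back to defaults.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @return A named list with the raw blocks.
#' @export
read_pipeline_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) abort(sprintf("Config file %s does not exist.", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Export a specimen as a Wavefront OBJ model
#'
#' Writes each fiber bundle's uniform arc-length samples as a polyline
#' object, each tendon outline as a closed polyline, and each region's line
#' of force as a two-vertex segment. Group names encode region and part, so
#' downstream viewers can color-code the architecture.
#'
#' @param points Long point table of a single specimen.
#' @param file Output `.obj` path.
#' @param config A [geometry_config()]; `n_samples` controls polyline
#'   resolution.
#' @param samples_per_fiber Vertices written per fiber polyline (default 25).
#' @return Invisibly, `file`.
#' @export
write_obj_model <- function(points, file, config = geometry_config(),
                            samples_per_fiber = 25) {
  ids <- unique(points$specimen_id)
  if (length(ids) != 1) abort("OBJ export expects the points of exactly one specimen.")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fascicle3d model of specimen %s", ids), con)
  offset <- 0L

  emit_polyline <- function(name, group, verts, closed = FALSE) {
    writeLines(sprintf("o %s", name), con)
    writeLines(sprintf("g %s", group), con)
    writeLines(sprintf("v %.6f %.6f %.6f", verts[, 1], verts[, 2], verts[, 3]), con)
    idx <- offset + seq_len(nrow(verts))
    if (closed) idx <- c(idx, idx[1])
    writeLines(paste("l", paste(idx, collapse = " ")), con)
    offset <<- offset + nrow(verts)
  }

  fibers <- dplyr::filter(points, .data$record_type == "fiber")
  for (bid in unique(fibers$record_id)) {
    df <- fibers[fibers$record_id == bid, ]
    df <- df[order(df$point_index), ]
    if (nrow(df) < 4) next
    crv <- catmull_rom(as.matrix(df[, c("x_cm", "y_cm", "z_cm")]),
                       config$knot_parameterization)
    crv <- arclength_resample(crv, samples_per_fiber,
                              config$quadrature_subdivisions)
    emit_polyline(paste0("fiber_", bid),
                  paste(df$region[1], df$part[1], sep = "_"),
                  crv$uniform_samples)
  }

  outlines <- dplyr::filter(points, .data$record_type == "tendon_outline")
  for (oid in unique(outlines$record_id)) {
    df <- outlines[outlines$record_id == oid, ]
    df <- df[order(df$point_index), ]
    emit_polyline(paste0("outline_", oid),
                  paste0(df$region[1], "_tendon"),
                  as.matrix(df[, c("x_cm", "y_cm", "z_cm")]), closed = TRUE)
  }

  axes <- dplyr::filter(points, .data$record_type == "tendon_axis")
  for (reg in unique(axes$region)) {
    df <- axes[axes$region == reg, ]
    df <- df[order(df$point_index), ]
    lof <- estimate_line_of_force(as.matrix(df[, c("x_cm", "y_cm", "z_cm")]))
    half <- diff(range(df$x_cm)) / 2 + 0.5
    seg <- rbind(lof$anchor - half * lof$direction,
                 lof$anchor + half * lof$direction)
    emit_polyline(paste0("line_of_force_", reg),
                  paste0(reg, "_line_of_force"), seg)
  }
  invisible(file)
}

# Run manifest: provenance record tying outputs to inputs and settings.
write_run_manifest <- function(dir, step, seed = NULL, config = NULL,
                               inputs = character()) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    step = step,
    package = "fascicle3d",
    version = as.character(utils::packageVersion("fascicle3d")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_checksums = checksums
  )
  path <- file.path(dir, paste0("run_manifest_", step, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}
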