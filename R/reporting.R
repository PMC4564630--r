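# Orchestration layer: generate / measure / report, mirroring the shape of
# the reference workflow's outputs (specimen summary, region-level and
# part-level architecture tables, test log).

#' Generate a synthetic cohort on disk
#'
#' @param out_dir Output directory.
#' @param seed Master seed for the generator.
#' @param config_path Optional YAML/JSON config; its `generator` block
#'   overrides [generator_config()] defaults.
#' @param n_per_category Specimens per tear category (default 4).
#' @return Invisibly, the files written.
#' @export
cmd_generate <- function(out_dir, seed, config_path = NULL, n_per_category = 4) {
  cfg_file <- read_pipeline_config(config_path)
  gen_args <- c(list(seed = seed), cfg_file$generator)
  if (!is.null(gen_args$targets)) {
    gen_args$targets <- tibble::as_tibble(gen_args$targets)
  }
  config <- do.call(generator_config, gen_args)
  cohort <- generate_cohort(config, n_per_category = n_per_category)
  files <- write_cohort(cohort, out_dir)
  mfst <- write_run_manifest(
    out_dir, "generate", seed = seed,
    config = c(cfg_file$generator, list(n_per_category = n_per_category)),
    inputs = files
  )
  invisible(c(files, mfst))
}

#' Measure fascicle architecture of a cohort on disk
#'
#' Loads a cohort directory, validates the point table, measures every fiber
#' bundle, writes `measurements.csv` and one OBJ model per specimen.
#'
#' @param in_dir Cohort directory (see [write_cohort()]).
#' @param out_dir Output directory.
#' @param config_path Optional YAML/JSON config; its `geometry` block
#'   overrides [geometry_config()] defaults.
#' @param export_obj Write OBJ models (default `TRUE`).
#' @return Invisibly, the files written.
#' @export
cmd_measure <- function(in_dir, out_dir, config_path = NULL, export_obj = TRUE) {
  cfg_file <- read_pipeline_config(config_path)
  config <- do.call(geometry_config, cfg_file$geometry %||% list())
  cohort <- load_cohort(in_dir)
  validate_digitized_points(cohort$points)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meas <- measure_bundles(cohort$points, config)
  mfile <- file.path(out_dir, "measurements.csv")
  readr::write_csv(meas, mfile)
  files <- mfile

  sfile <- file.path(out_dir, "specimens.csv")
  readr::write_csv(cohort$specimens, sfile)
  files <- c(files, sfile)

  if (export_obj) {
    for (id in unique(cohort$points$specimen_id)) {
      of <- file.path(out_dir, paste0(id, ".obj"))
      write_obj_model(cohort$points[cohort$points$specimen_id == id, ], of,
                      config)
      files <- c(files, of)
    }
  }
  mfst <- write_run_manifest(out_dir, "measure", config = cfg_file$geometry,
                             inputs = files)
  invisible(c(files, mfst))
}

format_cell <- function(med, lo, hi) {
  ifelse(is.na(med), "", sprintf("%.2f (%.2f-%.2f)", med, lo, hi))
}

#' Format an architecture summary as a display table
#'
#' Spreads one metric of a [summarize_architecture()] result into the
#' familiar "median (min-max)" layout with one row per region x category and
#' one column per part.
#'
#' @param summary A `fascicle_summary` tibble.
#' @param metric `"fbl_cm"`, `"lat_pa_deg"` or `"med_pa_deg"`.
#' @return A tibble of formatted strings.
#' @export
architecture_table <- function(summary, metric = c("fbl_cm", "lat_pa_deg", "med_pa_deg")) {
  metric <- match.arg(metric)
  summary |>
    dplyr::mutate(cell = format_cell(
      .data[[paste0(metric, "_median")]],
      .data[[paste0(metric, "_min")]],
      .data[[paste0(metric, "_max")]]
    )) |>
    dplyr::select("region", "part", "category", "n_specimens", "cell") |>
    tidyr::pivot_wider(names_from = "part", values_from = "cell") |>
    dplyr::arrange(.data$region, .data$category)
}

write_text_table <- function(df, path, title) {
  txt <- utils::capture.output(print(as.data.frame(df), row.names = FALSE))
  writeLines(c(title, txt, ""), path)
  invisible(path)
}

#' Report tables and test log for measured cohorts
#'
#' Produces the analysis deliverables from a measurement directory: a
#' demographic and tear-dimension summary (with the category B vs C
#' Mann-Whitney comparison of tear diameters), region-level and part-level
#' median (min-max) architecture tables for each metric (CSV plus aligned
#' text), and a JSON-lines log of every hypothesis test. Cells backed by
#' fewer than `min_specimens` specimens are summarized but excluded from
#' testing with a warning.
#'
#' @param measure_dir Directory holding `measurements.csv` and
#'   `specimens.csv` (see [cmd_measure()]).
#' @param out_dir Output directory.
#' @param alpha Family significance level (default 0.05).
#' @param min_specimens Minimum specimens per group for testing (default 3).
#' @return Invisibly, the files written.
#' @export
cmd_report <- function(measure_dir, out_dir, alpha = 0.05, min_specimens = 3) {
  mfile <- file.path(measure_dir, "measurements.csv")
  sfile <- file.path(measure_dir, "specimens.csv")
  if (!file.exists(mfile) || !file.exists(sfile)) {
    abort(sprintf("%s lacks measurements.csv/specimens.csv.", measure_dir))
  }
  meas <- readr::read_csv(mfile, show_col_types = FALSE)
  specimens <- readr::read_csv(sfile, show_col_types = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  # --- specimen summary (demographics + tear dimensions) ------------------
  ages <- describe(specimens$age)
  demo <- list(
    n_specimens = nrow(specimens),
    n_male = sum(specimens$sex == "M"),
    n_female = sum(specimens$sex == "F"),
    age_mean = round(ages$mean, 1),
    age_sd = round(ages$sd, 1),
    age_min = ages$min, age_max = ages$max,
    per_category = as.list(table(specimens$category))
  )
  tear_tests <- list()
  bc <- specimens[specimens$category %in% c("B", "C"), ]
  if (all(table(bc$category) >= 1) && dplyr::n_distinct(bc$category) == 2) {
    for (dim in c("coronal_cm", "sagittal_cm")) {
      res <- mann_whitney(bc[[dim]][bc$category == "B"],
                          bc[[dim]][bc$category == "C"])
      tear_tests[[dim]] <- list(
        dimension = dim, U = res$statistic, z = res$z_value,
        p_value = res$p_value, method = res$method
      )
    }
    demo$tear_median_B <- list(
      coronal_cm = median(bc$coronal_cm[bc$category == "B"], na.rm = TRUE),
      sagittal_cm = median(bc$sagittal_cm[bc$category == "B"], na.rm = TRUE)
    )
    demo$tear_median_C <- list(
      coronal_cm = median(bc$coronal_cm[bc$category == "C"], na.rm = TRUE),
      sagittal_cm = median(bc$sagittal_cm[bc$category == "C"], na.rm = TRUE)
    )
  }
  dfile <- file.path(out_dir, "specimen_summary.json")
  jsonlite::write_json(c(demo, list(tear_tests = tear_tests)), dfile,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  files <- c(files, dfile)

  # --- architecture tables -------------------------------------------------
  meas <- dplyr::left_join(
    meas, specimens[, c("specimen_id", "category")], by = "specimen_id"
  )
  region_summary <- summarize_architecture(meas, by_part = FALSE,
                                           min_specimens = min_specimens)
  part_summary <- summarize_architecture(meas, by_part = TRUE,
                                         min_specimens = min_specimens)
  rfile <- file.path(out_dir, "architecture_regions.csv")
  readr::write_csv(region_summary, rfile)
  pfile <- file.path(out_dir, "architecture_parts.csv")
  readr::write_csv(part_summary, pfile)
  files <- c(files, rfile, pfile)

  for (metric in c("fbl_cm", "lat_pa_deg", "med_pa_deg")) {
    tab <- architecture_table(part_summary, metric)
    tw <- file.path(out_dir, paste0("table_", metric, ".txt"))
    write_text_table(tab, tw, sprintf("Median %s (min-max) by region, part, category", metric))
    files <- c(files, tw)
  }
  write_text_table(
    architecture_table(region_summary, "fbl_cm"),
    file.path(out_dir, "table_regions_fbl.txt"),
    "Median FBL (min-max), regions as a whole"
  )
  files <- c(files, file.path(out_dir, "table_regions_fbl.txt"))

  # --- hypothesis tests ----------------------------------------------------
  compare_block <- function(by, between) {
    res <- compare_architecture(meas, by = by, between = between,
                                alpha = alpha, min_specimens = min_specimens)
    if (is.null(res) || nrow(res) == 0) return(NULL)
    res$stratum <- apply(res[, by, drop = FALSE], 1, function(r) {
      paste(paste0(by, "=", r), collapse = "/")
    })
    res$between <- between
    res
  }
  tests <- withCallingHandlers(
    dplyr::bind_rows(
      compare_block("region", "category"),
      compare_block(c("region", "part"), "category"),
      compare_block(c("region", "category"), "part")
    ),
    warning = function(w) {
      message("note: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (nrow(tests) == 0) {
    tests <- tibble::tibble(
      stratum = character(), between = character(), metric = character(),
      comparison = character(), test = character(), statistic = double(),
      z_value = double(), p_value = double(), alpha_adjusted = double(),
      significant = logical()
    )
  }
  tfile <- file.path(out_dir, "test_log.jsonl")
  con <- file(tfile, "w")
  for (i in seq_len(nrow(tests))) {
    writeLines(jsonlite::toJSON(as.list(tests[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  close(con)
  tcsv <- file.path(out_dir, "test_log.csv")
  readr::write_csv(tests, tcsv)
  files <- c(files, tfile, tcsv)

  mfst <- write_run_manifest(out_dir, "report",
                             config = list(alpha = alpha,
                                           min_specimens = min_specimens),
                             inputs = files)
  invisible(c(files, mfst))
}
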