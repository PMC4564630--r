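#' Default per-cell architecture targets of the generator
#'
#' Median fiber bundle length (cm) and lateral/medial pennation angle
#' (degrees) for every region x part x tear-category cell. These are the
#' generator's built-in study conditions: the reference cohort's published
#' per-part medians, so that synthetic cohorts carry the same qualitative
#' structure (anterior fibers shorten progressively with tear severity and
#' with depth; pennation grows with retraction; posterior pennation is
#' largest in partial tears).
#'
#' @return A tibble with columns `region`, `part`, `category`, `fbl_cm`,
#'   `lat_pa_deg`, `med_pa_deg`.
#' @export
default_architecture_targets <- function() {
  parts <- c("superficial", "middle", "deep")
  tibble::tibble(
    region = rep(c("anterior", "posterior"), each = 9),
    part = rep(rep(parts, times = 3), 2),
    category = rep(rep(c("A", "B", "C"), each = 3), 2),
    fbl_cm = c(
      7.56, 6.71, 6.24, 5.58, 4.71, 5.16, 2.95, 2.57, 2.50,
      5.89, 6.42, 5.85, 4.88, 4.98, 4.65, 2.96, 3.48, 2.80
    ),
    lat_pa_deg = c(
      14.26, 15.71, 14.15, 15.59, 12.73, 14.15, 25.16, 22.92, 21.80,
      26.39, 25.60, 18.79, 27.17, 23.43, 17.71, 38.46, 35.25, 25.17
    ),
    med_pa_deg = c(
      15.58, 12.97, 13.87, 19.22, 15.95, 11.52, 28.40, 22.96, 19.99,
      17.85, 14.46, 16.54, 14.06, 13.55, 10.71, 19.40, 12.58, 13.89
    )
  )
}

# Tear-record conditions per category: thickness, sagittal spanning, and the
# median coronal/sagittal diameters (cm) around which tears are drawn.
# Diameters are not measured for partial-thickness tears.
tear_defaults <- function() {
  tibble::tibble(
    category = c("A", "B", "C"),
    thickness = c("partial", "full", "full"),
    spans_full_sagittal_width = c(FALSE, FALSE, TRUE),
    coronal_cm = c(NA, 1.44, 2.96),
    sagittal_cm = c(NA, 1.58, 3.72)
  )
}

#' Configuration of the synthetic digitized-specimen generator
#'
#' Encodes the digitization protocol being emulated (10-60 fiber bundles per
#' dissection layer, 10-20 digitized sites per bundle, layers about 1.5 mm
#' apart, tendon outline dots about 2 mm apart) and the architecture the
#' cohort should carry (per-cell median targets plus dispersion). Fiber
#' bundle lengths are drawn log-normally around the cell median (the
#' log-normal median is the target regardless of spread); pennation angles
#' are drawn folded-normally on \[0, 90\] degrees.
#'
#' @param seed Master seed (required). Every specimen and bundle derives a
#'   named sub-stream from it, so adding bundles never perturbs existing
#'   ones.
#' @param targets Per-cell target tibble, see
#'   [default_architecture_targets()].
#' @param fbl_sigma_log Log-scale SD of fiber bundle length (default 0.25).
#' @param pa_sd_deg SD of the folded-normal pennation draw (default 7).
#' @param bundles_per_layer Integer range, default `c(10, 60)`.
#' @param points_per_bundle Integer range, default `c(10, 20)`; within it the
#'   digitized-site count scales with fiber length (about one site per 4 mm),
#'   as a digitizer would space sites.
#' @param layers_per_part Dissection layers per part (default 3, so 9 layers
#'   per region).
#' @param layer_spacing_mm Depth between layers (default 1.5).
#' @param outline_dot_spacing_mm Tendon outline dot spacing (default 2).
#' @param digitization_noise_sd_cm Isotropic per-point noise SD (default
#'   0.02).
#' @param fiber_curvature In \[0, 1\]: 0 generates straight fibers at the
#'   lateral pennation angle; 1 (default) lets the medial end realize its own
#'   independently drawn angle, giving gently curved fibers with a 1-3%
#'   arc/chord excess.
#' @param posterior_absent_prob Probability that a category-C specimen lacks
#'   a posterior region (default 0.5; half of the reference category-C
#'   specimens lacked one).
#' @param tear_sigma_log Log-scale SD of tear diameters (default 0.15).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             targets = default_architecture_targets(),
                             fbl_sigma_log = 0.25,
                             pa_sd_deg = 7,
                             bundles_per_layer = c(10, 60),
                             points_per_bundle = c(10, 20),
                             layers_per_part = 3,
                             layer_spacing_mm = 1.5,
                             outline_dot_spacing_mm = 2,
                             digitization_noise_sd_cm = 0.02,
                             fiber_curvature = 1,
                             posterior_absent_prob = 0.5,
                             tear_sigma_log = 0.15) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is required and must be a single integer.")
  }
  req <- c("region", "part", "category", "fbl_cm", "lat_pa_deg", "med_pa_deg")
  if (!all(req %in% names(targets))) {
    abort("`targets` must have columns region, part, category, fbl_cm, lat_pa_deg, med_pa_deg.")
  }
  stopifnot(
    fbl_sigma_log > 0, pa_sd_deg > 0, tear_sigma_log > 0,
    length(bundles_per_layer) == 2, bundles_per_layer[1] >= 1,
    bundles_per_layer[2] >= bundles_per_layer[1],
    length(points_per_bundle) == 2, points_per_bundle[1] >= 4,
    points_per_bundle[2] >= points_per_bundle[1],
    layers_per_part >= 1, layer_spacing_mm > 0, outline_dot_spacing_mm > 0,
    digitization_noise_sd_cm >= 0,
    fiber_curvature >= 0, fiber_curvature <= 1,
    posterior_absent_prob >= 0, posterior_absent_prob <= 1
  )
  structure(
    list(
      seed = as.integer(seed), targets = targets,
      fbl_sigma_log = fbl_sigma_log, pa_sd_deg = pa_sd_deg,
      bundles_per_layer = as.integer(bundles_per_layer),
      points_per_bundle = as.integer(points_per_bundle),
      layers_per_part = as.integer(layers_per_part),
      layer_spacing_mm = layer_spacing_mm,
      outline_dot_spacing_mm = outline_dot_spacing_mm,
      digitization_noise_sd_cm = digitization_noise_sd_cm,
      fiber_curvature = fiber_curvature,
      posterior_absent_prob = posterior_absent_prob,
      tear_sigma_log = tear_sigma_log
    ),
    class = "generator_config"
  )
}

# fold a normal draw into [0, 90] degrees
fold_angle <- function(x) {
  x <- abs(x)
  x <- x %% 360
  x <- ifelse(x > 180, 360 - x, x)
  ifelse(x > 90, 180 - x, x)
}

# Smoothstep tangent-angle profile along arc length: flat plateaus over the
# terminal 15% at each end (so the configured end angles are exact ground
# truth for tangent averaging over the terminal 10%) with a smooth turn in
# the middle supplying the fiber's curvature.
angle_profile <- function(s_over_L, phi_med, phi_lat, plateau = 0.15) {
  tau <- (s_over_L - plateau) / (1 - 2 * plateau)
  tau <- pmin(pmax(tau, 0), 1)
  w <- 3 * tau^2 - 2 * tau^3
  phi_med + (phi_lat - phi_med) * w
}

# Build one fascicle: an analytic constant-speed curve of exact arc length L
# whose tangents make the prescribed in-plane angles with the tendon axis
# direction u, lying in the plane spanned by u and e, ending at `attach`
# (the lateral attachment). Returns dense points medial -> lateral.
make_fiber_curve <- function(L, phi_med_deg, phi_lat_deg, u, e, attach,
                             n_dense = 400) {
  s <- seq(0, L, length.out = n_dense)
  phi <- deg2rad(angle_profile(s / L, phi_med_deg, phi_lat_deg))
  tang <- outer(cos(phi), u) + outer(sin(phi), e)
  ds <- L / (n_dense - 1)
  # trapezoidal cumulative integral of the unit tangent
  avg <- (tang[-1, , drop = FALSE] + tang[-n_dense, , drop = FALSE]) / 2
  disp <- rbind(c(0, 0, 0), apply(avg * ds, 2, cumsum))
  total <- disp[n_dense, ]
  pos <- sweep(disp, 2, total) + matrix(attach, n_dense, 3, byrow = TRUE)
  list(s = s, points = pos)
}

# Digitize a dense analytic curve at n roughly equidistant sites with
# along-curve jitter and isotropic coordinate noise; endpoints exact in s.
digitize_curve <- function(curve, n_points, noise_sd) {
  L <- tail(curve$s, 1)
  s_sites <- seq(0, L, length.out = n_points)
  if (n_points > 2) {
    jit <- runif(n_points - 2, -0.25, 0.25) * L / (n_points - 1)
    s_sites[2:(n_points - 1)] <- s_sites[2:(n_points - 1)] + jit
  }
  pts <- cbind(
    stats::approx(curve$s, curve$points[, 1], xout = s_sites)$y,
    stats::approx(curve$s, curve$points[, 2], xout = s_sites)$y,
    stats::approx(curve$s, curve$points[, 3], xout = s_sites)$y
  )
  pts + matrix(rnorm(3 * n_points, 0, noise_sd), n_points, 3)
}

# Region layout constants of the canonical right-side specimen (cm): the
# medial-lateral axis is +x, anterior is +y, superior is +z; the superficial
# muscle surface sits at z = 0 and dissection proceeds downward.
region_layout <- function(region) {
  if (region == "anterior") {
    list(axis_y = 1.0, axis_x = c(4, 10), attach_x = c(6, 9),
         side_y = +1, fan_y = c(0.0, 2.5))
  } else {
    list(axis_y = -1.5, axis_x = c(4, 9), attach_x = c(5, 8),
         side_y = -1, fan_y = c(-2.5, -0.5))
  }
}

point_rows <- function(specimen_id, record_type, record_id, region, part,
                       layer_depth_mm, pts) {
  tibble::tibble(
    specimen_id = specimen_id, record_type = record_type,
    record_id = record_id, region = region, part = part,
    layer_depth_mm = layer_depth_mm,
    point_index = seq_len(nrow(pts)),
    x_cm = pts[, 1], y_cm = pts[, 2], z_cm = pts[, 3]
  )
}

#' Generate one synthetic digitized specimen
#'
#' Emulates the serial dissection and digitization of one cadaveric
#' supraspinatus with a given tendon-tear category. The anterior region is
#' penniform: bundles converge obliquely onto the anterior intramuscular
#' tendon axis. The posterior region is fusiform: near-parallel bundles with
#' laterally spread attachments. Bundles are realized as smooth
#' constant-speed curves with exact (ground-truth) arc length and end
#' angles, digitized at 10-20 sites with isotropic noise, and stacked in
#' dissection layers labelled superficial/middle/deep. Tendon outlines, the
#' tendon axis points, bony landmarks, and (for full-thickness tears) an
#' elliptical tear boundary are emitted in the same long point format.
#'
#' @param category Tear category `"A"`, `"B"` or `"C"`.
#' @param config A [generator_config()].
#' @param specimen_id Identifier (default derived from the category).
#' @param posterior_absent Force posterior-region absence; default `NA` draws
#'   it (category C only) with `config$posterior_absent_prob`.
#' @return A list with `specimen` (one-row manifest tibble), `points` (long
#'   point table) and `ground_truth` (one row per bundle with true FBL and
#'   pennation angles).
#' @export
generate_specimen <- function(category, config, specimen_id = NULL,
                              posterior_absent = NA) {
  stopifnot(inherits(config, "generator_config"))
  category <- match.arg(category, c("A", "B", "C"))
  if (is.null(specimen_id)) specimen_id <- paste0(category, "1")
  set.seed(derive_seed(config$seed, "specimen", specimen_id))

  side <- sample(c("right", "left"), 1, prob = c(5, 1) / 6)
  sex <- sample(c("F", "M"), 1, prob = c(0.75, 0.25))
  age <- sample(64:95, 1)
  if (is.na(posterior_absent)) {
    posterior_absent <- category == "C" &&
      runif(1) < config$posterior_absent_prob
  }

  # landmarks: canonical positions with mild per-specimen jitter
  lm <- list(
    scapular_spine = c(0, 0, 0) + rnorm(3, 0, 0.1),
    coracoid_process = c(9, 3, -1) + rnorm(3, 0, 0.1),
    greater_tubercle = c(12, 0, 0) + rnorm(3, 0, 0.1)
  )
  frame <- build_specimen_frame(lm$scapular_spine, lm$coracoid_process,
                                lm$greater_tubercle)

  # tear record and boundary
  td <- tear_defaults()
  td <- td[td$category == category, ]
  if (td$thickness == "full") {
    coronal <- exp(log(td$coronal_cm) + rnorm(1, 0, config$tear_sigma_log))
    sagittal <- exp(log(td$sagittal_cm) + rnorm(1, 0, config$tear_sigma_log))
  } else {
    coronal <- NA_real_
    sagittal <- NA_real_
  }

  points <- list()
  truth <- list()

  if (!is.na(coronal)) {
    # elliptical tear in the tendon plane (spanned by the ml and ap axes of
    # the landmark frame) so projected caliper diameters equal the draws
    theta <- seq(0, 2 * pi, length.out = 65)[-65]
    center <- frame$origin + 10.5 * frame$axes["ml", ] + 0.8 * frame$axes["ap", ]
    boundary <- matrix(center, 64, 3, byrow = TRUE) +
      outer(coronal / 2 * cos(theta), frame$axes["ml", ]) +
      outer(sagittal / 2 * sin(theta), frame$axes["ap", ])
    points$tear <- point_rows(specimen_id, "tear_boundary", "tear", "anterior",
                              NA_character_, NA_real_, boundary)
  }

  regions <- if (posterior_absent) "anterior" else c("anterior", "posterior")
  n_layers <- 3L * config$layers_per_part
  parts <- rep(c("superficial", "middle", "deep"), each = config$layers_per_part)
  depth_cm_mid <- (n_layers - 1) * config$layer_spacing_mm / 10 / 2

  for (region in regions) {
    lay <- region_layout(region)
    # tendon axis points (medial -> lateral), lightly noised
    ax_x <- seq(lay$axis_x[1], lay$axis_x[2], length.out = 15)
    axis_pts <- cbind(ax_x, lay$axis_y, -depth_cm_mid) +
      matrix(rnorm(45, 0, config$digitization_noise_sd_cm / 2), 15, 3)
    points[[paste0(region, "_axis")]] <- point_rows(
      specimen_id, "tendon_axis", paste0(region, "_axis"), region,
      NA_character_, NA_real_, axis_pts
    )

    # tendon outlines every ~3 mm of depth
    for (d_mm in seq(0, (n_layers - 1) * config$layer_spacing_mm, by = 3)) {
      per <- 2 * pi * sqrt((1.5^2 + 0.5^2) / 2)
      n_dots <- max(8L, round(per / (config$outline_dot_spacing_mm / 10)))
      th <- seq(0, 2 * pi, length.out = n_dots + 1)[-(n_dots + 1)]
      outline <- cbind(
        mean(lay$axis_x) + 1.5 * cos(th),
        lay$axis_y + 0.5 * sin(th),
        -d_mm / 10
      )
      points[[paste0(region, "_out", d_mm)]] <- point_rows(
        specimen_id, "tendon_outline", sprintf("%s_outline_%gmm", region, d_mm),
        region, NA_character_, d_mm, outline
      )
    }

    u <- c(1, 0, 0)
    for (layer in seq_len(n_layers)) {
      part <- parts[layer]
      depth_mm <- (layer - 1) * config$layer_spacing_mm
      tgt <- config$targets[config$targets$region == region &
                              config$targets$part == part &
                              config$targets$category == category, ]
      if (nrow(tgt) != 1) {
        abort(sprintf("No generator target for %s/%s/%s.", region, part, category))
      }
      # one named sub-stream per dissection layer; bundles consume it in
      # order, so appending bundles never perturbs earlier ones and other
      # layers are untouched (reseeding per bundle would correlate the first
      # draws of structurally similar hash seeds)
      set.seed(derive_seed(config$seed, "specimen", specimen_id, region,
                           "layer", layer))
      n_bundles <- sample(config$bundles_per_layer[1]:config$bundles_per_layer[2], 1)
      for (b in seq_len(n_bundles)) {
        L <- exp(log(tgt$fbl_cm) + rnorm(1, 0, config$fbl_sigma_log))
        th_lat <- fold_angle(rnorm(1, tgt$lat_pa_deg, config$pa_sd_deg))
        th_med <- fold_angle(rnorm(1, tgt$med_pa_deg, config$pa_sd_deg))
        cc <- config$fiber_curvature
        phi_lat <- -th_lat
        phi_med <- cc * th_med - (1 - cc) * th_lat
        gamma <- rnorm(1, 0, deg2rad(10))
        e <- lay$side_y * c(0, cos(gamma), sin(gamma))
        if (region == "anterior") {
          attach <- c(runif(1, lay$attach_x[1], lay$attach_x[2]),
                      lay$axis_y, -depth_mm / 10)
        } else {
          attach <- c(runif(1, lay$attach_x[1], lay$attach_x[2]),
                      runif(1, lay$fan_y[1], lay$fan_y[2]), -depth_mm / 10)
        }
        curve <- make_fiber_curve(L, phi_med, phi_lat, u, e, attach)
        n_pts <- round(L / 0.4) + sample(-1:1, 1)
        n_pts <- min(config$points_per_bundle[2],
                     max(config$points_per_bundle[1], n_pts))
        dig <- digitize_curve(curve, n_pts, config$digitization_noise_sd_cm)
        bid <- sprintf("%s_L%02d_B%03d", substr(region, 1, 1), layer, b)
        points[[bid]] <- point_rows(specimen_id, "fiber", bid, region, part,
                                    depth_mm, dig)
        truth[[bid]] <- tibble::tibble(
          specimen_id = specimen_id, bundle_id = bid, region = region,
          part = part, layer_depth_mm = depth_mm,
          true_fbl_cm = L, true_lat_pa_deg = th_lat,
          true_med_pa_deg = abs(phi_med)
        )
      }
    }
  }

  points_df <- dplyr::bind_rows(points)
  if (side == "left") {
    # raw digitized coordinates of a left shoulder: reflected across the
    # sagittal plane relative to the canonical right-side frame
    points_df$y_cm <- -points_df$y_cm
    lm <- lapply(lm, function(p) p * c(1, -1, 1))
  }

  specimen <- tibble::tibble(
    specimen_id = specimen_id, side = side, sex = sex, age = age,
    category = category, thickness = td$thickness,
    spans_full_sagittal_width = td$spans_full_sagittal_width,
    coronal_cm = coronal, sagittal_cm = sagittal,
    posterior_present = !posterior_absent,
    lm_ss_x = lm$scapular_spine[1], lm_ss_y = lm$scapular_spine[2],
    lm_ss_z = lm$scapular_spine[3],
    lm_cp_x = lm$coracoid_process[1], lm_cp_y = lm$coracoid_process[2],
    lm_cp_z = lm$coracoid_process[3],
    lm_gt_x = lm$greater_tubercle[1], lm_gt_y = lm$greater_tubercle[2],
    lm_gt_z = lm$greater_tubercle[3]
  )
  list(
    specimen = specimen,
    points = points_df,
    ground_truth = dplyr::bind_rows(truth)
  )
}

#' Generate a synthetic cohort of digitized specimens
#'
#' The reference study design: `n_per_category` specimens (default 4) in
#' each tear category A, B and C. Each specimen draws from its own named
#' sub-stream of the master seed. Category-C specimens lack a posterior
#' region with probability `config$posterior_absent_prob`.
#'
#' @param config A [generator_config()].
#' @param n_per_category Specimens per category (default 4).
#' @return An object of class `fascicle_cohort`: a list with `specimens`,
#'   `points`, `ground_truth` tibbles and the `config`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_config(seed = 1), n_per_category = 1)
#' dplyr::count(coh$points, record_type)
#' }
#' @export
generate_cohort <- function(config, n_per_category = 4) {
  stopifnot(inherits(config, "generator_config"), n_per_category >= 1)
  specs <- purrr::map(
    unlist(lapply(c("A", "B", "C"), function(cat) {
      paste0(cat, seq_len(n_per_category))
    })),
    function(id) {
      generate_specimen(substr(id, 1, 1), config, specimen_id = id)
    }
  )
  out <- list(
    specimens = dplyr::bind_rows(purrr::map(specs, "specimen")),
    points = dplyr::bind_rows(purrr::map(specs, "points")),
    ground_truth = dplyr::bind_rows(purrr::map(specs, "ground_truth")),
    config = config
  )
  class(out) <- "fascicle_cohort"
  out
}

#' @export
print.fascicle_cohort <- function(x, ...) {
  cat(sprintf(
    "<fascicle_cohort> %d specimens (%s), %d fiber bundles, seed %d\n",
    nrow(x$specimens),
    paste(sprintf("%s:%d", names(table(x$specimens$category)),
                  table(x$specimens$category)), collapse = " "),
    nrow(x$ground_truth), x$config$seed
  ))
  invisible(x)
}
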