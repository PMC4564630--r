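#' Descriptive statistics of a numeric sample
#'
#' @param x Numeric vector with at least one finite value.
#' @return A one-row tibble with `n`, `mean`, `sd` (sample, n-1 denominator;
#'   `NA` with a warning for n = 1), `min`, `max`, `median` (even-length
#'   median is the mean of the two middle order statistics).
#' @examples
#' describe(c(67, 95, 64, 89, 73, 77, 94, 94, 82, 76, 83, 91))
#' @export
describe <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || all(is.na(x))) abort("`x` must contain at least one value.")
  x <- x[!is.na(x)]
  s <- if (length(x) < 2) {
    warn("Standard deviation undefined for a single value; returning NA.")
    NA_real_
  } else {
    sd(x)
  }
  tibble::tibble(
    n = length(x), mean = mean(x), sd = s,
    min = min(x), max = max(x), median = median(x)
  )
}

# midranks of the pooled sample and the tie-correction sum  t^3 - t
pooled_ranks <- function(pooled) {
  r <- rank(pooled, ties.method = "average")
  tab <- table(pooled)
  list(ranks = r, tie_sum = sum(tab^3 - tab))
}

new_htest <- function(method_name, statistic, z_value, p_value, method,
                      df = NA_real_, n = integer(), groups = character()) {
  structure(
    list(
      method_name = method_name, statistic = statistic, z_value = z_value,
      p_value = p_value, method = method, df = df, n = n, groups = groups
    ),
    class = "fascicle_htest"
  )
}

#' @export
print.fascicle_htest <- function(x, ...) {
  cat(sprintf("<%s> (%s)\n", x$method_name, x$method))
  cat(sprintf("  statistic = %.4f", x$statistic))
  if (!is.na(x$z_value)) cat(sprintf(", z = %.4f", x$z_value))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  cat(sprintf("  n = %s\n", paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.fascicle_htest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, z_value = x$z_value, df = x$df,
    p_value = x$p_value, method = paste(x$method_name, x$method, sep = "/")
  )
}

#' @export
glance.fascicle_htest <- function(x, ...) {
  tidy(x) |> dplyr::mutate(n_total = sum(x$n))
}

#' Mann-Whitney U test (tie-corrected asymptotic or exact enumeration)
#'
#' Two-sample rank test on midranks. The default `"asymptotic"` method is the
#' normal approximation with tie-corrected variance and *no* continuity
#' correction (the convention of mainstream statistical suites such as SPSS,
#' which this package reproduces): `z = (U - n1*n2/2) / sigma` with
#' `sigma^2 = n1*n2/12 * ((N+1) - sum(t^3 - t)/(N*(N-1)))`, two-sided p from
#' the normal law. The `"exact"` method enumerates all `choose(N, n1)`
#' labelings of the pooled midranks (feasible for small samples) and returns
#' `p = min(1, 2*min(P(U <= u), P(U >= u)))`. Note that at n1 = n2 = 4 the
#' smallest attainable exact two-sided p is 2/70 = 0.0286.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @param max_enumeration Guard on `choose(N, n1)` for the exact method.
#' @return A `fascicle_htest` with U (for the `x` sample), z (asymptotic
#'   only), and the two-sided p value. [tidy()] and [glance()] methods apply.
#' @examples
#' mann_whitney(c(1.88, 1.04, 1.47, 1.40), c(3.33, 5.0, 2.59, 2.59))
#' @export
mann_whitney <- function(x, y, method = c("asymptotic", "exact"),
                         max_enumeration = 2e5) {
  method <- match.arg(method)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("Both groups must be non-empty.")
  N <- n1 + n2
  pr <- pooled_ranks(c(x, y))
  U <- sum(pr$ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (method == "asymptotic") {
    sigma2 <- n1 * n2 / 12 * ((N + 1) - pr$tie_sum / (N * (N - 1)))
    if (sigma2 <= 0) {
      z <- 0
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    return(new_htest("Mann-Whitney U", U, z, p, "asymptotic_tie_corrected",
                     n = c(n1, n2)))
  }

  n_comb <- choose(N, n1)
  if (n_comb > max_enumeration) {
    abort(sprintf(
      "Exact enumeration needs %.0f labelings (> %g); use method = 'asymptotic'.",
      n_comb, max_enumeration
    ))
  }
  combs <- combn(N, n1)
  offset <- n1 * (n1 + 1) / 2
  U_all <- colSums(matrix(pr$ranks[combs], nrow = n1)) - offset
  p_le <- mean(U_all <= U + 1e-9)
  p_ge <- mean(U_all >= U - 1e-9)
  p <- min(1, 2 * min(p_le, p_ge))
  new_htest("Mann-Whitney U", U, NA_real_, p, "exact_permutation",
            n = c(n1, n2))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' H on midranks, divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)`; p from the chi-squared law with k-1
#' degrees of freedom. For two groups, H equals the square of the
#' tie-corrected Mann-Whitney z statistic.
#'
#' @param values Numeric vector of pooled observations, or a list of numeric
#'   group vectors (in which case `groups` is ignored).
#' @param groups Group labels aligned with `values`.
#' @return A `fascicle_htest` with H, df = k-1 and the chi-squared p value.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- !is.na(values)
  values <- as.numeric(values[keep])
  groups <- groups[keep]
  sizes <- table(groups)
  k <- length(sizes)
  if (k < 2 || any(sizes == 0)) abort("Kruskal-Wallis needs at least 2 non-empty groups.")
  N <- length(values)
  pr <- pooled_ranks(values)
  rank_sums <- tapply(pr$ranks, groups, sum)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / as.numeric(sizes)) - 3 * (N + 1)
  correction <- 1 - pr$tie_sum / (N^3 - N)
  if (correction <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / correction
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  new_htest("Kruskal-Wallis", H, NA_real_, p, "asymptotic_tie_corrected",
            df = k - 1, n = as.integer(sizes), groups = names(sizes))
}

#' Bonferroni-adjusted pairwise Mann-Whitney comparisons
#'
#' All pairwise Mann-Whitney U tests between the levels of a grouping
#' column, with significance declared at `alpha / m` (default `m` = number of
#' pairs actually tested; the reference workflow uses alpha 0.05 over 3
#' comparisons, threshold 0.0167). Groups smaller than `min_group_n`
#' observations are excluded with a warning; the adjustment is applied to the
#' p values only through the threshold, so raw p values are reported.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurements and group
#'   labels.
#' @param alpha Family significance level (default 0.05).
#' @param m Number of comparisons for the Bonferroni divisor; defaults to the
#'   number of pairs tested.
#' @param method Passed to [mann_whitney()].
#' @param min_group_n Minimum observations per group to enter testing.
#' @return A tibble with one row per comparison: `comparison`, `n1`, `n2`,
#'   `statistic`, `z_value`, `p_value`, `alpha_adjusted`, `significant`.
#' @export
pairwise_compare <- function(data, value, group, alpha = 0.05, m = NULL,
                             method = c("asymptotic", "exact"),
                             min_group_n = 1) {
  method <- match.arg(method)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  levels_g <- sort(unique(g))
  sizes <- table(g)
  too_small <- names(sizes)[sizes < min_group_n]
  if (length(too_small) > 0) {
    warn(sprintf("Group(s) %s below the minimum size of %d; excluded from testing.",
                 paste(too_small, collapse = ", "), min_group_n))
    levels_g <- setdiff(levels_g, too_small)
  }
  if (length(levels_g) < 2) abort("Need at least 2 testable groups.")
  pairs <- combn(levels_g, 2, simplify = FALSE)
  if (is.null(m)) m <- length(pairs)
  thr <- alpha / m
  purrr::map_dfr(pairs, function(pr) {
    res <- mann_whitney(v[g == pr[1]], v[g == pr[2]], method = method)
    tibble::tibble(
      comparison = paste(pr[1], "vs", pr[2]),
      n1 = res$n[1], n2 = res$n[2],
      statistic = res$statistic, z_value = res$z_value,
      p_value = res$p_value,
      alpha_adjusted = thr,
      significant = res$p_value < thr
    )
  })
}

#' Summarize fascicle architecture per region, part and tear category
#'
#' Builds the median (min-max) summary cells of fiber bundle length and
#' lateral/medial pennation angle for every populated combination of region,
#' part (or the region as a whole) and tear category. Fiber bundles are
#' pooled across the specimens of a category; `n_specimens` records how many
#' specimens contribute, and `stats_eligible` flags cells with enough
#' specimens for hypothesis testing (cells backed by fewer than
#' `min_specimens` specimens are summarized but excluded from tests, as done
#' for a two-specimen cell in the reference analysis).
#'
#' @param measurements Measurement tibble from [measure_bundles()], joined
#'   with a `category` column (and optionally `specimen_id`).
#' @param by_part Summarize per part (`TRUE`, default) or per whole region.
#' @param min_specimens Minimum specimens per cell for `stats_eligible`.
#' @return A tibble of class `fascicle_summary`: one row per cell with
#'   `n_bundles`, `n_specimens`, and `<metric>_{median,min,max}` for
#'   `fbl_cm`, `lat_pa_deg`, `med_pa_deg`.
#' @export
summarize_architecture <- function(measurements, by_part = TRUE,
                                   min_specimens = 3) {
  req <- c("region", "part", "category", "fbl_cm", "lat_pa_deg", "med_pa_deg")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols) > 0) {
    abort(paste0("Measurements are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  lab <- measurements[, c("region", "part", "category")]
  if (anyNA(lab)) abort("Every measurement must carry region, part and category labels.")
  grouped <- if (by_part) {
    dplyr::group_by(measurements, .data$region, .data$part, .data$category)
  } else {
    measurements |>
      dplyr::mutate(part = "whole") |>
      dplyr::group_by(.data$region, .data$part, .data$category)
  }
  out <- grouped |>
    dplyr::summarise(
      n_bundles = dplyr::n(),
      n_specimens = if ("specimen_id" %in% names(measurements)) {
        dplyr::n_distinct(.data$specimen_id)
      } else {
        NA_integer_
      },
      dplyr::across(
        dplyr::all_of(c("fbl_cm", "lat_pa_deg", "med_pa_deg")),
        list(median = median, min = min, max = max),
        .names = "{.col}_{.fn}"
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      stats_eligible = is.na(.data$n_specimens) | .data$n_specimens >= min_specimens
    )
  class(out) <- c("fascicle_summary", class(out))
  out
}

#' Compare architecture across tear categories or parts
#'
#' The package's inference workflow: for each metric and each region (or
#' region x part stratum), a Kruskal-Wallis test across the levels of
#' `between`, followed by Bonferroni-adjusted pairwise Mann-Whitney
#' comparisons. Strata in which a level is backed by fewer than
#' `min_specimens` specimens drop that level from testing with a warning.
#'
#' @param measurements Measurement tibble with `category` (see
#'   [summarize_architecture()]).
#' @param metrics Metric columns to test.
#' @param by Stratifying columns (default `"region"`).
#' @param between Column whose levels are compared (default `"category"`).
#' @param alpha Family significance level.
#' @param m Bonferroni divisor (default: number of pairs per stratum).
#' @param min_specimens Minimum specimens per level to enter testing.
#' @return A tibble with one row per stratum x metric x comparison; the
#'   omnibus Kruskal-Wallis row carries `comparison = "omnibus"`.
#' @export
compare_architecture <- function(measurements,
                                 metrics = c("fbl_cm", "lat_pa_deg", "med_pa_deg"),
                                 by = "region", between = "category",
                                 alpha = 0.05, m = NULL, min_specimens = 3) {
  measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_map(function(df, key) {
      lvl_tab <- if ("specimen_id" %in% names(df)) {
        df |>
          dplyr::distinct(.data$specimen_id, lvl = .data[[between]]) |>
          dplyr::count(.data$lvl)
      } else {
        df |> dplyr::count(lvl = .data[[between]])
      }
      drop_lvls <- lvl_tab$lvl[lvl_tab$n < min_specimens]
      if (length(drop_lvls) > 0) {
        warn(sprintf(
          "Stratum %s: level(s) %s below %d specimens; excluded from testing.",
          paste(unlist(key), collapse = "/"),
          paste(drop_lvls, collapse = ", "), min_specimens
        ))
        df <- df[!(df[[between]] %in% drop_lvls), ]
      }
      if (dplyr::n_distinct(df[[between]]) < 2) return(NULL)
      purrr::map_dfr(metrics, function(metric) {
        kw <- kruskal_wallis(df[[metric]], df[[between]])
        omnibus <- tibble::tibble(
          metric = metric, comparison = "omnibus", test = "kruskal_wallis",
          statistic = kw$statistic, z_value = NA_real_, p_value = kw$p_value,
          alpha_adjusted = alpha, significant = kw$p_value < alpha
        )
        pw <- pairwise_compare(df, !!rlang::sym(metric), !!rlang::sym(between),
                               alpha = alpha, m = m) |>
          dplyr::mutate(test = "mann_whitney", metric = metric) |>
          dplyr::select("metric", "comparison", "test", "statistic",
                        "z_value", "p_value", "alpha_adjusted", "significant")
        dplyr::bind_rows(omnibus, pw)
      }) |>
        dplyr::mutate(!!!as.list(key), .before = 1)
    }) |>
    dplyr::bind_rows()
}
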