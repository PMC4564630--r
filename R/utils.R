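# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a master seed and a stream label.
# Lets each specimen/layer own an independent stream so adding bundles never
# perturbs previously generated ones. The multiplier keeps h * 48271 + k below
# 2^53 so the modular arithmetic stays exact in doubles (a larger multiplier
# silently drops the low bits that distinguish similar labels).
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(label)
  h <- 1
  for (k in codes) {
    h <- (h * 48271 + k) %% 2147483647
  }
  # one extra mixing pass decorrelates labels sharing long prefixes
  for (k in rev(codes)) {
    h <- (h * 48271 + k) %% 2147483647
  }
  as.integer(h)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Coerce points to an n x 3 numeric matrix with columns x, y, z.
as_point_matrix <- function(points, what = "points") {
  if (is.data.frame(points)) {
    cols <- intersect(c("x_cm", "y_cm", "z_cm"), names(points))
    if (length(cols) == 3) {
      points <- as.matrix(points[, cols])
    } else if (all(c("x", "y", "z") %in% names(points))) {
      points <- as.matrix(points[, c("x", "y", "z")])
    } else {
      abort(sprintf("`%s` must have columns x,y,z or x_cm,y_cm,z_cm.", what))
    }
  }
  points <- as.matrix(points)
  if (ncol(points) != 3 || !is.numeric(points)) {
    abort(sprintf("`%s` must be an n x 3 numeric matrix.", what))
  }
  if (!all(is.finite(points))) {
    abort(sprintf("`%s` contains non-finite coordinates.", what))
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  points
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) abort(sprintf("`%s` has (near-)zero norm.", what))
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))
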