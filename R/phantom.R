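#' Specification of a synthetic vein phantom
#'
#' The phantom emulates a 192x192 NIR dorsal-hand capture: a bright or dark
#' background with a smooth planar illumination gradient, dark curvilinear
#' veins of Gaussian cross-section, and additive Gaussian sensor noise. The
#' defaults describe the low-contrast bright regime (mean intensity about
#' 0.65, vein contrast 30 levels); `background_mean < 0.5` gives the dark
#' regime.
#'
#' @param side image side length (pixels, default 192).
#' @param n_veins number of veins (default 3).
#' @param width_range bounds of the vein half-width sigma_v (pixels).
#' @param depth vein darkness below the background, in levels (default 30).
#' @param background_mean target mean background intensity in (0,1).
#' @param gradient_amp peak-to-peak amplitude of the planar illumination
#'   gradient (levels).
#' @param noise_sd additive Gaussian noise standard deviation (levels).
#' @param seed RNG seed (integer) or `NULL` for the session RNG state.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 192L, n_veins = 3L, width_range = c(1.8, 2.6),
                         depth = 30, background_mean = 0.65, gradient_amp = 25,
                         noise_sd = 5, seed = NULL) {
  if (background_mean <= 0 || background_mean >= 1)
    stop("background_mean must be in (0, 1)")
  if (n_veins < 0L) stop("n_veins must be >= 0")
  if (depth <= 0) stop("depth must be > 0")
  structure(list(side = as.integer(side), n_veins = as.integer(n_veins),
                 width_range = width_range, depth = depth,
                 background_mean = background_mean,
                 gradient_amp = gradient_amp, noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phantom_spec")
}

# minimum distance from every pixel to a sampled curve, computed by
# stamping local distance patches around each curve sample; distances
# beyond `radius` are left at Inf (their Gaussian contribution and mask
# membership are both negligible/void there)
curve_distance_field <- function(pts, side, radius) {
  D <- matrix(Inf, side, side)
  r <- ceiling(radius)
  for (i in seq_len(nrow(pts))) {
    py <- pts[i, 1]; px <- pts[i, 2]
    r0 <- max(1L, floor(py) - r); r1 <- min(side, ceiling(py) + r)
    c0 <- max(1L, floor(px) - r); c1 <- min(side, ceiling(px) + r)
    if (r0 > r1 || c0 > c1) next
    dr <- (r0:r1) - py
    dc <- (c0:c1) - px
    patch <- sqrt(outer(dr^2, dc^2, "+"))
    D[r0:r1, c0:c1] <- pmin(D[r0:r1, c0:c1], patch)
  }
  D
}

# a smooth random curve traversing the image: a quadratic Bezier whose
# endpoints sit on two different image edges, with a random interior
# control point — smooth, non-self-crossing, and guaranteed to span the
# field of view like a dorsal vein crossing the ROI
random_vein_curve <- function(side, step = 0.5) {
  edges <- sample.int(4L, 2L)
  edge_point <- function(edge) {
    pos <- stats::runif(1, 0.1 * side, 0.9 * side)
    switch(edge, c(1, pos), c(side, pos), c(pos, 1), c(pos, side))
  }
  p0 <- edge_point(edges[1])
  p2 <- edge_point(edges[2])
  p1 <- stats::runif(2, 0.2 * side, 0.8 * side)
  n <- ceiling(3 * side)
  t <- seq(0, 1, length.out = n)
  ys <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
  xs <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  cbind(ys, xs)
}

#' Generate one synthetic vein phantom with its ground-truth mask
#'
#' Background: `background_mean * 255` plus a zero-mean planar gradient of
#' peak-to-peak amplitude `gradient_amp` in a random direction. Each vein is
#' a smooth random curve rendered by subtracting
#' `depth * exp(-d^2 / (2 sigma_v^2))`, where `d` is the distance to the
#' curve; the truth mask marks pixels with `d <= sigma_v * sqrt(2 ln 2)`
#' (the profile's half-maximum width). Gaussian noise is added last and the
#' result clamped to `[0, 255]`. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a `gray_image`), `mask` (a `seg_mask`) and
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  side <- spec$side
  yy <- matrix(rep(seq_len(side), side), side)
  xx <- matrix(rep(seq_len(side), each = side), side)

  phi <- stats::runif(1, 0, 2 * pi)
  t <- (yy - (side + 1) / 2) * sin(phi) + (xx - (side + 1) / 2) * cos(phi)
  span <- max(t) - min(t)
  bg <- spec$background_mean * 255 +
    if (span > 0) spec$gradient_amp * (t - mean(t)) / span else 0

  img <- bg
  mask <- matrix(FALSE, side, side)
  if (spec$n_veins > 0L) {
    for (v in seq_len(spec$n_veins)) {
      sigma_v <- stats::runif(1, spec$width_range[1], spec$width_range[2])
      pts <- random_vein_curve(side)
      D <- curve_distance_field(pts, side, radius = 4 * sigma_v)
      fin <- is.finite(D)
      drop <- matrix(0, side, side)
      drop[fin] <- spec$depth * exp(-D[fin]^2 / (2 * sigma_v^2))
      img <- img - drop
      mask <- mask | (D <= sigma_v * sqrt(2 * log(2)))
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(side * side, 0, spec$noise_sd)
  }
  list(image = gray_image(img), mask = seg_mask(mask), spec = spec)
}

#' Generate a reproducible dataset of phantoms
#'
#' Per-item seeds are derived from the master seed by fixed arithmetic
#' (`(seed * 1009 + 7919 * i) mod (2^31 - 1)`), so the dataset is
#' reproducible and its items mutually distinct.
#'
#' @param n number of phantoms (>= 1).
#' @param spec a [phantom_spec()] shared by all items (its `seed` field is
#'   ignored).
#' @param seed master seed (integer).
#' @return list of `n` phantoms as returned by [generate_phantom()].
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- as.integer((as.numeric(seed) * 1009 + 7919 * i) %% 2147483647)
    generate_phantom(s)
  })
}
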