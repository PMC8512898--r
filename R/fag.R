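#' Fuzzify a grayscale image
#'
#' Linear mapping of gray levels into the fuzzy membership domain `[0,1]`
#' using the image's own observed minimum and maximum:
#' `m = (I - I_min) / (I_max - I_min)`.
#'
#' @param img a non-constant `gray_image`.
#' @return a `fuzzy_image`: numeric matrix of memberships in `[0,1]` with
#'   attribute `L` (gray levels of the source image).
#' @export
fuzzify <- function(img) {
  L <- levels_of(img)
  m <- as_pixel_matrix(img)
  lo <- min(m); hi <- max(m)
  if (hi <= lo) stop("degenerate input: constant image cannot be fuzzified")
  structure((m - lo) / (hi - lo), L = L, class = c("fuzzy_image", "matrix", "array"))
}

#' @export
print.fuzzy_image <- function(x, ...) {
  cat(sprintf("<fuzzy_image %dx%d, mean %.3f, sd %.3f>\n",
              nrow(x), ncol(x), mean(x), stats::sd(x)))
  invisible(x)
}

#' Heaviside step function (left-continuous)
#'
#' `0` for `x <= 0`, `1` for `x > 0`.
#'
#' @param x numeric.
#' @return 0/1 numeric of the same shape.
#' @export
heaviside <- function(x) as.numeric(x > 0)

#' Image statistics driving the adaptive gamma branch
#'
#' The adaptive exponent is `gamma = -log2(sigma)` where `sigma` is the
#' population standard deviation of the memberships; the branch is chosen by
#' the mean membership `mu` (bright iff `mu >= 0.5`). `gamma` is clamped to
#' `[gamma_min, gamma_max]` so near-constant images remain well-defined.
#'
#' @param f a `fuzzy_image` (or numeric matrix in `[0,1]`).
#' @param gamma_min,gamma_max clamp bounds for the exponent.
#' @return list with `mu`, `sigma`, `gamma`, `branch`.
#' @export
compute_agc_stats <- function(f, gamma_min = 0.1, gamma_max = 10) {
  x <- as.numeric(f)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))   # population sd
  gamma <- if (sigma > 0 && sigma < 1) -log2(sigma) else if (sigma <= 0) Inf else 0
  gamma <- min(max(gamma, gamma_min), gamma_max)
  list(mu = mu, sigma = sigma, gamma = gamma,
       branch = if (mu >= 0.5) "bright" else "dark")
}

#' Adaptive gamma transform of a membership plane
#'
#' Bright images (`mu >= 0.5`): the Heaviside factor zeroes the correction,
#' giving the pure power law `m^gamma`. Dark images (`mu < 0.5`):
#' `m^gamma / (m^gamma + (1 - m^gamma) * mu^gamma)` — the per-pixel
#' normalization `k = m^gamma + (1 - m^gamma) mu^gamma` lifts dark content.
#' Both branches fix 0 and 1 and map `[0,1]` into `[0,1]`.
#'
#' @param f a `fuzzy_image`.
#' @param stats statistics from [compute_agc_stats()] (computed from `f` if
#'   omitted).
#' @return transformed `fuzzy_image`.
#' @export
agc_transform <- function(f, stats = compute_agc_stats(f)) {
  g <- stats$gamma
  p <- unclass(f)^g
  out <- if (stats$branch == "bright") {
    # c = 1 / (1 + Heaviside(0.5 - mu) * (k - 1)) = 1 when mu >= 0.5
    p
  } else {
    denom <- p + (1 - p) * stats$mu^g
    r <- p / denom
    r[denom == 0] <- 0   # I = 0 with mu = 0: 0 stays a fixed point
    r
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  structure(out, L = attr(f, "L"), class = class(f))
}

#' Defuzzify a membership plane back to gray levels
#'
#' Hyperbolic (exponential) inverse mapping:
#' `I = (L-1) / (e^{-1} - 1) * (e^{-m} - 1)`, strictly increasing in the
#' membership `m`, sending 0 to 0 and 1 to `L-1`; the result is rounded
#' (half away from zero) and clamped to `[0, L-1]`.
#'
#' @param f a `fuzzy_image` (memberships in `[0,1]`).
#' @param L gray levels of the output (defaults to the source image's).
#' @return a `gray_image`.
#' @export
defuzzify <- function(f, L = NULL) {
  if (is.null(L)) L <- attr(f, "L")
  if (is.null(L)) L <- 256L
  vals <- (L - 1) / (exp(-1) - 1) * (exp(-unclass(f)) - 1)
  gray_image(vals, L = L)
}

#' Fuzzy adaptive gamma (FAG) enhancement
#'
#' Three stages: fuzzification ([fuzzify()]), adaptive-gamma modification of
#' the membership plane ([agc_transform()]), and hyperbolic defuzzification
#' ([defuzzify()]). Every stage is monotone, so pixel intensity ordering is
#' preserved.
#'
#' @param img a non-constant `gray_image`.
#' @param gamma_min,gamma_max clamp bounds for the adaptive exponent.
#' @return enhanced `gray_image`.
#' @export
apply_fag <- function(img, gamma_min = 0.1, gamma_max = 10) {
  f <- fuzzify(img)
  st <- compute_agc_stats(f, gamma_min, gamma_max)
  defuzzify(agc_transform(f, st), L = levels_of(img))
}

#' Fuzzy histogram hyperbolization (FHH) baseline
#'
#' Memberships are raised to the hedge power `beta_h` and then defuzzified
#' hyperbolically. Hedge below 1 brightens; above 1 darkens.
#'
#' @param img a non-constant `gray_image`.
#' @param beta_h hedge factor, > 0 (default 1.5).
#' @return enhanced `gray_image`.
#' @export
apply_fhh <- function(img, beta_h = 1.5) {
  if (!is.numeric(beta_h) || beta_h <= 0) stop("parameter error: hedge factor must be > 0")
  f <- fuzzify(img)
  g <- structure(unclass(f)^beta_h, L = attr(f, "L"), class = class(f))
  defuzzify(g, L = levels_of(img))
}

#' Adaptive gamma correction (AGC) baseline on gray levels
#'
#' The plain (non-fuzzy) adaptive gamma: intensities are normalized to
#' `[0,1]` by `L-1` (not by observed min/max), transformed with
#' [agc_transform()] using the normalized image's statistics, and rescaled
#' linearly by `L-1`.
#'
#' @param img a `gray_image`.
#' @param gamma_min,gamma_max clamp bounds for the exponent.
#' @return enhanced `gray_image`.
#' @export
apply_agc_gray <- function(img, gamma_min = 0.1, gamma_max = 10) {
  L <- levels_of(img)
  n <- as_pixel_matrix(img) / (L - 1)
  f <- structure(n, L = L, class = c("fuzzy_image", "matrix", "array"))
  st <- compute_agc_stats(f, gamma_min, gamma_max)
  out <- agc_transform(f, st)
  gray_image(unclass(out) * (L - 1), L = L)
}
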