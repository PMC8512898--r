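#' Fusion parameters
#'
#' Weights and constants for the improved weighted-average fusion of the
#' CLAHE and FAG outputs. The defaults are the bright-image profile
#' (`alpha = 7`); the dark profile uses `alpha = 1` (see [fusion_profile()]).
#'
#' @param w0 weight of the second image (FAG output) in `[0,1]`.
#' @param alpha additive brightness constant, in gray-level units.
#' @param beta weight of the difference term.
#' @param alpha_inside if `TRUE`, uses the alternative reading in which
#'   `alpha` is added to `g1` inside the weighted average
#'   (`... + w0 * (g1 + alpha) ...`) rather than to the whole sum.
#' @return a list of class `fusion_params`.
#' @export
fusion_params <- function(w0 = 0.5, alpha = 7, beta = 0.01, alpha_inside = FALSE) {
  if (w0 < 0 || w0 > 1) stop("parameter error: w0 must be in [0, 1]")
  structure(list(w0 = w0, alpha = alpha, beta = beta,
                 alpha_inside = isTRUE(alpha_inside)),
            class = "fusion_params")
}

#' Fusion parameter profile for bright or dark images
#'
#' Bright images (mean intensity at or above 0.5) use `alpha = 7`; dark
#' images use `alpha = 1`. `w0 = 0.5` and `beta = 0.01` in both.
#'
#' @param profile `"bright"` or `"dark"`.
#' @return a [fusion_params()] object.
#' @export
fusion_profile <- function(profile = c("bright", "dark")) {
  profile <- match.arg(profile)
  fusion_params(w0 = 0.5, alpha = if (profile == "bright") 7 else 1, beta = 0.01)
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch: images must have the same dimensions")
}

#' Plain weighted-average fusion
#'
#' Per pixel: `(1 - w0) * g0 + w0 * g1`, rounded and clamped.
#'
#' @param g0,g1 `gray_image`s of equal size.
#' @param w0 weight of `g1` in `[0,1]`.
#' @return fused `gray_image`.
#' @export
weighted_average <- function(g0, g1, w0 = 0.5) {
  check_same_shape(g0, g1)
  L <- levels_of(g0)
  f <- (1 - w0) * as_pixel_matrix(g0) + w0 * as_pixel_matrix(g1)
  gray_image(f, L = L)
}

#' Improved weighted-average fusion
#'
#' Per pixel: `f = (1 - w0) * g0 + w0 * g1 + alpha - beta * (g0 - g1)` —
#' the weighted average raised by the constant `alpha` and balanced by the
#' `beta`-scaled difference of the two inputs. Rounded and clamped to
#' `[0, L-1]`.
#'
#' @param g0 CLAHE output (`gray_image`).
#' @param g1 FAG output (`gray_image`), same size.
#' @param params a [fusion_params()] object.
#' @return fused `gray_image`.
#' @export
improved_weighted_average <- function(g0, g1, params = fusion_params()) {
  check_same_shape(g0, g1)
  L <- levels_of(g0)
  a <- as_pixel_matrix(g0)
  b <- as_pixel_matrix(g1)
  f <- if (params$alpha_inside) {
    (1 - params$w0) * a + params$w0 * (b + params$alpha) - params$beta * (a - b)
  } else {
    (1 - params$w0) * a + params$w0 * b + params$alpha - params$beta * (a - b)
  }
  gray_image(f, L = L)
}
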