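#' Mean squared error between two images
#'
#' `(1/N) * sum((x_n - y_n)^2)` on the 0--255 intensity scale.
#'
#' @param x,y `gray_image`s (or numeric matrices) of equal size.
#' @return non-negative numeric scalar (levels squared).
#' @export
mse <- function(x, y) {
  a <- if (inherits(x, "gray_image")) as_pixel_matrix(x) else x
  b <- if (inherits(y, "gray_image")) as_pixel_matrix(y) else y
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 / MSE)` in decibels; identical images return `Inf`.
#'
#' @inheritParams mse
#' @return PSNR in dB.
#' @export
psnr <- function(x, y) {
  e <- mse(x, y)
  if (e == 0) return(Inf)
  10 * log10(255^2 / e)
}

#' Global structural similarity index
#'
#' Single-statistics SSIM computed from whole-image means, population
#' variances and covariance (not the windowed original):
#' `(2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' with the standard stabilizers `c1 = (0.01 * 255)^2`, `c2 = (0.03 * 255)^2`.
#'
#' @inheritParams mse
#' @param c1,c2 stabilizing constants.
#' @return similarity in `[-1, 1]`.
#' @export
ssim_global <- function(x, y, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  a <- if (inherits(x, "gray_image")) as_pixel_matrix(x) else x
  b <- if (inherits(y, "gray_image")) as_pixel_matrix(y) else y
  check_same_shape(a, b)
  mx <- mean(a); my <- mean(b)
  vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
  cxy <- mean((a - mx) * (b - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Pixelwise confusion counts between a predicted and a truth mask
#'
#' TP: vein pixel segmented as vein; FP: background segmented as vein;
#' TN: background segmented as background; FN: vein segmented as background.
#'
#' @param mask predicted binary mask (`seg_mask` or 0/1 matrix).
#' @param truth ground-truth binary mask, same size.
#' @return list with `tp`, `fp`, `tn`, `fn` (counts summing to the pixel
#'   count).
#' @export
confusion <- function(mask, truth) {
  p <- unclass(mask); t <- unclass(truth)
  check_same_shape(p, t)
  if (!all(p %in% c(0L, 1L)) || !all(t %in% c(0L, 1L)))
    stop("masks must be binary (0/1)")
  list(tp = sum(p == 1L & t == 1L),
       fp = sum(p == 1L & t == 0L),
       tn = sum(p == 0L & t == 0L),
       fn = sum(p == 0L & t == 1L))
}

#' Segmentation scores from confusion counts
#'
#' Sensitivity `Se = TP/(TP+FN)`, accuracy `Acc = (TP+TN)/(TP+TN+FP+FN)`,
#' and Dice coefficient `Dice = 2TP/(2TP+FP+FN)`. A zero denominator yields
#' `NaN` with a warning.
#'
#' @param counts a list with `tp`, `fp`, `tn`, `fn` (from [confusion()]).
#' @return list with `se`, `acc`, `dice`.
#' @export
seg_scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  se <- if (tp + fn > 0) tp / (tp + fn) else { warning("Se undefined: no vein pixels in truth"); NaN }
  acc <- (tp + tn) / (tp + tn + fp + fn)
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else {
    warning("Dice undefined: both masks empty"); NaN
  }
  list(se = se, acc = acc, dice = dice)
}

#' Enhancement-quality metrics of an enhanced image against its original
#'
#' @param original,enhanced `gray_image`s of equal size.
#' @return list with `mse`, `psnr`, `ssim`.
#' @export
quality_metrics <- function(original, enhanced) {
  list(mse = mse(original, enhanced),
       psnr = psnr(original, enhanced),
       ssim = ssim_global(original, enhanced))
}
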