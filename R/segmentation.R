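#' MF-FODG segmentation parameters
#'
#' The matched filter (MF) models the vein cross-section as an (inverted)
#' Gaussian; its first-order derivative (FDOG) discriminates true vessels
#' from step edges: a vein centerline gives a strong MF response but a
#' near-zero local mean of the FDOG response, while non-vessel edges score
#' high on both.
#'
#' @param sigma Gaussian cross-section scale in pixels (default 2).
#' @param kernel_length along-vessel extent of the kernel in pixels (default 9).
#' @param n_orientations number of filter orientations over 180 degrees
#'   (default 12, i.e. 15-degree steps); must be >= 4.
#' @param c_thresh threshold coefficient multiplying the mean MF response
#'   (default 4.5, calibrated so the
#'   thresholded stripe on a clean matched Gaussian vein approximates the
#'   profile's half-maximum width).
#' @param mean_window odd side length of the local-mean window applied to
#'   the absolute FDOG response (default 13, the kernel-support scale).
#' @param min_object minimum connected-component area kept, in pixels
#'   (8-connectivity; default 30).
#' @param opening_radius radius of an optional morphological opening applied
#'   after thresholding (0 disables; opening never adds vein pixels).
#' @return a list of class `mf_fodg_params`.
#' @export
mf_fodg_params <- function(sigma = 2, kernel_length = 9L, n_orientations = 12L,
                           c_thresh = 4.5, mean_window = 13L, min_object = 30L,
                           opening_radius = 0L) {
  if (sigma <= 0) stop("parameter error: sigma must be > 0")
  if (n_orientations < 4L) stop("parameter error: need at least 4 orientations")
  if (mean_window %% 2L != 1L) stop("parameter error: mean_window must be odd")
  if (c_thresh <= 0) stop("parameter error: c_thresh must be > 0")
  structure(list(sigma = sigma, kernel_length = kernel_length,
                 n_orientations = as.integer(n_orientations),
                 c_thresh = c_thresh, mean_window = as.integer(mean_window),
                 min_object = as.integer(min_object),
                 opening_radius = as.integer(opening_radius)),
            class = "mf_fodg_params")
}

# square odd support grid and rotated coordinates for a kernel at angle
# theta (radians); u runs across the vessel, v along it
kernel_coords <- function(sigma, length, theta) {
  s <- ceiling(max(3 * sigma, length / 2))
  g <- seq(-s, s)
  x <- matrix(rep(g, each = length(g)), length(g))   # column offset
  y <- matrix(rep(g, times = length(g)), length(g))  # row offset
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  keep <- abs(u) <= 3 * sigma & abs(v) <= length / 2
  list(u = u, keep = keep)
}

#' Matched-filter kernel for a dark Gaussian vessel profile
#'
#' Cross-section profile `-exp(-u^2 / 2 sigma^2)` (negative: veins are dark,
#' so centerlines give a positive filter response), truncated at
#' `|u| <= 3 sigma` across and `|v| <= length/2` along the vessel, rotated
#' by `theta`, and mean-subtracted over its support so the entries sum to
#' zero (the response is invariant to constant offsets).
#'
#' @param sigma cross-section scale (pixels).
#' @param length along-vessel extent (pixels).
#' @param theta orientation in radians.
#' @return a square numeric kernel matrix (odd side).
#' @export
mf_kernel <- function(sigma, length = 9L, theta = 0) {
  kc <- kernel_coords(sigma, length, theta)
  k <- matrix(0, nrow(kc$u), ncol(kc$u))
  prof <- -exp(-kc$u[kc$keep]^2 / (2 * sigma^2))
  k[kc$keep] <- prof - mean(prof)
  k
}

#' First-order derivative-of-Gaussian kernel
#'
#' Cross-section profile proportional to `-u * exp(-u^2 / 2 sigma^2)`, with
#' the same support and rotation as [mf_kernel()]. Odd symmetry across the
#' vessel axis: the kernel vanishes on the centerline and its entries sum to
#' zero.
#'
#' @inheritParams mf_kernel
#' @return a square numeric kernel matrix (odd side).
#' @export
fdog_kernel <- function(sigma, length = 9L, theta = 0) {
  kc <- kernel_coords(sigma, length, theta)
  k <- matrix(0, nrow(kc$u), ncol(kc$u))
  k[kc$keep] <- -kc$u[kc$keep] * exp(-kc$u[kc$keep]^2 / (2 * sigma^2))
  k
}

# reflect-padded convolution (symmetric padding, edge included)
conv_reflect <- function(m, kernel) {
  s <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (nr <= s || nc <= s) stop("image smaller than kernel support")
  ri <- c(s:1, 1:nr, nr:(nr - s + 1L))
  ci <- c(s:1, 1:nc, nc:(nc - s + 1L))
  p <- m[ri, ci]
  out <- EBImage::imageData(EBImage::filter2(EBImage::Image(p), kernel,
                                             boundary = "circular"))
  out[(s + 1L):(s + nr), (s + 1L):(s + nc)]
}

# label connected components with 8-connectivity; returns integer matrix
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))   # 4-connected labels
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal adjacencies down-right and down-left
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  lab
}

# drop components smaller than min_object (8-connectivity)
remove_small_objects <- function(mask, min_object) {
  if (min_object <= 1L || !any(mask > 0)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Segment veins with a matched-filter / FDOG orientation bank
#'
#' For each of `n_orientations` angles the image is convolved with the MF
#' and FDOG kernels (reflect padding). `H` is the pixelwise maximum MF
#' response over orientations and `D` the FDOG response at each pixel's
#' argmax orientation. The local mean of `|D|` over a `mean_window` square,
#' rescaled to `[0,1]`, modulates an adaptive threshold
#' `T = (1 + Dm) * c_thresh * mean(H)`: vein pixels must clear `T` with a
#' strictly positive MF response (so flat images yield empty masks).
#' Morphological refinement — optional opening, then removal of connected
#' components below `min_object` pixels (8-connectivity) — never adds vein
#' pixels.
#'
#' @param img a `gray_image` (typically enhancement output).
#' @param params a [mf_fodg_params()] object.
#' @return a `seg_mask` (integer 0/1 matrix) of the same size.
#' @export
segment_veins <- function(img, params = mf_fodg_params()) {
  m <- as_pixel_matrix(img)
  thetas <- pi * (seq_len(params$n_orientations) - 1L) / params$n_orientations
  H <- NULL; D <- NULL; arg <- NULL
  for (i in seq_along(thetas)) {
    h <- conv_reflect(m, mf_kernel(params$sigma, params$kernel_length, thetas[i]))
    d <- conv_reflect(m, fdog_kernel(params$sigma, params$kernel_length, thetas[i]))
    if (is.null(H)) {
      H <- h; D <- d; arg <- matrix(1L, nrow(m), ncol(m))
    } else {
      upd <- h > H
      H[upd] <- h[upd]
      D[upd] <- d[upd]
      arg[upd] <- i
    }
  }
  W <- params$mean_window
  box <- matrix(1 / (W * W), W, W)
  Dm <- conv_reflect(abs(D), box)
  mx <- max(Dm)
  if (mx > 0) Dm <- Dm / mx
  Tmap <- (1 + Dm) * params$c_thresh * mean(H)
  raw <- (H >= Tmap & H > 0) * 1L
  storage.mode(raw) <- "integer"
  if (params$opening_radius > 0L && any(raw > 0)) {
    brush <- EBImage::makeBrush(2L * params$opening_radius + 1L, shape = "disc")
    raw <- EBImage::imageData(EBImage::opening(raw, brush))
    storage.mode(raw) <- "integer"
  }
  seg_mask(remove_small_objects(raw, params$min_object))
}

#' Isodata threshold of a grayscale image
#'
#' Iterates `t <- (mean(pixels <= t) + mean(pixels > t)) / 2` starting from
#' the global mean until the change drops below 0.5 levels. Used for the
#' automatic part of semi-automatic ground-truth labeling.
#'
#' @param img a `gray_image` (or numeric matrix) with at least two distinct
#'   values.
#' @param max_iter iteration cap.
#' @return the converged threshold (numeric scalar).
#' @export
isodata_threshold <- function(img, max_iter = 100L) {
  x <- if (inherits(img, "gray_image")) as_pixel_matrix(img) else as.matrix(img)
  x <- as.numeric(x)
  if (length(unique(x)) < 2L) stop("degenerate input: constant image has no threshold")
  t <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 0.5) { t <- t_new; break }
    t <- t_new
  }
  t
}
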