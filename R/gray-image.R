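#' Construct a grayscale image object
#'
#' The package's working currency is an 8-bit style grayscale image: an
#' integer matrix of intensity levels in `[0, L-1]`, row-major with the
#' origin at the top-left.
#'
#' @param pixels numeric matrix; values are rounded (half away from zero)
#'   and clamped to `[0, L-1]`.
#' @param L number of gray levels (default 256).
#' @return an object of class `gray_image`: an integer matrix with
#'   attribute `L`.
#' @export
gray_image <- function(pixels, L = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  px <- clamp_levels(pixels, L)
  structure(px, L = as.integer(L), class = c("gray_image", class(px)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, L=%d, range [%d, %d], mean %.2f>\n",
              nrow(x), ncol(x), levels_of(x), min(x), max(x), mean(x)))
  invisible(x)
}

#' Number of gray levels of an image
#' @param img a `gray_image`
#' @return integer L
#' @export
levels_of <- function(img) {
  L <- attr(img, "L")
  if (is.null(L)) 256L else as.integer(L)
}

# round half away from zero -- R's round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# round + clamp to [0, L-1], return integer matrix
clamp_levels <- function(x, L = 256L) {
  y <- round_half_away(x)
  y[y < 0] <- 0
  y[y > L - 1] <- L - 1
  storage.mode(y) <- "integer"
  y
}

as_pixel_matrix <- function(img) {
  x <- unclass(img)
  attr(x, "L") <- NULL
  storage.mode(x) <- "double"
  x
}

#' Read a grayscale image from PNG or JPG
#'
#' Color inputs are converted to single-channel luminance
#' (0.299 R + 0.587 G + 0.114 B). Alpha channels are dropped.
#'
#' @param path path to a PNG or JPG file.
#' @return a [gray_image()] with `L = 256`.
#' @export
load_gray <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else {
      EBImage::imageData(EBImage::readImage(path))
    }
  }, error = function(e) {
    stop("input error: cannot decode image file: ", path, " (", conditionMessage(e), ")")
  })
  if (ext != "png" && length(dim(arr)) >= 2L) {
    # EBImage stores x (columns) in dim 1; transpose back to row/col
    arr <- if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
  }
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  gray_image(arr * 255, L = 256L)
}

#' Write a grayscale image or binary mask as PNG
#'
#' Masks (see [segment_veins()]) are written with values {0, 255}.
#'
#' @param img a `gray_image` or a binary 0/1 `seg_mask` matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_gray <- function(img, path) {
  if (inherits(img, "seg_mask")) {
    m <- unclass(img) * 255L
    png::writePNG(m / 255, path)
  } else {
    L <- levels_of(img)
    png::writePNG(as_pixel_matrix(img) / (L - 1), path)
  }
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' Pixels with value >= 128 (on the 0--255 scale) are vein (1), the rest
#' background (0).
#'
#' @param path PNG path.
#' @return a `seg_mask`: integer 0/1 matrix.
#' @export
load_mask <- function(path) {
  img <- load_gray(path)
  seg_mask(as_pixel_matrix(img) >= 128)
}

#' Construct a binary segmentation mask
#' @param m logical or 0/1 matrix, 1 = vein.
#' @return integer 0/1 matrix of class `seg_mask`.
#' @export
seg_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  v <- unclass(m)
  if (is.logical(v)) v <- v * 1L
  if (!all(v %in% c(0L, 1L))) stop("mask values must be binary (0/1)")
  storage.mode(v) <- "integer"
  structure(v, class = c("seg_mask", class(v)))
}

#' Standardize an image to a square working size
#'
#' Takes the largest centered square of the input, then resizes it with
#' bilinear interpolation to `side` x `side`. With `crop = "none"` the
#' (possibly non-square) image is resized directly.
#'
#' @param img a `gray_image`.
#' @param side target side length in pixels (default 192).
#' @param crop `"center"` (default) or `"none"`.
#' @return a `side` x `side` `gray_image`.
#' @export
preprocess <- function(img, side = 192L, crop = c("center", "none")) {
  crop <- match.arg(crop)
  if (side < 8L) stop("side must be >= 8")
  L <- levels_of(img)
  m <- as_pixel_matrix(img)
  if (crop == "center") {
    s <- min(dim(m))
    r0 <- (nrow(m) - s) %/% 2L
    c0 <- (ncol(m) - s) %/% 2L
    m <- m[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
  }
  if (nrow(m) == side && ncol(m) == side) {
    return(gray_image(m, L = L))
  }
  r <- EBImage::resize(EBImage::Image(m), w = side, h = side, filter = "bilinear")
  gray_image(EBImage::imageData(r), L = L)
}

#' Classify an image as bright or dark by mean intensity
#'
#' The mean intensity on the `[0,1]` scale is `mean(pixels)/(L-1)`; images
#' with mean at or above 0.5 are bright, below 0.5 dark. This drives both
#' the adaptive gamma branch and the fusion profile.
#'
#' @param img a `gray_image`.
#' @return a list with `label` (`"bright"` or `"dark"`) and `mean_intensity`.
#' @export
classify_brightness <- function(img) {
  mu <- mean(as_pixel_matrix(img)) / (levels_of(img) - 1)
  list(label = if (mu >= 0.5) "bright" else "dark", mean_intensity = mu)
}
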