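#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization splits the image into a
#' grid of non-overlapping contextual regions (tiles), equalizes each tile
#' with a clipped histogram, and blends the per-tile mappings bilinearly.
#'
#' @param tiles_x,tiles_y tile counts along image columns / rows (default 8).
#' @param clip_limit maximum histogram bin height as a fraction of the tile
#'   pixel count, in (0, 1]. Default 0.01 (1% of tile pixels).
#' @param range `"full"` maps each tile onto the full `[0, L-1]` output range
#'   (the canonical equalization); `"tile"` uses the tile's observed min/max.
#' @return a list of class `clahe_params`.
#' @export
clahe_params <- function(tiles_x = 8L, tiles_y = 8L, clip_limit = 0.01,
                         range = c("full", "tile")) {
  if (tiles_x < 1L || tiles_y < 1L) stop("tile counts must be >= 1")
  if (!is.numeric(clip_limit) || clip_limit <= 0 || clip_limit > 1)
    stop("parameter error: clip_limit must be in (0, 1]")
  structure(list(tiles_x = as.integer(tiles_x), tiles_y = as.integer(tiles_y),
                 clip_limit = clip_limit, range = match.arg(range)),
            class = "clahe_params")
}

#' Clip a histogram and redistribute the excess
#'
#' Bins are capped at `ceiling(clip_limit * n_pixels)`; the total clipped
#' excess is redistributed uniformly across all bins, with the remainder
#' after integer division given one count each to the lowest-index bins.
#' The total count is conserved exactly.
#'
#' @param hist integer vector of per-level counts (length L).
#' @param clip_limit fraction of `n_pixels` in (0, 1].
#' @param n_pixels total pixel count (must equal `sum(hist)`).
#' @return clipped counts, same length, same sum.
#' @export
clip_histogram <- function(hist, clip_limit, n_pixels = sum(hist)) {
  if (clip_limit <= 0) stop("parameter error: clip_limit must be > 0")
  L <- length(hist)
  if (!is.integer(hist)) storage.mode(hist) <- "integer"
  cap <- as.integer(ceiling(clip_limit * n_pixels))
  excess <- sum(pmax(hist - cap, 0L))
  h <- pmin(hist, cap)
  if (excess > 0L) {
    each <- excess %/% L
    rem <- excess %% L
    h <- h + each
    if (rem > 0L) h[seq_len(rem)] <- h[seq_len(rem)] + 1L
  }
  h
}

#' Per-tile equalization mapping
#'
#' The mapping sends gray level v to
#' `round((g_max - g_min) * Pf(v) + g_min)` where Pf is the cumulative
#' probability distribution of the (clipped) tile histogram.
#'
#' @param hist per-level counts.
#' @param g_min,g_max output range endpoints.
#' @return list with `lut` (length-L integer vector, monotone), `Pf`,
#'   `g_min`, `g_max`.
#' @export
tile_mapping <- function(hist, g_min = 0L, g_max = 255L) {
  total <- sum(hist)
  if (total <= 0) stop("empty histogram")
  Pf <- cumsum(hist) / total
  lut <- as.integer(round_half_away((g_max - g_min) * Pf + g_min))
  list(lut = lut, Pf = Pf, g_min = g_min, g_max = g_max)
}

# tile index boundaries: n values split into k nearly-equal runs
tile_breaks <- function(n, k) {
  b <- floor(seq(0L, n, length.out = k + 1L))
  as.integer(b)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is decomposed into `tiles_y` x `tiles_x` contextual regions;
#' each region's histogram is clipped ([clip_histogram()]) and turned into
#' an equalization mapping ([tile_mapping()]) anchored at the tile center;
#' every pixel's output is the bilinear blend of the mappings of its (up to
#' four) surrounding tile centers, with border pixels falling back on the
#' nearest available mapping.
#'
#' @param img a `gray_image`.
#' @param params a [clahe_params()] object.
#' @return enhanced `gray_image` of the same size.
#' @export
apply_clahe <- function(img, params = clahe_params()) {
  L <- levels_of(img)
  m <- unclass(img)
  nr <- nrow(m); nc <- ncol(m)
  ty <- params$tiles_y; tx <- params$tiles_x
  if (ty > nr || tx > nc) stop("parameter error: tile grid larger than image")

  rb <- tile_breaks(nr, ty)
  cb <- tile_breaks(nc, tx)

  # per-tile luts: array L x ty x tx
  luts <- array(0L, dim = c(L, ty, tx))
  cy <- numeric(ty); cx <- numeric(tx)
  for (i in seq_len(ty)) {
    rows <- (rb[i] + 1L):rb[i + 1L]
    cy[i] <- (rb[i] + rb[i + 1L] + 1) / 2   # tile center (1-based row coordinate)
    for (j in seq_len(tx)) {
      cols <- (cb[j] + 1L):cb[j + 1L]
      if (i == 1L) cx[j] <- (cb[j] + cb[j + 1L] + 1) / 2
      tile <- m[rows, cols]
      h <- tabulate(tile + 1L, nbins = L)
      h <- clip_histogram(h, params$clip_limit, length(tile))
      if (params$range == "full") {
        luts[, i, j] <- tile_mapping(h, 0L, L - 1L)$lut
      } else {
        luts[, i, j] <- tile_mapping(h, min(tile), max(tile))$lut
      }
    }
  }

  # bilinear blend between tile centers; outside the center lattice the
  # nearest mapping is used (weight pinned to the border)
  interp_idx <- function(coord, centers) {
    k <- length(centers)
    if (k == 1L) return(list(lo = rep(1L, length(coord)), hi = rep(1L, length(coord)),
                             w = rep(0, length(coord))))
    lo <- findInterval(coord, centers)
    lo[lo < 1L] <- 1L
    lo[lo > k - 1L] <- k - 1L
    hi <- lo + 1L
    w <- (coord - centers[lo]) / (centers[hi] - centers[lo])
    w[w < 0] <- 0
    w[w > 1] <- 1
    list(lo = lo, hi = hi, w = w)
  }
  ri <- interp_idx(seq_len(nr), cy)
  ci <- interp_idx(seq_len(nc), cx)

  v <- as.integer(m) + 1L                      # level index per pixel, column-major
  RLO <- rep(ri$lo, nc); RHI <- rep(ri$hi, nc); WY <- rep(ri$w, nc)
  CLO <- rep(ci$lo, each = nr); CHI <- rep(ci$hi, each = nr); WX <- rep(ci$w, each = nr)

  look <- function(ti, tj) luts[cbind(v, ti, tj)]
  out <- (1 - WY) * (1 - WX) * look(RLO, CLO) +
         (1 - WY) * WX       * look(RLO, CHI) +
         WY       * (1 - WX) * look(RHI, CLO) +
         WY       * WX       * look(RHI, CHI)
  gray_image(matrix(out, nr, nc), L = L)
}
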