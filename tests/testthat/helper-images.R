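# Fixtures are generated in code; no image files are stored.

# seeded random test image; low-contrast by default, like NIR captures
random_image <- function(seed, n = 32L, lo = 80L, hi = 180L) {
  set.seed(seed)
  gray_image(matrix(sample(lo:hi, n * n, replace = TRUE), n, n))
}

# image with an exact target mean intensity on the [0,1] scale
image_with_mean <- function(mu, n = 10L) {
  total <- round(mu * 255 * n * n)
  base <- total %/% (n * n)
  extra <- total - base * n * n
  v <- rep(base, n * n)
  if (extra > 0) v[seq_len(extra)] <- v[seq_len(extra)] + 1L
  gray_image(matrix(v, n, n))
}

# straight vein segment of Gaussian cross-section centered in the image at
# a given angle (fixed length, so rotations keep the same vein mass);
# returns image and half-maximum mask
straight_vein_image <- function(side = 96L, sigma_v = 2, depth = 60,
                                bg = 200, theta = 0, len = 0.8 * side) {
  yy <- matrix(rep(seq_len(side), side), side)
  xx <- matrix(rep(seq_len(side), each = side), side)
  c0 <- (side + 1) / 2
  # distance to the centered segment of length len at angle theta
  along <- (xx - c0) * cos(theta) + (yy - c0) * sin(theta)
  across <- -(xx - c0) * sin(theta) + (yy - c0) * cos(theta)
  over <- pmax(abs(along) - len / 2, 0)
  d <- sqrt(across^2 + over^2)
  img <- gray_image(bg - depth * exp(-d^2 / (2 * sigma_v^2)))
  mask <- seg_mask(d <= sigma_v * sqrt(2 * log(2)))
  list(image = img, mask = mask)
}

# independent global histogram-equalization oracle: cumulative
# distribution mapped onto [0, L-1], rounding half away from zero
global_he_oracle <- function(img) {
  L <- 256L
  v <- as.integer(unclass(img))
  h <- tabulate(v + 1L, nbins = L)
  Pf <- cumsum(h) / sum(h)
  lut <- as.integer(floor((L - 1) * Pf + 0.5))
  matrix(lut[v + 1L], nrow(img), ncol(img))
}

# scalar global-SSIM oracle written from the formula, population moments
ssim_scalar_oracle <- function(x, y, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  a <- as.numeric(unclass(x)); b <- as.numeric(unclass(y))
  n <- length(a)
  mx <- sum(a) / n; my <- sum(b) / n
  vx <- sum((a - mx)^2) / n; vy <- sum((b - my)^2) / n
  cxy <- sum((a - mx) * (b - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}
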