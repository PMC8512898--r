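test_that("fuzzification is the linear min/max normalization", {
  m <- matrix(c(10L, 200L, 105L, 50L), 2, 2)
  f <- fuzzify(gray_image(m))
  expect_equal(f[1, 1], 0)
  expect_equal(f[2, 1], 1)
  expect_equal(f[1, 2], 0.5)
  expect_true(all(f >= 0 & f <= 1))
  expect_error(fuzzify(gray_image(matrix(42L, 3, 3))), "degenerate")
})

test_that("Heaviside is 0 at and below zero, 1 above", {
  expect_equal(heaviside(0), 0)
  expect_equal(heaviside(0.2), 1)
  expect_equal(heaviside(-3), 0)
  expect_equal(heaviside(c(-1, 0, 1e-9)), c(0, 0, 1))
})

test_that("adaptive exponent is -log2(sigma) with boundary-inclusive branch", {
  f01 <- structure(matrix(c(0, 1), 1, 2), L = 256L,
                   class = c("fuzzy_image", "matrix", "array"))
  st <- compute_agc_stats(f01)
  expect_equal(st$mu, 0.5)
  expect_equal(st$sigma, 0.5)
  expect_equal(st$gamma, 1)           # -log2(0.5)
  expect_equal(st$branch, "bright")   # mu = 0.5 is bright

  f2 <- structure(matrix(c(0.25, 0.75), 1, 2), L = 256L,
                  class = c("fuzzy_image", "matrix", "array"))
  expect_equal(compute_agc_stats(f2)$gamma, 2)   # sigma = 0.25

  # clamping keeps near-constant planes finite
  fc <- structure(matrix(0.5 + c(-1e-8, 1e-8), 1, 2), L = 256L,
                  class = c("fuzzy_image", "matrix", "array"))
  expect_equal(compute_agc_stats(fc)$gamma, 10)
})

fuzzy <- function(m) structure(m, L = 256L, class = c("fuzzy_image", "matrix", "array"))

test_that("both AGC branches match scalar evaluation and fix the endpoints", {
  # bright branch: pure power law
  fb <- fuzzy(matrix(c(0.25, 0, 1, 0.7), 2, 2))
  stb <- list(mu = 0.6, sigma = 0.25, gamma = 2, branch = "bright")
  ob <- agc_transform(fb, stb)
  expect_equal(ob[1, 1], 0.0625)
  expect_equal(ob[2, 1], 0)
  expect_equal(ob[1, 2], 1)

  # dark branch: normalized power ratio, per-pixel k
  fd <- fuzzy(matrix(c(0.5, 0, 1, 0.3), 2, 2))
  std <- list(mu = 0.4, sigma = 0.5, gamma = 1, branch = "dark")
  od <- agc_transform(fd, std)
  expect_equal(od[1, 1], 0.5 / (0.5 + 0.5 * 0.4))   # 0.714285...
  expect_equal(od[2, 1], 0)
  expect_equal(od[1, 2], 1)

  # vectorized equals an independent scalar loop to 1e-12, both branches
  set.seed(5)
  for (branch in c("bright", "dark")) {
    vals <- matrix(runif(100), 10, 10)
    f <- fuzzy(vals)
    st <- compute_agc_stats(f)
    st$branch <- branch
    st$mu <- if (branch == "bright") max(st$mu, 0.5) else min(st$mu, 0.49)
    got <- agc_transform(f, st)
    for (i in seq_along(vals)) {
      x <- vals[i]^st$gamma
      want <- if (branch == "bright") x else x / (x + (1 - x) * st$mu^st$gamma)
      expect_lt(abs(got[i] - want), 1e-12)
    }
  }

  # maps [0,1] into [0,1] on a dense grid in both branches
  g <- fuzzy(matrix(seq(0, 1, length.out = 1e4), 100, 100))
  for (st in list(list(mu = 0.7, sigma = 0.1, gamma = 3.32, branch = "bright"),
                  list(mu = 0.3, sigma = 0.1, gamma = 3.32, branch = "dark"))) {
    out <- agc_transform(g, st)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("hyperbolic defuzzification is exact at the endpoints and increasing", {
  f <- fuzzy(matrix(c(0, 1, 0.5), 1, 3))
  out <- defuzzify(f, L = 256)
  expect_equal(out[1, 1], 0L)
  expect_equal(out[1, 2], 255L)
  expect_equal(out[1, 3], 159L)   # 255*(exp(-0.5)-1)/(exp(-1)-1) = 158.73 -> 159

  m <- seq(0, 1, length.out = 1e4)
  raw <- 255 / (exp(-1) - 1) * (exp(-m) - 1)
  expect_true(all(diff(raw) > 0))
  got <- unclass(defuzzify(fuzzy(matrix(m, 100, 100)), L = 256))
  expect_identical(got[, ], matrix(as.integer(floor(raw + 0.5)), 100, 100)[, ])
})

test_that("FAG preserves pixel ordering and hits the full output range", {
  for (s in 1:10) {
    img <- random_image(s, n = 24)
    out <- apply_fag(img)
    o <- order(as.integer(unclass(img)))
    expect_true(all(diff(as.integer(unclass(out))[o]) >= 0L),
                label = sprintf("seed %d ordering", s))
  }
  img <- random_image(20, n = 24)
  out <- unclass(apply_fag(img))
  expect_equal(min(out), 0L)
  expect_equal(max(out), 255L)
  expect_error(apply_fag(gray_image(matrix(7L, 4, 4))), "degenerate")
})

test_that("FHH hedge behaves as documented", {
  img <- random_image(9, n = 16)
  h1 <- apply_fhh(img, beta_h = 1)
  ref <- defuzzify(fuzzify(img), L = 256)
  expect_identical(unclass(h1)[, ], unclass(ref)[, ])

  h2 <- apply_fhh(img, beta_h = 2)
  expect_lt(mean(unclass(h2)), mean(unclass(h1)))   # larger hedge darkens

  expect_equal(min(unclass(h2)), 0L)
  expect_equal(max(unclass(h2)), 255L)
  expect_error(apply_fhh(img, beta_h = 0), "hedge")
})

test_that("gray-level AGC fixes 0 and 255 and is a power law on bright images", {
  expect_true(all(unclass(apply_agc_gray(gray_image(matrix(0L, 4, 4)))) == 0L))

  img <- image_with_mean(0.7, n = 12)
  px <- unclass(img); px[1, 1] <- 255L; px[1, 2] <- 0L
  img <- gray_image(px)
  out <- apply_agc_gray(img)
  expect_equal(unclass(out)[1, 1], 255L)
  expect_equal(unclass(out)[1, 2], 0L)

  n <- unclass(img) / 255
  mu <- mean(n); sg <- sqrt(mean((n - mu)^2))
  g <- min(max(-log2(sg), 0.1), 10)
  want <- floor(255 * n^g + 0.5)
  expect_identical(unclass(out)[, ], matrix(as.integer(want), 12, 12)[, ])
})
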