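# Schmid and RFS/MR8 filter banks, their responses, and CLAHE.

test_that("schmid kernels are zero-sum, radially symmetric, correctly valued", {
  for (p in list(c(2, 1), c(6, 2), c(10, 3))) {
    k <- schmid_kernel(p[1], p[2])
    expect_lt(abs(sum(k$kernel)), 1e-12)
    expect_equal(k$kernel, t(k$kernel), tolerance = 1e-14)
    n <- nrow(k$kernel)
    expect_equal(k$kernel, k$kernel[n:1, ], tolerance = 1e-14)
    expect_equal(k$kernel, k$kernel[, n:1], tolerance = 1e-14)
    # centre: cos(0) = exp(0) = 1, so value is (F0 + 1) / L1
    ctr <- (n + 1) / 2
    expect_equal(k$kernel[ctr, ctr], (k$f0 + 1) / k$l1, tolerance = 1e-12)
    expect_equal(sum(abs(k$kernel)), 1, tolerance = 1e-12)
  }
  expect_error(schmid_kernel(-1, 1), "positive")
})

test_that("schmid bank has the 12 published (sigma, tau) pairs in order", {
  bank <- schmid_bank()
  expect_length(bank, 12L)
  expect_equal(bank[[1]]$sigma, 2)
  expect_equal(bank[[1]]$tau, 1)
  pairs <- t(vapply(bank, function(k) c(k$sigma, k$tau), numeric(2)))
  expect_equal(pairs[, 1], c(2, 4, 4, 6, 6, 6, 8, 8, 8, 10, 10, 10))
  expect_equal(pairs[, 2], c(1, 1, 2, 1, 2, 3, 1, 2, 3, 1, 2, 3))
  for (k in bank) expect_lt(abs(sum(k$kernel)), 1e-12)
})

test_that("schmid kernels are isotropic under arbitrary-angle rotation", {
  # bilinear resampling of the kernel at 37 degrees, compared on the
  # inscribed disc (corners leave the support); the residual is pure
  # resampling error, which grows with the radial frequency tau / sigma --
  # the smoothest kernel is rotation-invariant to < 2% relative L2, the
  # sharpest stays bounded
  rotate <- function(k, th) {
    n <- nrow(k); h <- (n + 1) / 2
    rot <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      y <- i - h; x <- j - h
      ys <- cos(th) * y - sin(th) * x + h
      xs <- sin(th) * y + cos(th) * x + h
      y0 <- floor(ys); x0 <- floor(xs)
      if (y0 >= 1 && y0 < n && x0 >= 1 && x0 < n) {
        fy <- ys - y0; fx <- xs - x0
        rot[i, j] <- k[y0, x0] * (1 - fy) * (1 - fx) +
          k[y0 + 1, x0] * fy * (1 - fx) +
          k[y0, x0 + 1] * (1 - fy) * fx + k[y0 + 1, x0 + 1] * fy * fx
      }
    }
    rot
  }
  rel_err <- function(sigma, tau) {
    k <- schmid_kernel(sigma, tau)$kernel
    n <- nrow(k); h <- (n + 1) / 2
    rot <- rotate(k, 37 * pi / 180)
    d <- sqrt(outer((1:n) - h, (1:n) - h, function(a, b) a^2 + b^2))
    m <- d <= h - 2
    sqrt(sum(((rot - k)[m])^2)) / sqrt(sum((k[m])^2))
  }
  expect_lt(rel_err(10, 1), 0.02)
  expect_lt(rel_err(6, 1), 0.05)
  expect_lt(rel_err(2, 1), 0.30)
})

test_that("schmid responses: zero on constants, kernel on impulses, equivariant", {
  bank1 <- schmid_bank()[1]
  flat <- matrix(0.4, 40, 40)
  expect_lt(max(abs(schmid_responses(flat, bank1)[[1]])), 1e-10)

  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  resp <- schmid_responses(imp, bank1)[[1]]
  k <- bank1[[1]]$kernel  # symmetric, so flip == kernel
  h <- (nrow(k) - 1) / 2
  expect_equal(resp[(16 - h):(16 + h), (16 - h):(16 + h)], k,
               tolerance = 1e-10)

  img <- random_raster(32, 32, seed = 40)
  r1 <- schmid_responses(img, bank1)[[1]]
  rot <- t(img)[, nrow(img):1]  # 90-degree rotation
  r2 <- schmid_responses(rot, bank1)[[1]]
  expect_equal(t(r1)[, nrow(r1):1], r2, tolerance = 1e-6)
})

test_that("RFS bank has 38 kernels with the published structure", {
  bank <- rfs_bank()
  expect_length(bank$kernels, 38L)
  expect_equal(sum(bank$meta$family %in% c("edge", "bar")), 36L)
  expect_equal(sort(unique(bank$meta$orientation[1:36])) / (pi / 6), 0:5,
               tolerance = 1e-12)
  # edge kernels antisymmetric, bar kernels symmetric along the derivative
  # axis (theta = 0: derivative along rows)
  e0 <- bank$kernels[[which(bank$meta$family == "edge" &
                              bank$meta$scale == 1 &
                              bank$meta$orientation == 0)]]
  b0 <- bank$kernels[[which(bank$meta$family == "bar" &
                              bank$meta$scale == 1 &
                              bank$meta$orientation == 0)]]
  expect_equal(e0, -e0[nrow(e0):1, ], tolerance = 1e-12)
  expect_equal(b0, b0[nrow(b0):1, ], tolerance = 1e-12)
  # zero-mean except the Gaussian; all L1-normalized
  sums <- vapply(bank$kernels, sum, numeric(1))
  gidx <- which(bank$meta$family == "gaussian")
  expect_lt(max(abs(sums[-gidx])), 1e-10)
  expect_equal(sums[gidx], 1, tolerance = 1e-10)
  for (k in bank$kernels) expect_equal(sum(abs(k)), 1, tolerance = 1e-10)
})

test_that("MR8 yields 8 responses with the documented behavior on constants", {
  bank <- rfs_bank()
  flat <- matrix(0.37, 60, 60)
  mr <- mr8_responses(flat, bank)
  expect_length(mr$responses, 8L)
  for (i in c(1:6, 8)) expect_lt(max(abs(mr$responses[[i]])), 1e-9)
  expect_equal(mr$responses[[7]], flat, tolerance = 1e-9)
})

test_that("MR8 responses are equivariant under 90-degree rotation", {
  # even families (bar, gaussian, log) are equivariant under the signed
  # collapse; the odd edge family needs the polarity-invariant (rectified)
  # collapse, since a 90-degree rotation maps some orientations onto their
  # negated 180-degree counterparts
  bank <- rfs_bank()
  img <- random_raster(56, 56, seed = 77)
  rot90 <- function(m) t(m)[, nrow(m):1]
  a <- mr8_responses(img, bank)
  b <- mr8_responses(rot90(img), bank)
  for (i in 4:8)
    expect_equal(rot90(a$responses[[i]]), b$responses[[i]], tolerance = 1e-6)
  ar <- mr8_responses(img, bank, rectify = TRUE)
  br <- mr8_responses(rot90(img), bank, rectify = TRUE)
  for (i in 1:8)
    expect_equal(rot90(ar$responses[[i]]), br$responses[[i]],
                 tolerance = 1e-6)
})

test_that("mr8_response_at matches the full stack", {
  bank <- rfs_bank()
  img <- random_raster(40, 40, seed = 13)
  full <- mr8_responses(img, bank)
  for (i in c(1, 3, 5, 7, 8))
    expect_equal(mr8_response_at(img, i, bank), full$responses[[i]],
                 tolerance = 1e-12)
})

test_that("filter responses are bounded by the input range (L1 kernels)", {
  img <- random_raster(30, 30, seed = 3)
  rng <- diff(range(img))
  for (r in schmid_responses(img, schmid_bank()[c(1, 5)]))
    expect_lte(max(abs(r)), rng + 1e-9)
})

test_that("CLAHE is range-preserving, identity on constants, boosts contrast", {
  expect_equal(clahe_enhance(matrix(0.2, 32, 32)), matrix(0.2, 32, 32))

  # low-contrast step of 0.05 on top of mild noise
  set.seed(50)
  img <- matrix(0.45, 64, 64) + matrix(rnorm(64 * 64, 0, 0.003), 64, 64)
  img[, 33:64] <- img[, 33:64] + 0.05
  out <- clahe_enhance(img, clip_limit = 0.02, tiles = c(4, 4))
  expect_true(all(out >= 0 & out <= 1))
  step_before <- mean(img[, 33:64]) - mean(img[, 1:32])
  step_after <- mean(out[, 33:64]) - mean(out[, 1:32])
  expect_gte(step_after, step_before)
})
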