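# FCM clustering, edge-region selection and texture-noise inpainting.

test_that("analysis region enlarges the radius by the configured margin", {
  est <- disc_estimate(c(110, 110), 60)
  reg <- enlarged_analysis_region(est, margin = 50, roi_dim = c(221, 221))
  expect_equal(reg$radius, 110)
  expect_equal(formals(enlarged_analysis_region)$margin, 50)
  pix <- which(reg$mask, arr.ind = TRUE) - 1
  expect_true(all((pix[, 1] - 110)^2 + (pix[, 2] - 110)^2 <= 110^2))
  expect_warning(enlarged_analysis_region(est, 50, roi_dim = c(150, 150)),
                 "clipped")
})

test_that("feature stack is 3-deep and z-scored over the region", {
  set.seed(60)
  img <- matrix(runif(120 * 120), 120, 120)
  est <- disc_estimate(c(60, 60), 10)
  reg <- enlarged_analysis_region(est, 30, roi_dim = c(120, 120))
  feats <- build_feature_stack(img, reg)
  expect_equal(dim(feats), c(120L, 120L, 3L))
  for (k in 1:3) {
    v <- feats[, , k][reg$mask]
    expect_lt(abs(mean(v)), 1e-8)
    expect_equal(sd(v), 1, tolerance = 1e-8)
  }
  # constant input: all zero-mean filters fire 0, z-score degenerates to 0
  flat <- build_feature_stack(matrix(0.5, 120, 120), reg)
  expect_equal(max(abs(flat[, , 1])), 0)
  expect_equal(max(abs(flat[, , 2])), 0)
})

test_that("fcm memberships are normalized and the objective never increases", {
  set.seed(70)
  pts <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 4), 100, 2))
  res <- fcm(pts, fcm_config(seed = 5))
  expect_equal(rowSums(res$memberships), rep(1, 200), tolerance = 1e-12)
  expect_true(all(res$memberships >= 0))
  expect_true(all(diff(res$objective) <= 1e-8))
})

test_that("fcm separates distant blobs exactly and is seed-deterministic", {
  set.seed(71)
  a <- matrix(rnorm(160, 0, 1), 80, 2)
  b <- matrix(rnorm(160, 10, 1), 80, 2)   # 10 sigma apart
  pts <- rbind(a, b)
  res <- fcm(pts, fcm_config(seed = 3))
  truth <- apply(rbind(res$centers), 1, function(ctr)
    sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  expect_equal(res$labels, max.col(-truth))
  expect_identical(fcm(pts, fcm_config(seed = 3))$memberships,
                   res$memberships)
  expect_error(fcm(matrix(1, 10, 2)), "distinct")
})

test_that("fcm agrees with the e1071 reference on well-posed data", {
  skip_if_not_installed("e1071")
  set.seed(72)
  pts <- rbind(matrix(rnorm(300, 0), 150, 2), matrix(rnorm(300, 6), 150, 2))
  mine <- fcm(pts, fcm_config(seed = 1, tolerance = 1e-9,
                              max_iterations = 300))
  ref <- e1071::cmeans(pts, centers = 2, m = 2, iter.max = 300)
  # same partition up to label swap
  agree <- mean(mine$labels == ref$cluster)
  expect_true(agree > 0.99 || agree < 0.01)
  d <- as.matrix(dist(rbind(mine$centers, ref$centers)))[1:2, 3:4]
  expect_lt(min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1]), 0.05)
})

test_that("edge-region selection keeps the majority-complement ring only", {
  nr <- 201
  rr <- matrix(0:(nr - 1), nr, nr); cc <- t(rr)
  d <- sqrt((rr - 100)^2 + (cc - 100)^2)
  est <- disc_estimate(c(100, 100), 50)
  reg <- enlarged_analysis_region(est, 40, roi_dim = c(nr, nr))
  # annulus labelled TRUE (edge-like, ~20% of region), plus a small blob
  annulus <- d >= 45 & d <= 55
  blob <- (rr - 30)^2 + (cc - 100)^2 <= 7^2
  labels <- annulus | blob
  erm <- edge_region_mask(labels, reg, open_se_radius = 3)
  expect_true(all(erm$edge_mask[d >= 47 & d <= 53]))
  expect_false(any(erm$edge_mask & blob))         # not the max component
  expect_false(any(erm$edge_mask & erm$background_mask))
  expect_true(all(xor(erm$edge_mask, erm$background_mask)[reg$mask]))

  # a small speckle well inside the background never reaches the edge mask
  # (it is not part of the largest complement component)
  hole <- (rr - 130)^2 + (cc - 100)^2 <= 2^2
  erm2 <- edge_region_mask(labels | hole, reg, open_se_radius = 3)
  expect_false(any(erm2$edge_mask & hole))
})

test_that("degenerate labels make edge-region selection fail loudly", {
  est <- disc_estimate(c(50, 50), 20)
  reg <- enlarged_analysis_region(est, 20, roi_dim = c(101, 101))
  expect_error(edge_region_mask(matrix(FALSE, 101, 101), reg, 5),
               "noise suppression failed")
})

test_that("suppress_noise inpaints the background and freezes the edge ridge", {
  nr <- 151
  rr <- matrix(0:(nr - 1), nr, nr); cc <- t(rr)
  d <- sqrt((rr - 75)^2 + (cc - 75)^2)
  tex <- exp(-(d - 50)^2 / (2 * 4^2))          # disc-rim ridge
  blob <- (rr - 75)^2 + (cc - 75)^2 <= 10^2    # cup-noise simulacrum
  tex_noisy <- tex + 0.8 * blob
  est <- disc_estimate(c(75, 75), 50)
  reg <- enlarged_analysis_region(est, 20, roi_dim = c(nr, nr))
  ring <- d >= 44 & d <= 56
  erm <- structure(list(edge_mask = ring & reg$mask,
                        background_mask = reg$mask & !ring,
                        analysis_radius = reg$radius),
                   class = "edge_region_mask")
  out <- suppress_noise(tex_noisy, erm)
  expect_identical(out[erm$edge_mask], tex_noisy[erm$edge_mask])
  # planted noise blob is flattened: residual contrast < 10% of original
  surround <- d > 15 & d < 30
  before <- mean(tex_noisy[blob]) - mean(tex_noisy[surround])
  after <- mean(out[blob]) - mean(out[surround])
  expect_lt(abs(after), 0.1 * abs(before))
  # maximum principle over the inpainted region
  expect_gte(min(out[erm$background_mask]), min(tex_noisy[!erm$background_mask]) - 1e-9)
  expect_lte(max(out[erm$background_mask]), max(tex_noisy[!erm$background_mask]) + 1e-9)
})

test_that("suppress_noise with an empty background is the identity", {
  tex <- random_raster(50, 50, seed = 80)
  erm <- structure(list(edge_mask = matrix(TRUE, 50, 50),
                        background_mask = matrix(FALSE, 50, 50),
                        analysis_radius = 10),
                   class = "edge_region_mask")
  expect_identical(suppress_noise(tex, erm), tex)
})
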