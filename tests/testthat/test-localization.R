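# Template matching, Canny, circle Hough and ROI bookkeeping.

test_that("HSI intensity is the per-pixel channel mean", {
  white <- array(1, dim = c(8, 8, 3))
  expect_equal(hsi_intensity(white), matrix(1, 8, 8))

  flat <- array(0, dim = c(4, 4, 3))
  flat[, , 1] <- 0.9; flat[, , 2] <- 0.6; flat[, , 3] <- 0.3
  expect_equal(hsi_intensity(flat), matrix(0.6, 4, 4))

  set.seed(42)
  rgb <- array(runif(10 * 12 * 3), dim = c(10, 12, 3))
  ref <- matrix(0, 10, 12)
  for (i in 1:10) for (j in 1:12) ref[i, j] <- mean(rgb[i, j, ])
  expect_equal(hsi_intensity(rgb), ref, tolerance = 1e-12)

  expect_error(hsi_intensity(matrix(1, 3, 3)), "3-channel")
})

test_that("disc template is bright-cored, radially symmetric, 401 px by default", {
  tmpl <- build_disc_template()
  expect_equal(dim(tmpl), c(401L, 401L))
  expect_gt(tmpl[201, 201], tmpl[1, 1])
  expect_equal(tmpl, t(tmpl), tolerance = 1e-12)
  expect_equal(tmpl, tmpl[401:1, ], tolerance = 1e-12)
  expect_equal(tmpl, tmpl[, 401:1], tolerance = 1e-12)
  expect_error(template_spec(side = 400), "odd")
})

test_that("pearson_match equals the direct evaluation of the correlation", {
  gray <- random_raster(64, 64, seed = 101)
  tmpl <- build_disc_template(template_spec(side = 9, core_diameter = 5,
                                            edge_softness = 2))
  res <- pearson_match(gray, tmpl)
  expect_equal(res$score_map, oracle_pearson_map(gray, tmpl),
               tolerance = 1e-10)
})

test_that("pearson_match scores a perfect and affine-rescaled window as 1", {
  tmpl <- build_disc_template(template_spec(side = 21, core_diameter = 11,
                                            edge_softness = 4))
  gray <- matrix(0.2, 60, 60)
  gray[11:31, 16:36] <- 0.3 * tmpl + 0.1   # positive affine transform
  res <- pearson_match(gray, tmpl)
  expect_equal(res$score, 1, tolerance = 1e-9)
  expect_equal(unname(res$peak), c(20, 25))  # 0-based centre of the window
})

test_that("pearson score map is invariant under positive affine rescaling", {
  gray <- random_raster(48, 48, seed = 5)
  tmpl <- random_raster(9, 9, seed = 6)
  a <- pearson_match(gray, tmpl)$score_map
  b <- pearson_match(0.4 * gray + 0.3, tmpl)$score_map
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("constant windows and constant templates are handled", {
  tmpl <- random_raster(5, 5, seed = 3)
  gray <- matrix(0.5, 20, 20)            # all windows constant
  res <- pearson_match(gray, tmpl)
  expect_true(all(res$score_map == 0))
  expect_error(pearson_match(gray, matrix(1, 5, 5)), "constant")
})

test_that("canny finds a sharp circle and nothing in flat or maxed-out input", {
  expect_false(any(canny_edges(matrix(0.5, 64, 64))))

  nr <- 201
  rr <- matrix(0:(nr - 1), nr, nr); cc <- t(rr)
  d <- sqrt((rr - 100)^2 + (cc - 100)^2)
  img <- ifelse(d <= 60, 0.9, 0.1)
  edges <- canny_edges(img, high_threshold = 0.4, sigma = 2)
  ep <- which(edges, arr.ind = TRUE) - 1
  expect_gt(nrow(ep), 100)
  radial <- sqrt((ep[, 1] - 100)^2 + (ep[, 2] - 100)^2)
  expect_true(all(abs(radial - 60) <= 3))

  # at the threshold ceiling at most isolated maximal-gradient pixels remain
  expect_lte(sum(canny_edges(img, high_threshold = 1.0, sigma = 2)), 10)
})

test_that("hough accumulator equals the brute-force voting oracle", {
  set.seed(8)
  edges <- matrix(runif(64 * 64) < 0.02, 64, 64)
  edges[10, 10] <- TRUE
  for (R in c(9L, 14L)) {
    ep <- which(edges, arr.ind = TRUE)
    off <- odseg:::midpoint_circle_offsets(R)
    acc <- odseg:::.hough_accumulate(ep[, 1] - 1L, ep[, 2] - 1L, 64L, 64L,
                                     off[, 1], off[, 2])
    expect_identical(acc, oracle_hough_accumulator(edges, R))
  }
})

test_that("hough_circle recovers a planted circle and obeys the vote ordering", {
  nr <- 128
  mk_circle <- function(ctr, R, frac = 1) {
    off <- odseg:::midpoint_circle_offsets(R)
    keep <- seq_len(ceiling(nrow(off) * frac))
    pts <- cbind(ctr[1] + off[keep, 1], ctr[2] + off[keep, 2])
    pts <- pts[pts[, 1] >= 0 & pts[, 1] < nr & pts[, 2] >= 0 & pts[, 2] < nr, ]
    m <- matrix(FALSE, nr, nr)
    m[pts + 1] <- TRUE
    m
  }
  edges <- mk_circle(c(64, 64), 30L)
  est <- hough_circle(edges, radii = c(20L, 30L, 40L))
  expect_equal(unname(est$center), c(64, 64))
  expect_equal(est$radius, 30)

  # full circle (more votes) beats a partial circle
  edges2 <- mk_circle(c(40, 40), 25L) | mk_circle(c(90, 90), 25L, frac = 0.5)
  est2 <- hough_circle(edges2, radii = 25L)
  expect_equal(unname(est2$center), c(40, 40))

  expect_error(hough_circle(matrix(FALSE, 10, 10), radii = 5L),
               "localization failed")
  expect_error(hough_circle(edges, radii = integer(0)), "non-empty")
})

test_that("hough_circle matches a full brute-force pipeline oracle", {
  # oracle: accumulate per radius with loops, 3x3 box smooth, global max
  # with smallest-radius then row-major tie-break
  set.seed(31)
  edges <- matrix(runif(96 * 96) < 0.01, 96, 96)
  off20 <- odseg:::midpoint_circle_offsets(20L)
  pts <- cbind(48 + off20[, 1], 48 + off20[, 2])
  edges[pts[pts[, 1] >= 1 & pts[, 1] <= 96 & pts[, 2] >= 1 & pts[, 2] <= 96, ]] <- TRUE

  radii <- c(15L, 20L, 25L)
  best <- NULL
  for (R in radii) {
    acc <- oracle_hough_accumulator(edges, R)
    sm <- matrix(0, 96, 96)
    for (i in 1:96) for (j in 1:96) {
      rs <- max(1, i - 1):min(96, i + 1); cs <- max(1, j - 1):min(96, j + 1)
      sm[i, j] <- sum(acc[rs, cs])
    }
    sm <- sm / nrow(odseg:::midpoint_circle_offsets(R))
    mx <- max(sm)
    if (is.null(best) || mx > best$score) {
      idx <- which(sm == mx, arr.ind = TRUE)
      ord <- order((idx[, 1] - 1) * 96 + (idx[, 2] - 1))
      best <- list(center = idx[ord[1], ] - 1, radius = R, score = mx)
    }
  }
  est <- hough_circle(edges, radii)
  expect_equal(unname(est$center), unname(best$center))
  expect_equal(est$radius, best$radius)
})

test_that("extract_roi slices the interior and pads corners by replication", {
  img <- random_raster(100, 120, seed = 12)
  roi <- extract_roi(img, c(50, 60), side = 21)
  expect_equal(roi$image, img[41:61, 51:71])
  expect_equal(unname(roi$offset - roi$pad), c(40, 50))

  corner <- extract_roi(img, c(0, 0), side = 21)
  expect_equal(dim(corner$image), c(21L, 21L))
  expect_equal(corner$image[11, 11], img[1, 1])
  expect_error(extract_roi(img, c(-5, 10)), "inside")
})

test_that("ROI coordinates round-trip to full-image coordinates", {
  img <- random_raster(80, 80, seed = 1)
  roi <- extract_roi(img, c(10, 70), side = 31)  # forces padding on two sides
  set.seed(2)
  pts <- cbind(sample(0:30, 100, TRUE), sample(0:30, 100, TRUE))
  full <- roi_to_full(roi, pts)
  inb <- full[, 1] >= 0 & full[, 1] <= 79 & full[, 2] >= 0 & full[, 2] <= 79
  expect_equal(roi$image[pts[inb, , drop = FALSE] + 1],
               img[full[inb, , drop = FALSE] + 1])
})

test_that("localization lands near the truth on default fixtures", {
  errs <- c(); rads <- c(); truth <- c()
  for (seed in c(2, 14)) {
    s <- generate_fundus(random_fundus_spec(seed, ppa_enabled = FALSE))
    est <- locate_disc(s$rgb)
    errs <- c(errs, sqrt(sum((est$center - s$spec$disc_center)^2)))
    rads <- c(rads, est$radius)
    truth <- c(truth, mean(s$spec$disc_semi_axes))
  }
  expect_true(all(errs <= 25))
  expect_true(all(abs(rads - truth) <= 15))
})
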