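## Rotation-invariant texture machinery. Two banks are used: the Schmid bank
## of isotropic "Gabor-like" kernels (a radial cosine under a Gaussian
## envelope, zero-mean by construction), and the Root Filter Set (RFS) of 38
## kernels whose oriented families are collapsed to the 8 rotation-invariant
## MR8 responses by taking the per-pixel maximum over orientations.

#' A single Schmid kernel
#'
#' `F(x, y) = F0 + cos(sqrt(x^2 + y^2) * pi * tau / sigma) *
#' exp(-(x^2 + y^2) / (2 sigma^2))` on a square support of side
#' `2 * ceil(3 sigma) + 1`, with the constant `F0` chosen so the kernel sums
#' to zero, then L1-normalized. `tau` counts the cycles of the radial
#' harmonic inside the Gaussian envelope; `sigma` is the scale in pixels.
#'
#' @param sigma scale in pixels (> 0).
#' @param tau cycle count (>= 1).
#' @return an object of class `schmid_kernel`: list with `kernel`, `sigma`,
#'   `tau` and the offset `f0` (before L1 normalization).
#' @export
schmid_kernel <- function(sigma, tau) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (tau < 1) stop("tau must be >= 1", call. = FALSE)
  h <- ceiling(3 * sigma)
  r <- sqrt(outer((-h):h, (-h):h, function(a, b) a^2 + b^2))
  k <- cos(r * pi * tau / sigma) * exp(-r^2 / (2 * sigma^2))
  f0 <- -mean(k)
  k <- k + f0
  l1 <- sum(abs(k))
  structure(list(kernel = k / l1, sigma = sigma, tau = tau, f0 = f0,
                 l1 = l1), class = "schmid_kernel")
}

#' The 12-kernel Schmid bank
#'
#' (sigma, tau) pairs (2,1), (4,1), (4,2), (6,1), (6,2), (6,3), (8,1),
#' (8,2), (8,3), (10,1), (10,2), (10,3), in that order.
#'
#' @return list of 12 [schmid_kernel()] objects.
#' @export
schmid_bank <- function() {
  pairs <- list(c(2, 1), c(4, 1), c(4, 2), c(6, 1), c(6, 2), c(6, 3),
                c(8, 1), c(8, 2), c(8, 3), c(10, 1), c(10, 2), c(10, 3))
  lapply(pairs, function(p) schmid_kernel(p[1], p[2]))
}

#' Schmid filter-bank responses
#'
#' Convolves the image with every kernel of the bank (reflect boundary).
#'
#' @param gray numeric matrix.
#' @param bank output of [schmid_bank()] (or a subset).
#' @return list of response matrices, same size as `gray`.
#' @export
schmid_responses <- function(gray, bank = schmid_bank()) {
  assert_gray(gray)
  conv2_same_bank(gray, lapply(bank, `[[`, "kernel"))
}

## anisotropic Gaussian-derivative kernel on a square support, rotated by
## `theta`; order 1 = edge (first derivative), 2 = bar (second derivative)
gaussian_derivative_kernel <- function(sigma_x, sigma_y, theta, order,
                                       support = 49) {
  h <- (support - 1) / 2
  x <- matrix(rep(-h:h, each = support), support, support)   # cols
  y <- matrix(rep(-h:h, times = support), support, support)  # rows
  ct <- cos(theta); st <- sin(theta)
  xr <- ct * x + st * y
  yr <- -st * x + ct * y
  g <- exp(-xr^2 / (2 * sigma_x^2) - yr^2 / (2 * sigma_y^2))
  k <- switch(order + 1L,
              g,
              (-yr / sigma_y^2) * g,
              (yr^2 / sigma_y^4 - 1 / sigma_y^2) * g)
  if (order > 0L) k <- k - mean(k)
  k / sum(abs(k))
}

laplacian_of_gaussian_kernel <- function(sigma, support = 49) {
  h <- (support - 1) / 2
  r2 <- outer((-h):h, (-h):h, function(a, b) a^2 + b^2)
  k <- (r2 / sigma^4 - 2 / sigma^2) * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)
  k / sum(abs(k))
}

#' The Root Filter Set (RFS) of 38 kernels
#'
#' First (edge) and second (bar) derivatives of anisotropic Gaussians at 6
#' orientations (0, 30, ..., 150 degrees) and 3 scales
#' ((sigma_x, sigma_y) = (3,1), (6,2), (12,4)), 36 kernels, plus an
#' isotropic Gaussian and a Laplacian of Gaussian at sigma = 10. Support is
#' 49 x 49; all kernels except the Gaussian are zero-mean; all are
#' L1-normalized. Scales and support are recorded in the metadata.
#'
#' @return an object of class `rfs_bank`: list with `kernels` (38 matrices)
#'   and `meta` (data.frame with family, scale index, sigma_x, sigma_y,
#'   orientation in radians).
#' @export
rfs_bank <- function() {
  scales <- list(c(3, 1), c(6, 2), c(12, 4))
  thetas <- seq(0, 5) * pi / 6
  kernels <- list(); meta <- list()
  for (family in c("edge", "bar")) {
    ord <- if (family == "edge") 1L else 2L
    for (s in seq_along(scales)) {
      for (th in thetas) {
        kernels[[length(kernels) + 1L]] <-
          gaussian_derivative_kernel(scales[[s]][1], scales[[s]][2], th, ord)
        meta[[length(meta) + 1L]] <-
          data.frame(family = family, scale = s, sigma_x = scales[[s]][1],
                     sigma_y = scales[[s]][2], orientation = th)
      }
    }
  }
  kernels[[37]] <- {
    g <- gaussian_derivative_kernel(10, 10, 0, 0L)
    g
  }
  meta[[37]] <- data.frame(family = "gaussian", scale = NA, sigma_x = 10,
                           sigma_y = 10, orientation = NA)
  kernels[[38]] <- laplacian_of_gaussian_kernel(10)
  meta[[38]] <- data.frame(family = "log", scale = NA, sigma_x = 10,
                           sigma_y = 10, orientation = NA)
  structure(list(kernels = kernels, meta = do.call(rbind, meta)),
            class = "rfs_bank")
}

#' MR8 responses of an image
#'
#' Convolves the image with the 38 RFS kernels and collapses each oriented
#' family x scale to one rotation-invariant response. Ordering:
#' \[edge scale 1..3, bar scale 1..3, gaussian, log\]. With
#' `rectify = FALSE` (the default) the collapse is the signed pointwise
#' maximum over the 6 orientations; with `rectify = TRUE` it is the maximum
#' of the absolute responses, which is polarity-invariant and is what the
#' segmentation pipeline uses for closed bright-region boundaries (the 6
#' orientations span only 180 degrees, so the signed maximum of an odd
#' filter vanishes along part of a closed boundary).
#'
#' @param gray numeric matrix.
#' @param bank an [rfs_bank()].
#' @param rectify take the maximum of absolute oriented responses.
#' @return an object of class `mr8_responses`: list with `responses` (8
#'   matrices) and `names`.
#' @export
mr8_responses <- function(gray, bank = rfs_bank(), rectify = FALSE) {
  assert_gray(gray)
  nm <- c(paste0("edge_s", 1:3), paste0("bar_s", 1:3), "gaussian", "log")
  raw <- conv2_same_bank(gray, bank$kernels)
  resp <- vector("list", 8L)
  idx <- 0L
  for (family in c("edge", "bar")) {
    for (s in 1:3) {
      idx <- idx + 1L
      sel <- which(bank$meta$family == family & bank$meta$scale == s)
      rs <- raw[sel]
      if (rectify) rs <- lapply(rs, abs)
      resp[[idx]] <- Reduce(pmax, rs)
    }
  }
  resp[[7]] <- raw[[which(bank$meta$family == "gaussian")]]
  resp[[8]] <- raw[[which(bank$meta$family == "log")]]
  structure(list(responses = resp, names = nm, rectified = rectify),
            class = "mr8_responses")
}

#' A single MR8 response by index
#'
#' Computes only the convolutions needed for response `index` under the
#' ordering \[edge s1..s3, bar s1..s3, gaussian, log\]. Index 3 (edge at the
#' largest scale) is the snake potential of the segmentation pipeline;
#' indices 5 (bar, middle scale) and 7 (gaussian) are clustering features.
#'
#' @inheritParams mr8_responses
#' @param index response index in 1..8.
#' @return numeric matrix.
#' @export
mr8_response_at <- function(gray, index, bank = rfs_bank(), rectify = FALSE) {
  assert_gray(gray)
  stopifnot(index >= 1, index <= 8)
  if (index <= 6) {
    family <- if (index <= 3) "edge" else "bar"
    s <- if (index <= 3) index else index - 3L
    sel <- which(bank$meta$family == family & bank$meta$scale == s)
    rs <- conv2_same_bank(gray, bank$kernels[sel])
    if (rectify) rs <- lapply(rs, abs)
    Reduce(pmax, rs)
  } else if (index == 7) {
    conv2_same(gray, bank$kernels[[which(bank$meta$family == "gaussian")]])
  } else {
    conv2_same(gray, bank$kernels[[which(bank$meta$family == "log")]])
  }
}

#' Contrast-limited adaptive histogram equalization of a texture response
#'
#' The response is min-max normalized to \[0, 1\] and enhanced with CLAHE
#' (clipped per-tile histograms, bilinear interpolation between tile
#' mappings). A constant input is returned unchanged.
#'
#' @param texture numeric matrix.
#' @param clip_limit clip limit as a fraction of the pixels per tile
#'   (default 0.01).
#' @param tiles (rows, cols) tile grid (default c(8, 8)).
#' @param bins histogram bins per tile.
#' @return numeric matrix in \[0, 1\].
#' @export
clahe_enhance <- function(texture, clip_limit = 0.01, tiles = c(8, 8),
                          bins = 256) {
  assert_gray(texture, "texture")
  rng <- range(texture)
  if (diff(rng) < 1e-12) return(texture)
  x <- (texture - rng[1]) / diff(rng)
  ## EBImage requires the image side to be a multiple of the tile count:
  ## pad by edge replication, enhance, crop back
  nr <- nrow(x); nc <- ncol(x)
  nr2 <- ceiling(nr / tiles[1]) * tiles[1]
  nc2 <- ceiling(nc / tiles[2]) * tiles[2]
  xp <- x[pmin(seq_len(nr2), nr), pmin(seq_len(nc2), nc), drop = FALSE]
  out <- EBImage::clahe(xp, nx = tiles[2], ny = tiles[1], bins = bins,
                        limit = max(clip_limit * bins, 1))
  clamp01(as.matrix(out)[seq_len(nr), seq_len(nc), drop = FALSE])
}
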