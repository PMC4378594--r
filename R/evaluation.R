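## Evaluation: dice overlap against ground truth, plus the two baseline
## segmenters used for comparison -- the classical gradient-force snake
## started near the estimated disc boundary, and fuzzy c-means texture
## clustering followed by an ellipse fit.

#' Dice coefficient between two binary masks
#'
#' `DC = 2 |A intersect B| / (|A| + |B|)`. Two empty masks score 1 (vacuous
#' agreement); exactly one empty mask scores 0.
#'
#' @param mask_a,mask_b logical matrices of the same shape.
#' @return an object of class `segmentation_score`: list with `dice`,
#'   `area_truth`, `area_pred`, `area_intersection`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must have the same shape", call. = FALSE)
  a <- sum(mask_a); b <- sum(mask_b); i <- sum(mask_a & mask_b)
  d <- if (a + b == 0) 1 else 2 * i / (a + b)
  structure(list(dice = d, area_truth = a, area_pred = b,
                 area_intersection = i), class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("<segmentation_score> dice %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
              x$dice, x$area_truth, x$area_pred, x$area_intersection))
  invisible(x)
}

#' Baseline: gradient-force snake
#'
#' The same balloon-snake engine, but driven by the classical potential
#' `P = -|grad(smoothed intensity)|` (normalized) with no texture machinery
#' or noise suppression, and initialized at the full estimated radius, as
#' gradient snakes need to start near the true boundary.
#'
#' @param roi numeric matrix (vessel-removed intensity ROI).
#' @param estimate a [disc_estimate()] in ROI coordinates.
#' @param cfg a [snake_config()].
#' @param sigma Gaussian smoothing before the gradient (px).
#' @return logical disc mask over the ROI.
#' @export
gradient_snake_segment <- function(roi, estimate, cfg = snake_config(),
                                   sigma = 5) {
  assert_gray(roi, "roi")
  sm <- EBImage::gblur(roi, sigma = sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- (rbind(sm[2:nr, ], sm[nr, ]) - rbind(sm[1, ], sm[1:(nr - 1), ])) / 2
  gc <- (cbind(sm[, 2:nc], sm[, nc]) - cbind(sm[, 1], sm[, 1:(nc - 1)])) / 2
  gm <- sqrt(gr^2 + gc^2)
  pot <- texture_potential(gm, provenance = "gradient magnitude")
  snake <- evolve(init_circle(estimate, cfg$n_points, radius_factor = 1),
                  pot, cfg)
  contour_to_mask(snake$contour, dim(roi))
}

## direct least-squares ellipse fit (Fitzgibbon); returns geometric
## parameters: center (row, col), semi-axes (major, minor), angle of the
## major axis measured from the col axis towards the row axis
fit_ellipse_lsq <- function(pts) {
  if (nrow(pts) < 5) stop("degenerate boundary: need >= 5 points", call. = FALSE)
  x <- pts[, 2] - mean(pts[, 2]); y <- pts[, 1] - mean(pts[, 1])
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- -solve(S3, t(S2))
  Mm <- S1 + S2 %*% T
  Mm <- rbind(Mm[3, ] / 2, -Mm[2, ], Mm[1, ] / 2)
  ev <- eigen(Mm)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  a1 <- Re(ev$vectors[, which(cond > 0)[1]])
  coef <- c(a1, T %*% a1)  # A x^2 + B xy + C y^2 + D x + E y + F = 0
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)  # quadratic form in (x, y)
  eq <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(pmax(-F0 / eq$values, 0))
  major <- which.max(ax)
  vec <- eq$vectors[, major]  # (x, y) direction of the major axis
  list(center = c(cy + mean(pts[, 1]), cx + mean(pts[, 2])),
       semi_axes = c(ax[major], ax[-major][1]),
       angle = atan2(vec[2], vec[1]))
}

ellipse_mask <- function(fit, shape) {
  rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  dr <- rr - fit$center[1]; dc <- cc - fit$center[2]
  ct <- cos(fit$angle); st <- sin(fit$angle)
  u <- ct * dc + st * dr   # along major axis
  v <- -st * dc + ct * dr
  (u / fit$semi_axes[1])^2 + (v / fit$semi_axes[2])^2 <= 1
}

#' Baseline: texture clustering with ellipse fit
#'
#' Two texture features of the red channel (5th MR response and 1st Schmid
#' response) are clustered into two groups by fuzzy c-means inside the
#' enlarged analysis region. The larger cluster is declared background and
#' cleaned by morphological opening; the largest connected component of its
#' complement is the boundary (edge) ring, and a direct least-squares
#' ellipse fitted to that ring's pixels is the segmentation.
#'
#' @param red_roi numeric matrix (red channel, vessel-removed ROI).
#' @param estimate a [disc_estimate()] in ROI coordinates.
#' @param fcm_cfg an [fcm_config()].
#' @param open_se_radius opening structuring-element radius (px).
#' @param bank an [rfs_bank()] (reused for speed).
#' @return logical disc mask over the ROI.
#' @export
fcm_texture_segment <- function(red_roi, estimate,
                                fcm_cfg = fcm_config(),
                                open_se_radius = 5,
                                bank = rfs_bank()) {
  assert_gray(red_roi, "red_roi")
  region <- enlarged_analysis_region(estimate, margin = 50,
                                     roi_dim = dim(red_roi))
  f1 <- mr8_response_at(red_roi, 5, bank = bank, rectify = TRUE)
  f2 <- schmid_responses(red_roi, schmid_bank()[1])[[1]]
  zs <- function(f) {
    v <- f[region$mask]; s <- sd(v)
    if (!is.finite(s) || s < 1e-12) return(f * 0)
    (f - mean(v)) / s
  }
  feats <- cbind(as.vector(zs(f1))[region$mask], as.vector(zs(f2))[region$mask])
  res <- fcm(feats, fcm_cfg)
  lab <- matrix(FALSE, nrow(red_roi), ncol(red_roi))
  lab[region$mask] <- res$labels == 1

  ring <- edge_region_mask(lab, region, open_se_radius)$edge_mask
  fit <- fit_ellipse_lsq(which(ring, arr.ind = TRUE) - 1)
  ellipse_mask(fit, dim(red_roi))
}

#' Run the synthetic three-method benchmark
#'
#' For every seed: generate a fixture, run the full texture balloon-snake
#' pipeline, then run the two baselines (gradient snake started at the full
#' estimated radius; texture clustering + ellipse fit) on the same
#' vessel-removed ROI and disc estimate, and score all three against the
#' ground-truth disc mask.
#'
#' @param seeds integer vector of fixture seeds.
#' @param ppa_enabled render PPA crescents (the hard case).
#' @param config an [odseg_config()].
#' @return data.frame with one row per seed: dice of the three methods,
#'   localization centre error (px), radius error (px), the number of
#'   predicted-mask pixels falling inside the PPA crescent for the proposed
#'   method, and `ppa_incursion` -- the median depth (px) beyond the true
#'   disc boundary of the predicted-mask pixels inside the crescent.
#' @export
run_benchmark <- function(seeds, ppa_enabled = TRUE, config = odseg_config()) {
  rows <- lapply(seeds, function(seed) {
    s <- generate_fundus(random_fundus_spec(seed, ppa_enabled = ppa_enabled))
    res <- suppressWarnings(segment_image(s$rgb, s$vessel_mask, config))
    truth_roi <- extract_roi(s$disc_mask * 1, res$estimate$center,
                             config$roi_side)$image > 0.5
    gray_roi <- hsi_intensity(res$devesseled)
    snake_mask <- gradient_snake_segment(gray_roi, res$roi_estimate,
                                         config$snake)
    cluster_mask <- fcm_texture_segment(res$devesseled[, , 1],
                                        res$roi_estimate,
                                        fcm_cfg = config$fcm)
    overlap <- res$disc_mask & s$ppa_mask
    incursion <- 0
    if (any(overlap)) {
      # median depth of the contour beyond the true disc boundary, over the
      # pixels it claims inside the PPA
      depth <- EBImage::distmap((!s$disc_mask) * 1)
      incursion <- stats::median(depth[overlap])
    }
    data.frame(seed = seed,
               dice_proposed = dice(truth_roi, res$disc_mask_roi)$dice,
               dice_snake = dice(truth_roi, snake_mask)$dice,
               dice_cluster = dice(truth_roi, cluster_mask)$dice,
               center_error = sqrt(sum((res$estimate$center -
                                          s$spec$disc_center)^2)),
               radius_error = res$estimate$radius -
                 mean(s$spec$disc_semi_axes),
               ppa_pixels = sum(overlap),
               ppa_incursion = incursion)
  })
  do.call(rbind, rows)
}

#' Score segmentations over a batch of samples
#'
#' @param samples list of lists with elements `truth` (logical mask) and one
#'   logical mask per method name.
#' @param methods character vector of method names to score.
#' @return data.frame with one row per method and columns `method`, `mu`
#'   (mean dice), `delta` (std of dice) and `n`; the per-sample scores in
#'   long format (`method`, `sample`, `dice`) are attached as attribute
#'   `"scores"`.
#' @export
evaluate_batch <- function(samples, methods) {
  stopifnot(length(samples) >= 1)
  long <- do.call(rbind, lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    data.frame(method = methods,
               sample = i,
               dice = vapply(methods,
                             function(m) dice(s$truth, s[[m]])$dice,
                             numeric(1)))
  }))
  summ <- do.call(rbind, lapply(methods, function(m) {
    d <- long$dice[long$method == m]
    data.frame(method = m, mu = mean(d),
               delta = if (length(d) > 1) sd(d) else 0,
               n = length(d))
  }))
  rownames(summ) <- NULL
  attr(summ, "scores") <- long
  summ
}
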