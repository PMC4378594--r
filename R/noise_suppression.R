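## Texture-noise suppression. The CLAHE-enhanced texture still contains
## ridges that are not the disc rim: the cup boundary and residual vessel
## edges. Pixels of a disc-centred analysis region are clustered (fuzzy
## c-means on three texture features) into an edge-like and a background
## cluster; the background is cleaned by binary opening, its complement's
## largest connected component is kept as the edge region, and the texture is
## harmonically inpainted over the background so the snake glides across it.

#' Circular analysis region around a disc estimate
#'
#' Disc-centred circle of radius `estimate$radius + margin`; only its pixels
#' take part in clustering. If the circle exceeds the ROI it is clipped with
#' a warning.
#'
#' @param estimate a [disc_estimate()] in ROI coordinates.
#' @param margin radius enlargement in pixels (default 50).
#' @param roi_dim (rows, cols) of the ROI the region lives in.
#' @return an object of class `analysis_region`: list with `center`,
#'   `radius` and `mask` (logical matrix).
#' @export
enlarged_analysis_region <- function(estimate, margin = 50,
                                     roi_dim = c(900, 900)) {
  stopifnot(inherits(estimate, "disc_estimate"))
  radius <- estimate$radius + margin
  ctr <- estimate$center
  if (ctr[1] - radius < 0 || ctr[2] - radius < 0 ||
      ctr[1] + radius > roi_dim[1] - 1 || ctr[2] + radius > roi_dim[2] - 1)
    warning("analysis region exceeds the ROI; clipped to the ROI bounds")
  rr <- matrix(seq_len(roi_dim[1]) - 1, roi_dim[1], roi_dim[2])
  cc <- matrix(seq_len(roi_dim[2]) - 1, roi_dim[1], roi_dim[2], byrow = TRUE)
  mask <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
  structure(list(center = ctr, radius = radius, mask = mask),
            class = "analysis_region")
}

#' Three-feature texture stack for clustering
#'
#' From the red channel of the vessel-removed ROI: the 1st Schmid response
#' (sigma = 2, tau = 1) and two MR responses, by default the bar family at
#' the middle scale (index 5) and the Laplacian of Gaussian (index 8). The
#' second isotropic response is preferred over the Gaussian (index 7)
#' because the Gaussian response is smoothed intensity, which the feature
#' space deliberately avoids: on high-contrast discs it makes the
#' clustering separate disc from background instead of edge from flat.
#' Each feature is z-scored over the analysis region; a degenerate
#' (constant) feature becomes all zeros.
#'
#' @param red_roi numeric matrix (red channel of the ROI).
#' @param region an [enlarged_analysis_region()]; when `NULL`, z-scoring uses
#'   the whole ROI.
#' @param bank an [rfs_bank()] (reused across calls for speed).
#' @param rectify polarity-invariant oriented maxima (pipeline default).
#' @param mr_indices the two MR response indices used as features 2 and 3.
#' @param responses optional precomputed list of the three raw responses
#'   (Schmid 1 and the two MR responses), e.g. shared with other stages.
#' @return rows x cols x 3 array.
#' @export
build_feature_stack <- function(red_roi, region = NULL, bank = rfs_bank(),
                                rectify = TRUE, mr_indices = c(5L, 8L),
                                responses = NULL) {
  assert_gray(red_roi, "red_roi")
  if (is.null(responses)) {
    responses <- c(schmid_responses(red_roi, schmid_bank()[1]),
                   lapply(mr_indices, function(i)
                     mr8_response_at(red_roi, i, bank = bank,
                                     rectify = rectify)))
  }
  sel <- if (is.null(region)) rep(TRUE, length(red_roi)) else region$mask
  zscore <- function(f) {
    mu <- mean(f[sel]); s <- sd(f[sel])
    if (!is.finite(s) || s < 1e-12) return(f * 0)
    (f - mu) / s
  }
  out <- array(0, dim = c(dim(red_roi), 3))
  out[, , 1] <- zscore(responses[[1]])
  out[, , 2] <- zscore(responses[[2]])
  out[, , 3] <- zscore(responses[[3]])
  out
}

#' Configuration for fuzzy c-means
#'
#' @param n_clusters number of clusters (2 for this pipeline).
#' @param fuzzifier_m fuzzifier exponent (> 1, default 2).
#' @param tolerance stop when the objective decreases by less than this.
#' @param max_iterations iteration cap.
#' @param seed seed for the random initial memberships.
#' @return an object of class `fcm_config`.
#' @export
fcm_config <- function(n_clusters = 2L, fuzzifier_m = 2, tolerance = 1e-5,
                       max_iterations = 100L, seed = 1L) {
  if (fuzzifier_m <= 1) stop("fuzzifier_m must be > 1", call. = FALSE)
  structure(list(n_clusters = as.integer(n_clusters),
                 fuzzifier_m = fuzzifier_m, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)), class = "fcm_config")
}

#' Fuzzy c-means clustering
#'
#' Standard FCM: memberships `u_ik` proportional to
#' `(1 / d_ik^2)^(1 / (m - 1))` normalized per point, centers the
#' `u^m`-weighted means, iterated until the objective
#' `J = sum u^m d^2` changes by less than `tolerance`. Initial memberships
#' are seeded uniform random, so the result is deterministic given the
#' config.
#'
#' @param points n x d numeric matrix of feature vectors.
#' @param cfg an [fcm_config()].
#' @return an object of class `fcm_result`: list with `centers` (k x d),
#'   `memberships` (n x k), `labels` (hard argmax per point), `objective`
#'   (per-iteration trace) and `iterations`.
#' @export
fcm <- function(points, cfg = fcm_config()) {
  stopifnot(inherits(cfg, "fcm_config"))
  points <- as.matrix(points)
  n <- nrow(points); k <- cfg$n_clusters; m <- cfg$fuzzifier_m
  if (nrow(unique(points)) < k)
    stop("need at least n_clusters distinct points", call. = FALSE)
  u <- with_seed(cfg$seed, matrix(runif(n * k), n, k))
  u <- u / rowSums(u)
  obj <- numeric(0)
  for (it in seq_len(cfg$max_iterations)) {
    um <- u^m
    centers <- crossprod(um, points) / colSums(um)
    d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") -
      2 * points %*% t(centers)
    d2 <- pmax(d2, 1e-300)
    obj <- c(obj, sum(um * d2))
    inv <- d2^(-1 / (m - 1))
    u <- inv / rowSums(inv)
    if (it > 1 && abs(obj[it] - obj[it - 1]) < cfg$tolerance) break
  }
  um <- u^m
  centers <- crossprod(um, points) / colSums(um)
  structure(list(centers = centers, memberships = u,
                 labels = max.col(u, ties.method = "first"),
                 objective = obj, iterations = length(obj)),
            class = "fcm_result")
}

#' Edge-region selection from binary cluster labels
#'
#' Implements the knowledge-based cluster selection: the larger-area cluster
#' is declared background, the background is cleaned by binary opening with a
#' disc structuring element (absorbing cup-boundary and vessel-edge holes),
#' the complement within the analysis region is taken, and its largest
#' 8-connected component becomes the edge region. Everything else in the
#' analysis region is background.
#'
#' @param labels logical matrix over the ROI: `TRUE` for cluster A, `FALSE`
#'   for cluster B (only pixels inside the region matter).
#' @param region an [enlarged_analysis_region()].
#' @param open_se_radius radius (px) of the opening structuring element.
#' @return an object of class `edge_region_mask`: list with `edge_mask`,
#'   `background_mask` (logical matrices) and `analysis_radius`.
#' @export
edge_region_mask <- function(labels, region, open_se_radius = 5) {
  stopifnot(inherits(region, "analysis_region"))
  sel <- region$mask
  a_size <- sum(labels & sel)
  b_size <- sum(!labels & sel)
  background <- if (a_size >= b_size) (labels & sel) else (!labels & sel)
  ## pixels outside the analysis circle count as background during the
  ## opening, so the element is not starved at the region rim (which would
  ## leave a spurious ring in the complement)
  opened <- EBImage::opening((background | !sel) * 1,
                             EBImage::makeBrush(2L * open_se_radius + 1L,
                                                "disc")) > 0
  candidate <- sel & !opened
  edge <- largest_component(candidate)
  if (!any(edge))
    stop("noise suppression failed: empty edge region after opening",
         call. = FALSE)
  structure(list(edge_mask = edge,
                 background_mask = sel & !edge,
                 analysis_radius = region$radius),
            class = "edge_region_mask")
}

#' Suppress texture noise by inpainting the background region
#'
#' Replaces the texture values over the background mask with harmonic
#' inpainting whose Dirichlet data are the edge region and the region
#' boundary, so the snake sees a smooth potential everywhere except at the
#' retained edge ridge. Edge-mask pixels are returned bit-exactly unchanged.
#'
#' @param texture numeric matrix (the CLAHE-enhanced snake potential
#'   channel).
#' @param edge_region an [edge_region_mask()].
#' @param cfg an [inpaint_config()]; the mask is not dilated here.
#' @return numeric matrix.
#' @export
suppress_noise <- function(texture, edge_region,
                           cfg = inpaint_config(mask_dilation = 0)) {
  stopifnot(inherits(edge_region, "edge_region_mask"))
  if (!any(edge_region$background_mask)) return(texture)
  cfg$mask_dilation <- 0L
  inpaint_diffusion(texture, edge_region$background_mask, cfg)
}
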