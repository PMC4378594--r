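## End-to-end pipeline: localization -> ROI -> vessel inpainting -> texture
## (rectified MR8 edge response at the largest scale) -> CLAHE -> FCM noise
## suppression -> texture potential -> balloon snake -> disc mask in
## full-image coordinates. Every stage artifact is retained on the result.

## RFS kernel indices backing one MR8 response index
mr8_kernel_indices <- function(index, meta) {
  if (index <= 6) {
    family <- if (index <= 3) "edge" else "bar"
    s <- if (index <= 3) index else index - 3L
    which(meta$family == family & meta$scale == s)
  } else if (index == 7) which(meta$family == "gaussian")
  else which(meta$family == "log")
}

#' Full pipeline configuration
#'
#' Collects every tunable of the pipeline in one nested list. Individual
#' entries can be overridden through `...` using their list names, e.g.
#' `odseg_config(snake = snake_config(rho = 0.2))`.
#'
#' @param template a [template_spec()].
#' @param radii Hough radius list (px).
#' @param roi_side ROI side (px).
#' @param canny_threshold high hysteresis threshold for the edge map.
#' @param inpaint an [inpaint_config()] for vessel removal.
#' @param potential_index MR8 response driving the snake (default 3: edge at
#'   the largest scale).
#' @param feature_mr_indices MR response indices of clustering features 2
#'   and 3 (default bar middle scale and Laplacian of Gaussian; see
#'   [build_feature_stack()]).
#' @param rectify_mr8 polarity-invariant oriented maxima for pipeline
#'   responses.
#' @param clahe_clip,clahe_tiles CLAHE parameters.
#' @param analysis_margin radius enlargement (px) of the clustering region.
#' @param fcm an [fcm_config()].
#' @param open_se_radius opening radius (px) in the cluster cleanup.
#' @param suppress_inpaint an [inpaint_config()] for noise inpainting.
#' @param snake a [snake_config()].
#' @param init_radius_factor initial contour radius as a fraction of the
#'   estimated radius.
#' @return an object of class `odseg_config`.
#' @export
odseg_config <- function(template = template_spec(),
                         radii = seq(140, 230, by = 15),
                         roi_side = 900,
                         canny_threshold = 0.4,
                         inpaint = inpaint_config(),
                         potential_index = 3L,
                         feature_mr_indices = c(5L, 8L),
                         rectify_mr8 = TRUE,
                         clahe_clip = 0.01,
                         clahe_tiles = c(8, 8),
                         analysis_margin = 50,
                         fcm = fcm_config(),
                         open_se_radius = 5,
                         suppress_inpaint = inpaint_config(mask_dilation = 0,
                                                           omega = 1.9),
                         snake = snake_config(),
                         init_radius_factor = 0.5) {
  structure(list(template = template, radii = radii, roi_side = roi_side,
                 canny_threshold = canny_threshold, inpaint = inpaint,
                 potential_index = as.integer(potential_index),
                 feature_mr_indices = as.integer(feature_mr_indices),
                 rectify_mr8 = rectify_mr8,
                 clahe_clip = clahe_clip, clahe_tiles = clahe_tiles,
                 analysis_margin = analysis_margin, fcm = fcm,
                 open_se_radius = open_se_radius,
                 suppress_inpaint = suppress_inpaint,
                 snake = snake,
                 init_radius_factor = init_radius_factor),
            class = "odseg_config")
}

#' Segment the optic disc in a fundus image
#'
#' Runs the full method: template + Hough localization, 900 x 900 ROI
#' extraction, diffusion inpainting of the vessels (skipped with a warning
#' when no vessel mask is given), rectified MR8 edge texture, CLAHE
#' enhancement, fuzzy-c-means noise suppression (skipped with a warning if
#' the edge region degenerates), and the texture-driven balloon snake grown
#' from half the estimated radius.
#'
#' @param rgb rows x cols x 3 array in \[0, 1\] (at least 1000 x 1000 px).
#' @param vessel_mask optional logical matrix marking vessel pixels.
#' @param config an [odseg_config()].
#' @return an object of class `odseg_result`: list with `estimate`
#'   (full-image coordinates), `roi` (the [extract_roi()] window),
#'   `roi_estimate`, stage artifacts (`devesseled`, `texture`, `enhanced`,
#'   `edge_region`, `clean_texture`), `contour` (ROI coordinates),
#'   `disc_mask_roi`, `disc_mask` (full-image frame), `trace`, `flags` and
#'   `config`.
#' @export
segment_image <- function(rgb, vessel_mask = NULL, config = odseg_config()) {
  assert_rgb(rgb)
  if (nrow(rgb) < 1000 || ncol(rgb) < 1000)
    stop("image must be at least 1000 x 1000 px to host the analysis window",
         call. = FALSE)
  flags <- list(vessel_removal = "inpaint", noise_suppression = "fcm")
  bank <- rfs_bank()

  ## (a) localization
  estimate <- locate_disc(rgb, template_spec = config$template,
                          radii = config$radii, roi_side = config$roi_side,
                          canny_threshold = config$canny_threshold)
  roi <- extract_roi(rgb, estimate$center, side = config$roi_side)
  roi_center <- estimate$center - (roi$offset - roi$pad)
  roi_estimate <- disc_estimate(roi_center, estimate$radius, estimate$score)

  ## (b) vessel removal
  if (is.null(vessel_mask)) {
    warning("no vessel mask supplied; vessel removal skipped")
    flags$vessel_removal <- "skipped"
    devesseled <- roi$image
  } else {
    mask_roi <- extract_roi(vessel_mask * 1, estimate$center,
                            side = config$roi_side)$image > 0.5
    devesseled <- inpaint_diffusion(roi$image, mask_roi, config$inpaint)
  }
  red <- devesseled[, , 1]

  ## (c) texture, enhancement, noise suppression; all filter-bank
  ## convolutions share one padded image FFT
  meta <- bank$meta
  pot_sel <- mr8_kernel_indices(config$potential_index, meta)
  f2_sel <- mr8_kernel_indices(config$feature_mr_indices[1], meta)
  f3_sel <- mr8_kernel_indices(config$feature_mr_indices[2], meta)
  kerns <- c(bank$kernels[pot_sel], bank$kernels[f2_sel],
             bank$kernels[f3_sel], list(schmid_bank()[[1]]$kernel))
  raw <- conv2_same_bank(red, kerns)
  np <- length(pot_sel); n2 <- length(f2_sel); n3 <- length(f3_sel)
  collapse <- function(rs, oriented = TRUE) {
    if (config$rectify_mr8 && oriented) rs <- lapply(rs, abs)
    Reduce(pmax, rs)
  }
  texture <- collapse(raw[seq_len(np)], config$potential_index <= 6)
  enhanced <- clahe_enhance(texture, clip_limit = config$clahe_clip,
                            tiles = config$clahe_tiles)
  region <- enlarged_analysis_region(roi_estimate,
                                     margin = config$analysis_margin,
                                     roi_dim = dim(red))
  feats <- build_feature_stack(
    red, region, bank = bank, rectify = config$rectify_mr8,
    responses = list(
      raw[[np + n2 + n3 + 1L]],
      collapse(raw[np + seq_len(n2)], config$feature_mr_indices[1] <= 6),
      collapse(raw[np + n2 + seq_len(n3)], config$feature_mr_indices[2] <= 6)))
  fmat <- cbind(as.vector(feats[, , 1])[region$mask],
                as.vector(feats[, , 2])[region$mask],
                as.vector(feats[, , 3])[region$mask])
  edge_region <- NULL
  clean <- enhanced
  suppression <- try({
    cl <- fcm(fmat, config$fcm)
    lab <- matrix(FALSE, nrow(red), ncol(red))
    lab[region$mask] <- cl$labels == 1
    edge_region <- edge_region_mask(lab, region, config$open_se_radius)
    clean <- suppress_noise(enhanced, edge_region, config$suppress_inpaint)
  }, silent = TRUE)
  if (inherits(suppression, "try-error")) {
    warning("noise suppression failed; using the unsuppressed texture: ",
            attr(suppression, "condition")$message)
    flags$noise_suppression <- "skipped"
  }

  ## (d) balloon snake
  pot <- texture_potential(clean, provenance = sprintf(
    "mr8[%d] rectified=%s + clahe + fcm suppression", config$potential_index,
    config$rectify_mr8))
  snake <- evolve(init_circle(roi_estimate, config$snake$n_points,
                              radius_factor = config$init_radius_factor),
                  pot, config$snake)
  disc_roi <- contour_to_mask(snake$contour, dim(red))

  ## map the mask back to the full-image frame
  full <- matrix(FALSE, nrow(rgb), ncol(rgb))
  src <- which(disc_roi, arr.ind = TRUE) - 1
  pts <- roi_to_full(roi, src)
  keep <- pts[, 1] >= 0 & pts[, 1] < nrow(rgb) &
    pts[, 2] >= 0 & pts[, 2] < ncol(rgb)
  full[pts[keep, , drop = FALSE] + 1] <- TRUE

  structure(list(estimate = estimate, roi = roi, roi_estimate = roi_estimate,
                 devesseled = devesseled, texture = texture,
                 enhanced = enhanced, edge_region = edge_region,
                 clean_texture = clean, contour = snake$contour,
                 disc_mask_roi = disc_roi, disc_mask = full,
                 trace = snake$trace, converged = snake$converged,
                 flags = flags, config = config),
            class = "odseg_result")
}

#' @export
print.odseg_result <- function(x, ...) {
  cat(sprintf("<odseg_result> disc at (%.1f, %.1f), radius %.0f px\n",
              x$estimate$center[1], x$estimate$center[2], x$estimate$radius))
  cat(sprintf("  mask area: %d px; snake iterations: %d (%s)\n",
              sum(x$disc_mask), nrow(x$trace),
              if (x$converged) "converged" else "max iterations"))
  cat(sprintf("  vessel removal: %s; noise suppression: %s\n",
              x$flags$vessel_removal, x$flags$noise_suppression))
  invisible(x)
}
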