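## Optic-disc localization: the disc is the brightest, roughly circular
## structure of a healthy fundus, so a bright-core template is slid over the
## HSI intensity channel (Pearson correlation), and a circle Hough transform
## on the Canny edge map then refines the centre and yields a radius estimate.

#' HSI intensity channel of an RGB raster
#'
#' @param rgb rows x cols x 3 array with values in \[0, 1\].
#' @return numeric matrix `(R + G + B) / 3`.
#' @export
hsi_intensity <- function(rgb) {
  assert_rgb(rgb, "rgb")
  (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
}

#' Specification of the disc-matching template
#'
#' A radially symmetric template with a bright circular plateau and a smooth
#' error-function falloff. The default side of 401 px suits discs 260--380 px
#' wide; the core diameter sits at the midpoint of that range. Pearson
#' correlation removes mean and scale, so only the shape matters.
#'
#' @param side odd template side in pixels.
#' @param core_diameter diameter of the bright plateau in pixels.
#' @param edge_softness falloff width in pixels.
#' @return an object of class `template_spec`.
#' @export
template_spec <- function(side = 401, core_diameter = 320, edge_softness = 40) {
  if (side %% 2 == 0) stop("template side must be odd", call. = FALSE)
  if (core_diameter >= side)
    stop("core_diameter must be smaller than the template side", call. = FALSE)
  structure(list(side = as.integer(side), core_diameter = core_diameter,
                 edge_softness = edge_softness), class = "template_spec")
}

#' Build the disc template raster
#'
#' @param spec a [template_spec()].
#' @return `side` x `side` numeric matrix in \[0, 1\].
#' @export
build_disc_template <- function(spec = template_spec()) {
  stopifnot(inherits(spec, "template_spec"))
  h <- (spec$side - 1) / 2
  d <- sqrt(outer((-h):h, (-h):h, function(a, b) a^2 + b^2))
  pnorm((spec$core_diameter / 2 - d) / (spec$edge_softness / 2))
}

#' Pearson-correlation template matching
#'
#' Slides `template` over `gray` and computes, at every valid position, the
#' Pearson correlation coefficient between the template and the window it
#' covers (both mean-subtracted, normalized by both standard deviations).
#' Positions where the window is constant are scored 0 so flat regions never
#' win. Computed exactly via FFT-based running sums.
#'
#' @param gray numeric matrix.
#' @param template numeric matrix, smaller than `gray` and non-constant.
#' @return list with `score_map` (matrix over valid template positions),
#'   `peak` (0-based (row, col) of the template centre at the maximum) and
#'   `score` (the maximum correlation).
#' @export
pearson_match <- function(gray, template) {
  assert_gray(gray); assert_gray(template, "template")
  if (nrow(template) > nrow(gray) || ncol(template) > ncol(gray))
    stop("template must be smaller than the image", call. = FALSE)
  n <- length(template)
  t0 <- template - mean(template)
  sst <- sum(t0^2)
  if (sst < 1e-24) stop("template must not be constant", call. = FALSE)
  ones <- matrix(1, nrow(template), ncol(template))
  s1 <- xcorr_valid(gray, ones)        # window sums
  s2 <- xcorr_valid(gray^2, ones)      # window sums of squares
  num <- xcorr_valid(gray, t0)         # sum f * t0  (== sum (f - fm) t0)
  ssf <- pmax(s2 - s1^2 / n, 0)        # window sum of squared deviations
  denom <- sqrt(ssf * sst)
  ## windows whose variance is at the FFT round-off floor count as constant
  score <- ifelse(ssf <= 1e-9 * pmax(s2, 1e-12), 0, num / denom)
  score <- pmin(pmax(score, -1), 1)
  peak_idx <- arrayInd(which.max(score), dim(score))
  half <- c((nrow(template) - 1) %/% 2, (ncol(template) - 1) %/% 2)
  list(score_map = score,
       peak = c(peak_idx[1] - 1 + half[1], peak_idx[2] - 1 + half[2]),
       score = score[peak_idx])
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction and hysteresis thresholding. The gradient
#' magnitude is normalized to \[0, 1\]; `high_threshold` is the high
#' hysteresis threshold on that scale and the low one is
#' `low_ratio * high_threshold`.
#'
#' @param gray numeric matrix in \[0, 1\].
#' @param high_threshold high hysteresis threshold (default 0.4).
#' @param sigma Gaussian pre-smoothing std in pixels.
#' @param low_ratio low threshold as a fraction of the high one.
#' @return logical edge map.
#' @export
canny_edges <- function(gray, high_threshold = 0.4, sigma = 5, low_ratio = 0.4) {
  assert_gray(gray)
  sm <- EBImage::gblur(gray, sigma = sigma)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/drow
  gy <- conv2_same(sm, sx)        # gradient along rows
  gx <- conv2_same(sm, t(sx))     # gradient along cols
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax < 1e-12) return(matrix(FALSE, nrow(gray), ncol(gray)))
  mag <- mag / mmax

  ## non-maximum suppression: compare with the two neighbours along the
  ## gradient direction quantized to 4 sectors
  ang <- atan2(gy, gx)                      # (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)    # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nr <- nrow(mag); nc <- ncol(mag)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  n1 <- shift(mag, 0, 1) * (sector == 0) + shift(mag, 1, 1) * (sector == 1) +
    shift(mag, 1, 0) * (sector == 2) + shift(mag, 1, -1) * (sector == 3)
  n2 <- shift(mag, 0, -1) * (sector == 0) + shift(mag, -1, -1) * (sector == 1) +
    shift(mag, -1, 0) * (sector == 2) + shift(mag, -1, 1) * (sector == 3)
  is_max <- mag >= n1 & mag >= n2

  strong <- is_max & mag >= high_threshold
  weak <- is_max & mag >= high_threshold * low_ratio
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- label_components(weak)
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, nr, nc)
}

#' Disc estimate (centre + radius hypothesis)
#'
#' @param center 0-based (row, col).
#' @param radius circle radius in pixels.
#' @param score accumulator or correlation value backing the estimate.
#' @return an object of class `disc_estimate`.
#' @export
disc_estimate <- function(center, radius, score = NA_real_) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 score = as.numeric(score)), class = "disc_estimate")
}

#' @export
print.disc_estimate <- function(x, ...) {
  cat(sprintf("<disc_estimate> centre (%.1f, %.1f), radius %.1f, score %.3g\n",
              x$center[1], x$center[2], x$radius, x$score))
  invisible(x)
}

## integer offsets of the midpoint (Bresenham) circle of radius R
midpoint_circle_offsets <- function(radius) {
  x <- 0L; y <- as.integer(radius); d <- 1L - as.integer(radius)
  xs <- integer(0); ys <- integer(0)
  while (x <= y) {
    xs <- c(xs, x); ys <- c(ys, y)
    if (d < 0L) d <- d + 2L * x + 3L
    else { d <- d + 2L * (x - y) + 5L; y <- y - 1L }
    x <- x + 1L
  }
  oct <- cbind(c(xs, ys, ys, xs, -xs, -ys, -ys, -xs),
               c(ys, xs, -xs, -ys, -ys, -xs, xs, ys))
  unique(oct)
}

#' Circle Hough transform over a fixed radius list
#'
#' Every edge pixel votes for all candidate centres at each radius (midpoint
#' circle offsets); each per-radius accumulator is smoothed with a 3x3 box
#' and normalized by the number of circle-template points, so radii compete
#' on the fraction of their circumference that is supported by edges rather
#' than on raw counts. Ties are broken towards the smallest radius, then
#' row-major scan order. The default radii cover disc radii 140--230 px in
#' steps of 15.
#'
#' @param edges logical edge map.
#' @param radii integer vector of candidate radii in pixels.
#' @param search_center optional 0-based (row, col); when given together with
#'   `search_radius`, only accumulator cells within that distance of the
#'   point compete for the maximum (the template-matching stage has already
#'   fixed the approximate centre, so far-away vote pile-ups from vessel
#'   edges are ignored).
#' @param search_radius search window radius in pixels.
#' @return a [disc_estimate()] whose score is the smoothed, per-template-point
#'   normalized vote count.
#' @export
hough_circle <- function(edges, radii = seq(140, 230, by = 15),
                         search_center = NULL, search_radius = Inf) {
  if (length(radii) == 0) stop("radius list must be non-empty", call. = FALSE)
  ep <- which(edges, arr.ind = TRUE)
  if (nrow(ep) == 0)
    stop("optic disc localization failed: empty edge map", call. = FALSE)
  nr <- nrow(edges); nc <- ncol(edges)
  window <- NULL
  if (!is.null(search_center) && is.finite(search_radius)) {
    rr <- matrix(seq_len(nr) - 1, nr, nc)
    cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
    window <- (rr - search_center[1])^2 + (cc - search_center[2])^2 <=
      search_radius^2
  }
  best <- NULL
  for (R in sort(radii)) {
    off <- midpoint_circle_offsets(R)
    acc <- .hough_accumulate(ep[, 1] - 1L, ep[, 2] - 1L, nr, nc,
                             off[, 1], off[, 2])
    ## votes scale with circumference, so they are normalized per template
    ## point; otherwise the largest radius wins on any curvilinear clutter
    sm <- box3_smooth(acc) / nrow(off)
    if (!is.null(window)) sm[!window] <- -1
    mx <- max(sm)
    if (is.null(best) || mx > best$score + 1e-9) {
      hits <- which(sm > mx - 1e-9)
      idx <- arrayInd(hits, dim(sm))
      rowmajor <- (idx[, 1] - 1) * nc + (idx[, 2] - 1)
      pick <- idx[which.min(rowmajor), ]
      best <- list(center = c(pick[1] - 1, pick[2] - 1), radius = R, score = mx)
    }
  }
  disc_estimate(best$center, best$radius, best$score)
}

#' Extract a square region of interest around a point
#'
#' Cuts a `side` x `side` window centred at `center`; where the window
#' exceeds the image, the image is padded by edge replication. The returned
#' `offset` is the 0-based crop origin in the padded image and `pad` the
#' (top, left) padding applied, so `full = roi + offset - pad` maps ROI
#' coordinates back to the original image exactly.
#'
#' @param image matrix or rows x cols x 3 array.
#' @param center 0-based (row, col) of the window centre.
#' @param side window side in pixels (default 900).
#' @return an object of class `roi_window` with elements `image`, `offset`,
#'   `pad`, `side` and `center` (the centre in ROI coordinates).
#' @export
extract_roi <- function(image, center, side = 900) {
  dims <- dim(image)
  nr <- dims[1]; nc <- dims[2]
  if (center[1] < 0 || center[1] > nr - 1 || center[2] < 0 || center[2] > nc - 1)
    stop("center must lie inside the image", call. = FALSE)
  half <- (side - 1) / 2
  r0 <- round(center[1] - half); c0 <- round(center[2] - half)  # 0-based origin
  pad_top <- max(0, -r0); pad_left <- max(0, -c0)
  pad_bottom <- max(0, r0 + side - nr); pad_right <- max(0, c0 + side - nc)
  pr <- max(pad_top, pad_bottom); pc <- max(pad_left, pad_right)
  crop1 <- function(m) {
    if (pr > 0 || pc > 0) m <- pad_image(m, pr, pc, mode = "replicate")
    m[(r0 + pr + 1):(r0 + pr + side), (c0 + pc + 1):(c0 + pc + side),
      drop = FALSE]
  }
  img <- if (length(dims) == 3) {
    out <- array(0, dim = c(side, side, dims[3]))
    for (ch in seq_len(dims[3])) out[, , ch] <- crop1(image[, , ch])
    out
  } else crop1(image)
  structure(list(image = img,
                 offset = c(r0 + pr, c0 + pc),
                 pad = c(pr, pc),
                 side = as.integer(side),
                 center = as.numeric(center) - c(r0, c0)),
            class = "roi_window")
}

#' Map ROI coordinates back to full-image coordinates
#'
#' @param roi a [extract_roi()] result.
#' @param pts n x 2 matrix (or length-2 vector) of 0-based (row, col) ROI
#'   coordinates.
#' @return coordinates in the original (unpadded) image frame.
#' @export
roi_to_full <- function(roi, pts) {
  stopifnot(inherits(roi, "roi_window"))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  sweep(pts, 2, roi$offset - roi$pad, "+")
}

## greedy non-maximum suppression over the correlation map: collect up to
## `k` peaks at least `peak_radius` apart, keep those within `score_slack`
## of the best, and return the (template-centre) location with the highest
## mean image intensity around it
brightest_match_peak <- function(score_map, image, peak_radius, half,
                                 k = 5L, score_slack = 0.85) {
  sm <- score_map
  cand <- list()
  for (i in seq_len(k)) {
    mx <- max(sm)
    if (!is.finite(mx) || mx <= -1) break
    idx <- arrayInd(which.max(sm), dim(sm))
    cand[[i]] <- c(idx[1], idx[2], mx)
    rs <- max(1, idx[1] - peak_radius):min(nrow(sm), idx[1] + peak_radius)
    cs <- max(1, idx[2] - peak_radius):min(ncol(sm), idx[2] + peak_radius)
    sm[rs, cs] <- -Inf
  }
  cand <- do.call(rbind, cand)
  keep <- cand[, 3] >= score_slack * cand[1, 3]
  cand <- cand[keep, , drop = FALSE]
  bright <- apply(cand, 1, function(p) {
    ctr <- c(p[1] + half, p[2] + half)  # template centre, 1-based
    rs <- max(1, ctr[1] - half %/% 2):min(nrow(image), ctr[1] + half %/% 2)
    cs <- max(1, ctr[2] - half %/% 2):min(ncol(image), ctr[2] + half %/% 2)
    mean(image[rs, cs])
  })
  best <- cand[which.max(bright), ]
  c(best[1] - 1 + half, best[2] - 1 + half)  # 0-based template centre
}

#' Localize the optic disc in a full fundus image
#'
#' Runs the two-stage localization: Pearson template matching on the HSI
#' intensity channel (coarse match on a 4x downsampled image, refined at full
#' resolution in a +/- 32 px window), then Canny + circle Hough inside the
#' ROI around the match to fix the centre and estimate the radius.
#'
#' @param rgb rows x cols x 3 array in \[0, 1\].
#' @param template_spec a [template_spec()].
#' @param radii Hough radius list in pixels.
#' @param roi_side ROI side in pixels.
#' @param canny_threshold high hysteresis threshold for [canny_edges()].
#' @param downsample integer coarse-search factor.
#' @return a [disc_estimate()] in full-image coordinates.
#' @export
locate_disc <- function(rgb, template_spec = odseg::template_spec(),
                        radii = seq(140, 230, by = 15), roi_side = 900,
                        canny_threshold = 0.4, downsample = 4L) {
  gray <- hsi_intensity(rgb)
  ## coarse: downsampled image against a correspondingly scaled template
  small <- downsample_mean(gray, downsample)
  sside <- floor(template_spec$side / downsample)
  if (sside %% 2 == 0) sside <- sside + 1
  tsmall <- build_disc_template(template_spec(
    side = sside,
    core_diameter = template_spec$core_diameter / downsample,
    edge_softness = max(template_spec$edge_softness / downsample, 2)))
  coarse <- pearson_match(small, tsmall)
  ## Pearson correlation is scale-invariant, so a faint radially symmetric
  ## shading patch can outscore a vessel-crossed disc. Among near-maximal
  ## correlation peaks, prefer the brightest: the disc is the brightest
  ## round structure of a normal fundus.
  approx_center <- brightest_match_peak(coarse$score_map, small,
                                        peak_radius = (sside - 1) %/% 2,
                                        half = (sside - 1) %/% 2) * downsample

  ## refine with the full-resolution template in a +/-32 px window
  tmpl <- build_disc_template(template_spec)
  half <- (template_spec$side - 1) / 2
  win <- 32
  sub <- extract_roi(gray, approx_center, side = template_spec$side + 2 * win)
  fine <- pearson_match(sub$image, tmpl)
  center <- roi_to_full(sub, fine$peak)[1, ]

  ## Hough refinement inside the ROI around the template match; the centre
  ## search stays near the template hit so vessel-edge vote pile-ups far
  ## from the disc cannot win
  roi <- extract_roi(gray, center, side = roi_side)
  edges <- canny_edges(roi$image, high_threshold = canny_threshold)
  est <- hough_circle(edges, radii, search_center = roi$center,
                      search_radius = 120)
  full_center <- roi_to_full(roi, est$center)[1, ]
  disc_estimate(full_center, est$radius, est$score)
}
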