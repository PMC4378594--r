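## Synthetic fundus-like fixtures: a bright, vertically slightly oval disc
## with a brighter inner cup, dark branching vessels radiating from the disc,
## an optional crescent of peripapillary atrophy (PPA) on the temporal side,
## smooth illumination inhomogeneity and Gaussian pixel noise. Every sample
## carries its ground-truth disc/cup/vessel/PPA masks, standing in for a
## high-resolution fundus database with expert annotations.

#' Specification of a synthetic fundus sample
#'
#' Defines the geometry, photometry and noise of one generated image. The
#' defaults reflect the image population the segmentation pipeline targets:
#' disc width (twice the horizontal semi-axis) in the 260--380 px range on a
#' high-resolution retina, a vertically slightly oval disc, a brighter cup
#' occupying about half the disc radius, and vessels 6--14 px wide.
#'
#' @param image_height,image_width canvas size in pixels.
#' @param disc_center 0-based (row, col) of the disc centre.
#' @param disc_semi_axes (vertical, horizontal) semi-axes in pixels; the
#'   vertical one must be >= the horizontal one (the disc is vertically
#'   slightly oval).
#' @param disc_brightness additive disc intensity relative to background, in
#'   \[0, 1\] (applied channel-wise with a yellowish-red weighting, so the red
#'   channel has the strongest disc/background contrast).
#' @param cup_ratio cup semi-axes as a fraction of the disc semi-axes,
#'   strictly inside (0, 1).
#' @param cup_brightness additive cup intensity on top of the disc.
#' @param edge_softness width (px) of the smooth error-function falloff of
#'   the disc rim, so fuzzy boundaries are representable.
#' @param n_vessels number of primary vessels leaving the disc.
#' @param vessel_width_range (min, max) vessel width in pixels.
#' @param vessel_darkening multiplicative darkening of vessel pixels (0--1).
#' @param ppa_enabled render a PPA crescent abutting the temporal disc rim.
#' @param ppa_thickness maximal radial thickness of the crescent in pixels.
#' @param ppa_brightness PPA intensity as a fraction of `disc_brightness`
#'   (strictly between 0 and 1 so PPA sits between background and disc).
#' @param illumination_tilt total intensity drop of the linear illumination
#'   ramp across the image diagonal.
#' @param noise_sigma std of i.i.d. Gaussian intensity noise.
#' @param seed integer seed; identical specs generate bit-identical samples.
#' @return an object of class `fundus_spec`.
#' @export
fundus_spec <- function(image_height = 1440, image_width = 1440,
                        disc_center = c(720, 720),
                        disc_semi_axes = c(175, 160),
                        disc_brightness = 0.45,
                        cup_ratio = 0.45,
                        cup_brightness = 0.18,
                        edge_softness = 8,
                        n_vessels = 6,
                        vessel_width_range = c(6, 14),
                        vessel_darkening = 0.55,
                        ppa_enabled = FALSE,
                        ppa_thickness = 45,
                        ppa_brightness = 0.5,
                        illumination_tilt = 0.10,
                        noise_sigma = 0.01,
                        seed = 1L) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               disc_center = as.numeric(disc_center),
               disc_semi_axes = as.numeric(disc_semi_axes),
               disc_brightness = disc_brightness,
               cup_ratio = cup_ratio,
               cup_brightness = cup_brightness,
               edge_softness = edge_softness,
               n_vessels = as.integer(n_vessels),
               vessel_width_range = as.numeric(vessel_width_range),
               vessel_darkening = vessel_darkening,
               ppa_enabled = isTRUE(ppa_enabled),
               ppa_thickness = ppa_thickness,
               ppa_brightness = ppa_brightness,
               illumination_tilt = illumination_tilt,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  class(spec) <- "fundus_spec"
  validate_fundus_spec(spec)
  spec
}

validate_fundus_spec <- function(spec, roi_margin = 500) {
  with(spec, {
    if (disc_semi_axes[1] < disc_semi_axes[2])
      stop("vertical disc semi-axis must be >= horizontal (slightly oval disc)",
           call. = FALSE)
    if (cup_ratio <= 0 || cup_ratio >= 1)
      stop("cup_ratio must lie strictly inside (0, 1)", call. = FALSE)
    if (ppa_brightness <= 0 || ppa_brightness >= 1)
      stop("ppa_brightness must lie strictly inside (0, 1)", call. = FALSE)
    if (n_vessels < 0) stop("n_vessels must be >= 0", call. = FALSE)
    margins <- c(top = disc_center[1], left = disc_center[2],
                 bottom = image_height - 1 - disc_center[1],
                 right = image_width - 1 - disc_center[2])
    bad <- margins < roi_margin
    if (any(bad))
      stop(sprintf(paste("disc centre violates the %d px margin on the %s",
                         "side (margin %.0f px): the analysis window would",
                         "not fit"),
                   roi_margin, names(margins)[bad][1], margins[bad][1]),
           call. = FALSE)
  })
  invisible(spec)
}

## signed soft step: ~1 well inside the ellipse, ~0 well outside, with an
## error-function transition of width `softness` around the rim
soft_ellipse <- function(rr, cc, center, semi, softness) {
  re <- sqrt(((rr - center[1]) / semi[1])^2 + ((cc - center[2]) / semi[2])^2)
  d <- (re - 1) * sqrt(prod(semi))  # approximate signed distance in px
  pnorm(-d / pmax(softness / 2, 1e-6))
}

hard_ellipse <- function(rr, cc, center, semi) {
  ((rr - center[1]) / semi[1])^2 + ((cc - center[2]) / semi[2])^2 <= 1
}

#' Generate the branching vessel tree of a synthetic sample
#'
#' Draws `n_vessels` curvilinear vessels as seeded random walks leaving the
#' disc-centre region, each with one or two side branches, rasterized at the
#' widths in `vessel_width_range` (tapering towards the periphery). The mask
#' doubles as the "golden" vessel segmentation consumed by vessel removal.
#'
#' @param spec a [fundus_spec()].
#' @return logical matrix of the canvas size.
#' @export
generate_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "fundus_spec"))
  nr <- spec$image_height; nc <- spec$image_width
  mask <- matrix(FALSE, nr, nc)
  if (spec$n_vessels == 0L) return(mask)
  wmin <- spec$vessel_width_range[1]; wmax <- spec$vessel_width_range[2]
  stamps <- with_seed(spec$seed * 7L + 101L, {
    base_angles <- seq(0, 2 * pi, length.out = spec$n_vessels + 1L)[-1L]
    out <- vector("list", spec$n_vessels)
    for (v in seq_len(spec$n_vessels)) {
      ang <- base_angles[v] + runif(1, -0.25, 0.25)
      start <- spec$disc_center + spec$disc_semi_axes *
        c(sin(ang), cos(ang)) * runif(1, 0.15, 0.45)
      w0 <- runif(1, (wmin + wmax) / 2, wmax)
      out[[v]] <- trace_vessel(start, ang, w0, wmin, spec, depth = 0L)
    }
    do.call(rbind, out)
  })
  ## rasterize all stamps into one mask (single local matrix, updated in place)
  for (k in seq_len(nrow(stamps))) {
    ctr <- stamps[k, 1:2]; radius <- stamps[k, 3]
    r0 <- max(1L, floor(ctr[1] - radius) + 1L)
    r1 <- min(nr, ceiling(ctr[1] + radius) + 1L)
    c0 <- max(1L, floor(ctr[2] - radius) + 1L)
    c1 <- min(nc, ceiling(ctr[2] + radius) + 1L)
    rows <- r0:r1; cols <- c0:c1
    sub <- outer((rows - 1) - ctr[1], (cols - 1) - ctr[2],
                 function(a, b) a * a + b * b) <= radius * radius
    mask[rows, cols] <- mask[rows, cols] | sub
  }
  mask
}

## random-walk polyline from `start` along `ang` with tapering width;
## returns the (row, col, radius) stamps that rasterize the vessel
trace_vessel <- function(start, ang, w0, wmin, spec, depth) {
  nr <- spec$image_height; nc <- spec$image_width
  n_steps <- if (depth == 0L) 240L else 90L
  step <- 4
  curl <- runif(1, -0.012, 0.012)
  pos <- start
  branch_at <- if (depth < 1L) sort(sample(40:200, 2L)) else integer(0)
  stamps <- matrix(0, 0, 3)
  for (s in seq_len(n_steps)) {
    ang <- ang + curl + rnorm(1, 0, 0.05)
    pos <- pos + step * c(sin(ang), cos(ang))
    if (pos[1] < 2 || pos[1] > nr - 1 || pos[2] < 2 || pos[2] > nc - 1) break
    w <- max(wmin, w0 * (1 - 0.5 * s / n_steps))
    stamps <- rbind(stamps, c(pos, w / 2))
    if (s %in% branch_at) {
      bang <- ang + sample(c(-1, 1), 1) * runif(1, 0.5, 0.9)
      stamps <- rbind(stamps,
                      trace_vessel(pos, bang, max(wmin, w * 0.7), wmin, spec,
                                   depth + 1L))
    }
  }
  stamps
}

#' Generate a synthetic fundus sample with ground truth
#'
#' Renders the RGB image described by `spec` together with binary
#' ground-truth masks for the disc, cup, vessels and (optionally) PPA. The
#' red channel carries the strongest disc/background contrast, vessels are
#' strictly darker than the tissue they overlay in every channel, and PPA
#' intensity lies strictly between background and disc. Identical specs
#' (including the seed) yield bit-identical samples.
#'
#' @param spec a [fundus_spec()].
#' @return an object of class `fundus_sample`: a list with elements `rgb`
#'   (rows x cols x 3 array in \[0, 1\]), `disc_mask`, `cup_mask`,
#'   `vessel_mask`, `ppa_mask` (logical matrices) and `spec`.
#' @export
generate_fundus <- function(spec) {
  stopifnot(inherits(spec, "fundus_spec"))
  validate_fundus_spec(spec)
  nr <- spec$image_height; nc <- spec$image_width
  rr <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)

  ## background: base tint + linear illumination ramp + low-frequency field
  diag_len <- sqrt(nr^2 + nc^2)
  ramp <- spec$illumination_tilt * ((rr - nr / 2) + (cc - nc / 2)) / diag_len
  lowfreq <- with_seed(spec$seed * 7L + 11L, {
    coarse <- matrix(runif(64, -1, 1), 8, 8)
    field <- EBImage::resize(coarse, w = nr, h = nc)
    0.05 * (field - mean(field))
  })
  shading <- ramp + lowfreq

  ## geometry, computed on a bounding box around the disc + PPA and embedded
  ## into full-size planes
  ext <- max(spec$disc_semi_axes) + spec$ppa_thickness + 6 * spec$edge_softness
  b_r <- max(1L, floor(spec$disc_center[1] - ext)):
    min(nr, ceiling(spec$disc_center[1] + ext))
  b_c <- max(1L, floor(spec$disc_center[2] - ext)):
    min(nc, ceiling(spec$disc_center[2] + ext))
  brr <- matrix(b_r - 1, length(b_r), length(b_c))
  bcc <- matrix(b_c - 1, length(b_r), length(b_c), byrow = TRUE)
  embed_num <- function(small) {
    m <- matrix(0, nr, nc); m[b_r, b_c] <- small; m
  }
  embed_bool <- function(small) {
    m <- matrix(FALSE, nr, nc); m[b_r, b_c] <- small; m
  }

  disc_soft <- embed_num(soft_ellipse(brr, bcc, spec$disc_center,
                                      spec$disc_semi_axes,
                                      spec$edge_softness))
  cup_semi <- spec$cup_ratio * spec$disc_semi_axes
  cup_soft <- embed_num(soft_ellipse(brr, bcc, spec$disc_center, cup_semi,
                                     spec$edge_softness * 0.75))
  disc_mask <- embed_bool(hard_ellipse(brr, bcc, spec$disc_center,
                                       spec$disc_semi_axes))
  cup_mask <- embed_bool(hard_ellipse(brr, bcc, spec$disc_center, cup_semi))

  ppa_mask <- matrix(FALSE, nr, nc)
  ppa_soft <- 0
  if (spec$ppa_enabled) {
    outer_semi <- spec$disc_semi_axes + spec$ppa_thickness
    ring_soft <- soft_ellipse(brr, bcc, spec$disc_center, outer_semi,
                              spec$edge_softness) *
      (1 - disc_soft[b_r, b_c])
    ## crescent on the temporal (positive-column) side with angular taper
    theta <- atan2(brr - spec$disc_center[1], bcc - spec$disc_center[2])
    taper <- pmax(cos(theta), 0)^0.75
    ppa_soft <- embed_num(ring_soft * taper)
    ring_hard <- hard_ellipse(brr, bcc, spec$disc_center, outer_semi) &
      !disc_mask[b_r, b_c]
    ppa_mask <- embed_bool(ring_hard & (abs(theta) < pi * 5 / 12))
  }

  vessel_mask <- generate_vessel_tree(spec)
  vessel_soft <- EBImage::gblur(vessel_mask * 1, sigma = 1)
  vessel_soft <- pmax(vessel_soft, vessel_mask)  # full darkening on the mask

  base <- c(0.46, 0.27, 0.12)              # reddish-orange retina
  disc_gain <- c(1.00, 0.70, 0.30)         # bright yellowish disc, red-dominant
  noise <- with_seed(spec$seed * 7L + 29L,
                     array(rnorm(nr * nc * 3, 0, spec$noise_sigma),
                           dim = c(nr, nc, 3)))
  img <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    plane <- base[ch] * (1 + shading) +
      spec$disc_brightness * disc_gain[ch] * disc_soft +
      spec$cup_brightness * disc_gain[ch] * cup_soft
    if (spec$ppa_enabled)
      plane <- plane +
        spec$ppa_brightness * spec$disc_brightness * disc_gain[ch] * ppa_soft
    plane <- plane * (1 - spec$vessel_darkening * vessel_soft)
    img[, , ch] <- clamp01(plane + noise[, , ch])
  }

  structure(list(rgb = img,
                 disc_mask = disc_mask,
                 cup_mask = cup_mask,
                 vessel_mask = vessel_mask,
                 ppa_mask = ppa_mask,
                 spec = spec),
            class = "fundus_sample")
}

#' Draw a randomized fundus spec for batch studies
#'
#' Samples the fixture geometry and photometry from their population ranges:
#' disc width uniform in 260--380 px, vertical elongation 1.00--1.15, centre
#' jitter within +/- 25 px, cup ratio 0.35--0.55, and moderate variation of
#' brightness, illumination tilt and PPA extent. Deterministic in `seed`.
#'
#' @param seed integer seed (also the rendering seed of the sample).
#' @param ppa_enabled render a PPA crescent.
#' @return a [fundus_spec()].
#' @export
random_fundus_spec <- function(seed, ppa_enabled = TRUE) {
  with_seed(seed * 13L + 7L, {
    width <- runif(1, 260, 380)
    ah <- width / 2
    av <- ah * runif(1, 1.0, 1.15)
    fundus_spec(disc_center = c(720, 720) + runif(2, -25, 25),
                disc_semi_axes = c(av, ah),
                disc_brightness = runif(1, 0.35, 0.5),
                cup_ratio = runif(1, 0.35, 0.55),
                n_vessels = sample(5:7, 1),
                ppa_enabled = ppa_enabled,
                ppa_thickness = runif(1, 30, 60),
                ppa_brightness = runif(1, 0.4, 0.6),
                illumination_tilt = runif(1, 0.05, 0.15),
                seed = seed)
  })
}

#' @export
print.fundus_sample <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<fundus_sample> %dx%d, disc at (%.0f, %.0f), semi-axes (%.0f, %.0f)\n",
              s$image_height, s$image_width, s$disc_center[1], s$disc_center[2],
              s$disc_semi_axes[1], s$disc_semi_axes[2]))
  cat(sprintf("  vessels: %d, PPA: %s, seed: %d\n", s$n_vessels,
              if (s$ppa_enabled) "yes" else "no", s$seed))
  invisible(x)
}
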