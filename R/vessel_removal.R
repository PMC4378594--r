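## Blood vessels leaving the disc cross (and visually break) the disc rim, so
## they are erased before texture extraction. The preferred operator solves
## the Laplace equation over the vessel mask (harmonic diffusion inpainting)
## with the surrounding tissue as Dirichlet data; grayscale closing and
## neighborhood-mean replacement are provided as alternatives.

#' Configuration for diffusion inpainting
#'
#' @param mask_dilation pixels of binary dilation applied to the mask before
#'   inpainting, to swallow vessel-edge halos (default 2).
#' @param tolerance stop when the largest per-pixel update of a Gauss-Seidel
#'   sweep falls below this (on the \[0, 1\] intensity scale).
#' @param max_iterations sweep cap.
#' @param omega relaxation factor of the checkerboard sweeps: 1 is plain
#'   Gauss-Seidel, values towards 2 over-relax (SOR) and converge much
#'   faster on large regions. Inpainted values are clamped to the Dirichlet
#'   range, so the maximum principle holds for any `omega`.
#' @return an object of class `inpaint_config`.
#' @export
inpaint_config <- function(mask_dilation = 2, tolerance = 1e-4,
                           max_iterations = 5000, omega = 1) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (omega <= 0 || omega >= 2) stop("omega must be in (0, 2)", call. = FALSE)
  structure(list(mask_dilation = as.integer(mask_dilation),
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 omega = omega),
            class = "inpaint_config")
}

dilate_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  EBImage::dilate(mask * 1, EBImage::makeBrush(2L * px + 1L, "disc")) > 0
}

#' Harmonic (diffusion) inpainting over a mask
#'
#' Replaces the pixels under the (optionally dilated) mask with the solution
#' of the Laplace equation whose boundary values are the untouched pixels,
#' via red-black Gauss-Seidel iteration. All pixels outside the dilated mask
#' are returned bit-exactly unchanged, and the inpainted values obey the
#' discrete maximum principle. Color images are processed per channel.
#'
#' @param image numeric matrix or rows x cols x 3 array.
#' @param mask logical matrix of the same spatial size; `TRUE` marks pixels
#'   to be replaced. An empty mask returns the input unchanged; an all-true
#'   mask is an error.
#' @param cfg an [inpaint_config()].
#' @return raster of the same shape as `image`.
#' @export
inpaint_diffusion <- function(image, mask, cfg = inpaint_config()) {
  stopifnot(inherits(cfg, "inpaint_config"))
  if (is.array(image) && length(dim(image)) == 3) {
    out <- image
    for (ch in seq_len(dim(image)[3]))
      out[, , ch] <- inpaint_diffusion(image[, , ch], mask, cfg)
    return(out)
  }
  assert_gray(image)
  mask <- mask > 0
  if (!identical(dim(mask), dim(image)))
    stop("mask and image must have the same shape", call. = FALSE)
  if (!any(mask)) return(image)
  m <- dilate_mask(mask, cfg$mask_dilation)
  if (all(m)) stop("mask covers the entire image; nothing to diffuse from",
                   call. = FALSE)
  out <- .inpaint_gs(image, m, cfg$tolerance, cfg$max_iterations,
                     if (is.null(cfg$omega)) 1 else cfg$omega)
  attr(out, "iterations") <- NULL
  out
}

#' Vessel removal by grayscale morphological closing
#'
#' Closes dark, thin structures with a disc structuring element; no vessel
#' mask is needed, but the operation blurs genuine texture as well. Closing
#' is extensive: the output is pointwise >= the input.
#'
#' @param image numeric matrix (one channel).
#' @param se_radius radius of the disc structuring element (default 15).
#' @return numeric matrix.
#' @export
remove_vessels_closing <- function(image, se_radius = 15) {
  assert_gray(image)
  EBImage::closing(image, EBImage::makeBrush(2L * se_radius + 1L, "disc"))
}

#' Vessel removal by neighborhood-mean replacement
#'
#' Each masked pixel is replaced by the mean of the non-masked pixels in its
#' `window` x `window` neighborhood; if that neighborhood contains no
#' unmasked pixel, the window is doubled (repeatedly) until one is found.
#' Non-masked pixels are unchanged.
#'
#' @param image numeric matrix.
#' @param mask logical matrix; `TRUE` marks vessel pixels.
#' @param window odd window side in pixels (default 31).
#' @return numeric matrix.
#' @export
remove_vessels_mean <- function(image, mask, window = 31) {
  assert_gray(image)
  mask <- mask > 0
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (!any(mask)) return(image)
  valid <- !mask
  out <- image
  todo <- mask
  w <- window
  while (any(todo) && w <= 4 * max(dim(image))) {
    ones <- matrix(1, w, w)
    num <- conv2_same(image * valid, ones, boundary = "zero")
    den <- conv2_same(valid * 1, ones, boundary = "zero")
    ok <- todo & den > 0.5
    out[ok] <- num[ok] / den[ok]
    todo <- todo & !ok
    w <- 2 * w + 1
  }
  out
}
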