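## Shared raster helpers. Images are plain numeric matrices indexed
## [row, col] with intensities in [0, 1]; color images are [row, col, channel]
## arrays in R, G, B order. All coordinates are 0-based (row, col) at pixel
## centres, matching the JSON/CLI interfaces.

assert_gray <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix (single-channel raster)", arg),
         call. = FALSE)
  invisible(x)
}

assert_rgb <- function(x, arg = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop(sprintf("`%s` must be a 3-channel array (rows x cols x 3)", arg),
         call. = FALSE)
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Two-dimensional convolution with selectable boundary handling
#'
#' Same-size convolution of a raster with a kernel, computed in the Fourier
#' domain. The default reflects the image at its borders, so filter-bank
#' responses have no wrap-around or zero-padding artifacts.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd side lengths.
#' @param boundary `"reflect"` (mirror the image at its borders) or `"zero"`.
#' @return numeric matrix of the same size as `img`.
#' @keywords internal
conv2_same <- function(img, kernel, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2 == 0 || kc %% 2 == 0)
    stop("kernel must have odd side lengths", call. = FALSE)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  pad <- pad_image(img, hr, hc, mode = if (boundary == "reflect") "reflect" else "zero")
  full <- conv2_full(pad, kernel)
  full[(2L * hr + 1L):(2L * hr + nrow(img)),
       (2L * hc + 1L):(2L * hc + ncol(img)), drop = FALSE]
}

## full (nr+kr-1) x (nc+kc-1) linear convolution via zero-padded FFT
conv2_full <- function(img, kernel) {
  nr <- nrow(img) + nrow(kernel) - 1L
  nc <- ncol(img) + ncol(kernel) - 1L
  A <- matrix(0, nr, nc); A[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  B <- matrix(0, nr, nc); B[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  Re(fft(fft(A) * fft(B), inverse = TRUE)) / (nr * nc)
}

## valid-positions cross-correlation: out[i,j] = sum_{u,v} f[i+u-1, j+v-1] k[u,v]
xcorr_valid <- function(f, k) {
  full <- conv2_full(f, k[nrow(k):1, ncol(k):1, drop = FALSE])
  full[nrow(k):nrow(f), ncol(k):ncol(f), drop = FALSE]
}

pad_image <- function(img, pr, pc, mode = c("reflect", "zero", "replicate")) {
  mode <- match.arg(mode)
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(seq_len(pr), seq_len(nr), nr + seq_len(pr))
  cidx <- c(seq_len(pc), seq_len(nc), nc + seq_len(pc))
  if (mode == "zero") {
    out <- matrix(0, nr + 2L * pr, nc + 2L * pc)
    out[pr + seq_len(nr), pc + seq_len(nc)] <- img
    return(out)
  }
  if (mode == "reflect") {
    rmap <- c(rev(seq_len(min(pr, nr - 1L)) + 1L), seq_len(nr),
              nr - seq_len(min(pr, nr - 1L)))
    if (length(rmap) < nr + 2L * pr)  # very small images: fall back to clamping
      rmap <- pmin(pmax(seq.int(1L - pr, nr + pr), 1L), nr)
    cmap <- c(rev(seq_len(min(pc, nc - 1L)) + 1L), seq_len(nc),
              nc - seq_len(min(pc, nc - 1L)))
    if (length(cmap) < nc + 2L * pc)
      cmap <- pmin(pmax(seq.int(1L - pc, nc + pc), 1L), nc)
    return(img[rmap, cmap, drop = FALSE])
  }
  rmap <- pmin(pmax(seq.int(1L - pr, nr + pr), 1L), nr)
  cmap <- pmin(pmax(seq.int(1L - pc, nc + pc), 1L), nc)
  img[rmap, cmap, drop = FALSE]
}

## 3x3 box sum via shifted adds (zero boundary); cheaper than FFT for tiny
## kernels on large rasters
box3_smooth <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- out[rs, cs] + m[rs - dr, cs - dc]
  }
  out
}

## convolve one image with several kernels sharing one padded image FFT;
## all kernels are zero-padded to the largest support
conv2_same_bank <- function(img, kernels) {
  sides <- vapply(kernels, nrow, integer(1))
  side <- max(sides)
  h <- (side - 1L) %/% 2L
  pad <- pad_image(img, h, h, mode = "reflect")
  nr <- nrow(pad) + side - 1L
  nc <- ncol(pad) + side - 1L
  A <- matrix(0, nr, nc); A[seq_len(nrow(pad)), seq_len(ncol(pad))] <- pad
  FA <- fft(A)
  out <- vector("list", length(kernels))
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    off <- (side - nrow(k)) %/% 2L  # centre smaller kernels in the support
    B <- matrix(0, nr, nc)
    B[off + seq_len(nrow(k)), off + seq_len(ncol(k))] <- k
    full <- Re(fft(FA * fft(B), inverse = TRUE)) / (nr * nc)
    shift <- 2L * h  # pad h + kernel half hk + embedding offset = 2h
    out[[i]] <- full[(shift + 1L):(shift + nrow(img)),
                     (shift + 1L):(shift + ncol(img)), drop = FALSE]
  }
  out
}

## 8-connected component labelling (see src/odseg.cpp)
label_components <- function(mask) {
  .cc_label8(mask)
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  n <- attr(lab, "n")
  if (n == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(sizes)
}

## block-mean downsampling by an integer factor (trailing remainder cropped)
downsample_mean <- function(img, factor) {
  nr <- (nrow(img) %/% factor) * factor
  nc <- (ncol(img) %/% factor) * factor
  x <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  x <- matrix(colMeans(matrix(x, nrow = factor)), nrow = nr %/% factor)
  t(matrix(colMeans(matrix(t(x), nrow = factor)), nrow = nc %/% factor))
}

## deterministic scoped RNG: run `expr` under set.seed(seed), restore state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read an image file as a [0, 1] raster
#'
#' @param path a PNG file.
#' @param gray if `TRUE`, collapse color inputs to the HSI intensity channel.
#' @return numeric matrix or rows x cols x 3 array.
#' @export
read_image <- function(path, gray = FALSE) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  if (gray && length(dim(x)) == 3L) x <- hsi_intensity(x)
  x
}

#' Write a [0, 1] raster to a PNG file
#'
#' @param x numeric matrix, logical matrix (masks), or rows x cols x 3 array.
#' @param path output path.
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- x * 1
  png::writePNG(clamp01(x), path)
  invisible(path)
}
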