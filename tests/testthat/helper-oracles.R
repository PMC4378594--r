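# Brute-force reference implementations used as independent oracles.
# All of them are plain double loops over pixels, kept deliberately naive.

# Pearson correlation score map by direct evaluation at every valid position
oracle_pearson_map <- function(gray, tmpl) {
  tr <- nrow(tmpl); tc <- ncol(tmpl)
  nr <- nrow(gray) - tr + 1; nc <- ncol(gray) - tc + 1
  tm <- mean(tmpl)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- gray[i:(i + tr - 1), j:(j + tc - 1)]
      fm <- mean(win)
      num <- sum((win - fm) * (tmpl - tm))
      den <- sqrt(sum((win - fm)^2) * sum((tmpl - tm)^2))
      out[i, j] <- if (den < 1e-12) 0 else num / den
    }
  }
  out
}

# circle Hough accumulator for one radius, explicit loops, midpoint circle
oracle_hough_accumulator <- function(edges, radius) {
  off <- odseg:::midpoint_circle_offsets(radius)
  nr <- nrow(edges); nc <- ncol(edges)
  acc <- matrix(0L, nr, nc)
  ep <- which(edges, arr.ind = TRUE)
  for (k in seq_len(nrow(ep))) {
    for (o in seq_len(nrow(off))) {
      r <- ep[k, 1] + off[o, 1]; c <- ep[k, 2] + off[o, 2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc)
        acc[r, c] <- acc[r, c] + 1L
    }
  }
  acc
}

# masked neighborhood-mean replacement, explicit loops with window doubling
oracle_mean_replace <- function(img, mask, window) {
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      w <- window
      repeat {
        h <- (w - 1) / 2
        rs <- max(1, i - h):min(nr, i + h)
        cs <- max(1, j - h):min(nc, j + h)
        vals <- img[rs, cs][!mask[rs, cs]]
        if (length(vals) > 0) { out[i, j] <- mean(vals); break }
        w <- 2 * w + 1
        if (w > 4 * max(nr, nc)) break
      }
    }
  }
  out
}

# even-odd point-in-polygon rasterization, one ray cast per pixel centre
oracle_polygon_mask <- function(pts, shape) {
  n <- nrow(pts)
  mask <- matrix(FALSE, shape[1], shape[2])
  for (r in 0:(shape[1] - 1)) {
    for (c in 0:(shape[2] - 1)) {
      inside <- FALSE
      for (k in seq_len(n)) {
        y1 <- pts[k, 1]; x1 <- pts[k, 2]
        kk <- if (k == n) 1 else k + 1
        y2 <- pts[kk, 1]; x2 <- pts[kk, 2]
        if ((y1 > r) != (y2 > r)) {
          xc <- x1 + (r - y1) / (y2 - y1) * (x2 - x1)
          if (xc < c) inside <- !inside
        }
      }
      mask[r + 1, c + 1] <- inside
    }
  }
  mask
}

# dice from explicit pixel loops
oracle_dice <- function(a, b) {
  na <- 0; nb <- 0; ni <- 0
  for (i in seq_along(a)) {
    na <- na + a[i]; nb <- nb + b[i]
    ni <- ni + (a[i] && b[i])
  }
  if (na + nb == 0) 1 else 2 * ni / (na + nb)
}

# small deterministic random raster
random_raster <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}
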