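## Texture-driven balloon snake. A closed contour u(s) inflates from a small
## circle inside the disc under four forces: tension (alpha u_ss), stiffness
## (-beta u_ssss), an isotropic outward pressure (rho times the unit outward
## normal) and an image force that is minus the gradient of a potential
## derived from texture rather than intensity gradient. Internal forces are
## integrated semi-implicitly (cyclic pentadiagonal solve), external forces
## explicitly; the contour is resampled to uniform arc length periodically.

#' Balloon-snake configuration
#'
#' @param alpha tension weight.
#' @param beta stiffness weight.
#' @param rho pressure weight (> 0: the balloon must inflate). Units are
#'   pixels of outward motion per unit time step.
#' @param xi potential (image force) weight.
#' @param time_step descent step.
#' @param n_points number of contour samples (>= 16).
#' @param resample_every resample to uniform arc length every this many
#'   iterations.
#' @param stop_displacement stop when the mean point displacement per
#'   iteration, averaged over `stop_window` iterations, falls below this
#'   (pixels).
#' @param stop_window window for the stopping statistic.
#' @param max_iterations iteration cap.
#' @return an object of class `snake_config`.
#' @export
snake_config <- function(alpha = 0.05, beta = 0.01, rho = 0.08, xi = 3.0,
                         time_step = 1.0, n_points = 120L,
                         resample_every = 10L, stop_displacement = 0.03,
                         stop_window = 20L, max_iterations = 2000L) {
  if (rho <= 0) stop("rho must be positive (the balloon must inflate)",
                     call. = FALSE)
  if (any(c(alpha, beta, xi) < 0)) stop("weights must be >= 0", call. = FALSE)
  if (n_points < 16) stop("n_points must be >= 16", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, rho = rho, xi = xi,
                 time_step = time_step, n_points = as.integer(n_points),
                 resample_every = as.integer(resample_every),
                 stop_displacement = stop_displacement,
                 stop_window = as.integer(stop_window),
                 max_iterations = as.integer(max_iterations)),
            class = "snake_config")
}

#' Texture potential for the snake
#'
#' The snake's external energy: the negated, min-max normalized texture, so
#' contour points are attracted to texture ridges (the disc rim). Stored on
#' \[-1, 0\].
#'
#' @param clean_texture numeric matrix (enhanced, noise-suppressed texture).
#' @param provenance free-form description of how the texture was produced.
#' @return an object of class `texture_potential`: list with `potential` and
#'   `provenance`.
#' @export
texture_potential <- function(clean_texture, provenance = "mr8[3]") {
  assert_gray(clean_texture, "clean_texture")
  if (!all(is.finite(clean_texture)))
    stop("texture contains non-finite values", call. = FALSE)
  rng <- range(clean_texture)
  p <- if (diff(rng) < 1e-12) clean_texture * 0
       else -(clean_texture - rng[1]) / diff(rng)
  structure(list(potential = p, provenance = provenance),
            class = "texture_potential")
}

#' Initial contour: a circle at half the estimated radius
#'
#' Uniformly sampled counter-clockwise circle centred on the disc estimate
#' with radius `estimate$radius / 2`, guaranteed to start inside the disc.
#'
#' @param estimate a [disc_estimate()] (in the potential's coordinates).
#' @param n_points number of samples.
#' @param radius_factor fraction of the estimated radius (default 0.5).
#' @return an object of class `snake_contour`: matrix of (row, col) points
#'   with attribute `closed = TRUE`.
#' @export
init_circle <- function(estimate, n_points = 120L, radius_factor = 0.5) {
  stopifnot(inherits(estimate, "disc_estimate"))
  r <- estimate$radius * radius_factor
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  pts <- cbind(row = estimate$center[1] + r * sin(th),
               col = estimate$center[2] + r * cos(th))
  structure(pts, class = c("snake_contour", "matrix", "array"))
}

## uniform arc-length resampling of a closed polyline to n points
resample_contour <- function(pts, n) {
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), ] - pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < 1e-12) return(pts[rep(1, n), ])
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  closed <- rbind(pts, pts[1, ])
  out <- cbind(approx(cum, closed[, 1], xout = target)$y,
               approx(cum, closed[, 2], xout = target)$y)
  colnames(out) <- c("row", "col")
  out
}

## signed polygon area (shoelace) in pixel^2; sign encodes orientation
polygon_area_signed <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## bilinear interpolation of matrix values at sub-pixel 0-based points
bilinear_at <- function(m, pts) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(pts[, 1], 0), nr - 1); c <- pmin(pmax(pts[, 2], 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

#' Evolve the balloon snake
#'
#' Gradient descent on the balloon-snake energy. Per iteration the internal
#' terms are applied through a semi-implicit solve of the cyclic system
#' `(I - dt (alpha D2 - beta D4)) x_new = x + dt F_ext`, and the external
#' forces -- pressure `rho` along the outward unit normal and the image
#' force `-xi grad P` (bilinearly interpolated, magnitude capped at 1) --
#' explicitly. The contour is resampled to uniform arc length every
#' `resample_every` iterations and evolution stops when the mean per-point
#' displacement averaged over `stop_window` iterations drops below
#' `stop_displacement`, or at `max_iterations`.
#'
#' @param contour a [init_circle()] contour (or any closed (row, col)
#'   matrix).
#' @param pot a [texture_potential()].
#' @param cfg a [snake_config()].
#' @return list with `contour` (final points), `trace` (data.frame with
#'   iteration, mean_displacement, area) and `converged`.
#' @export
evolve <- function(contour, pot, cfg = snake_config()) {
  stopifnot(inherits(pot, "texture_potential"), inherits(cfg, "snake_config"))
  P <- pot$potential
  nr <- nrow(P); nc <- ncol(P)
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n != cfg$n_points) pts <- resample_contour(pts, cfg$n_points)
  n <- nrow(pts)

  ## potential gradient (central differences), sampled bilinearly later
  gr <- (rbind(P[2:nr, ], P[nr, ]) - rbind(P[1, ], P[1:(nr - 1), ])) / 2
  gc <- (cbind(P[, 2:nc], P[, nc]) - cbind(P[, 1], P[, 1:(nc - 1)])) / 2

  ## semi-implicit internal-force operator (cyclic, solved once)
  idx <- function(s) ((seq_len(n) - 1 + s) %% n) + 1
  D2 <- diag(-2, n); D4 <- diag(6, n)
  for (s in c(-1, 1)) {
    D2[cbind(seq_len(n), idx(s))] <- D2[cbind(seq_len(n), idx(s))] + 1
    D4[cbind(seq_len(n), idx(s))] <- D4[cbind(seq_len(n), idx(s))] - 4
  }
  for (s in c(-2, 2))
    D4[cbind(seq_len(n), idx(s))] <- D4[cbind(seq_len(n), idx(s))] + 1
  A <- cfg$alpha * D2 - cfg$beta * D4
  M <- solve(diag(n) - cfg$time_step * A)

  clamped <- FALSE
  disp <- numeric(cfg$max_iterations)
  area <- numeric(cfg$max_iterations)
  it_done <- 0L
  for (it in seq_len(cfg$max_iterations)) {
    prev <- idx(-1); nxt <- idx(1)
    tang <- pts[nxt, ] - pts[prev, ]
    tlen <- sqrt(rowSums(tang^2)); tlen[tlen < 1e-12] <- 1e-12
    normal <- cbind(-tang[, 2], tang[, 1]) / tlen  # unit, orientation-dependent
    ## force the normal outward regardless of stored orientation
    centroid <- colMeans(pts)
    outward <- sweep(pts, 2, centroid)
    flip <- rowSums(normal * outward) < 0
    normal[flip, ] <- -normal[flip, ]

    fimg <- -cfg$xi * cbind(bilinear_at(gr, pts), bilinear_at(gc, pts))
    fmag <- sqrt(rowSums(fimg^2))
    over <- fmag > 1
    if (any(over)) fimg[over, ] <- fimg[over, ] / fmag[over]
    fext <- cfg$rho * normal + fimg

    rhs <- pts + cfg$time_step * fext
    new_pts <- M %*% rhs
    if (any(!is.finite(new_pts)))
      stop("snake update produced non-finite coordinates", call. = FALSE)
    out_of_bounds <- new_pts[, 1] < 0 | new_pts[, 1] > nr - 1 |
      new_pts[, 2] < 0 | new_pts[, 2] > nc - 1
    if (any(out_of_bounds)) {
      if (!clamped) { warning("contour clamped to the raster bounds"); clamped <- TRUE }
      new_pts[, 1] <- pmin(pmax(new_pts[, 1], 0), nr - 1)
      new_pts[, 2] <- pmin(pmax(new_pts[, 2], 0), nc - 1)
    }
    disp[it] <- mean(sqrt(rowSums((new_pts - pts)^2)))
    pts <- new_pts
    area[it] <- abs(polygon_area_signed(pts))
    it_done <- it
    if (it %% cfg$resample_every == 0L) pts <- resample_contour(pts, n)
    if (it >= cfg$stop_window &&
        mean(disp[(it - cfg$stop_window + 1L):it]) < cfg$stop_displacement)
      break
  }
  colnames(pts) <- c("row", "col")
  list(contour = structure(pts, class = c("snake_contour", "matrix", "array")),
       trace = data.frame(iteration = seq_len(it_done),
                          mean_displacement = disp[seq_len(it_done)],
                          area = area[seq_len(it_done)]),
       converged = it_done < cfg$max_iterations)
}

## first pair of properly crossing segments of a closed polyline, or NULL
first_self_intersection <- function(pts) {
  n <- nrow(pts)
  a <- pts; b <- pts[c(2:n, 1), ]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip segments sharing an endpoint
    if (!length(js)) next
    d1 <- b[i, ] - a[i, ]
    d2r <- b[js, 1] - a[js, 1]; d2c <- b[js, 2] - a[js, 2]
    denom <- d1[2] * d2r - d1[1] * d2c
    dr <- a[js, 1] - a[i, 1]; dc <- a[js, 2] - a[i, 2]
    t <- (dc * d2r - dr * d2c) / denom
    u <- (dc * d1[1] - dr * d1[2]) / denom
    hit <- is.finite(t) & is.finite(u) & t > 0 & t < 1 & u > 0 & u < 1
    if (any(hit)) return(c(i, js[which(hit)[1]]))
  }
  NULL
}

#' Rasterize a closed contour to a binary mask
#'
#' Even-odd scan fill: a pixel belongs to the mask when its centre (integer
#' 0-based coordinates) lies inside the polygon.
#'
#' @param contour closed (row, col) matrix of polygon vertices.
#' @param shape (rows, cols) of the output mask.
#' @return logical matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n >= 4) {
    x <- first_self_intersection(pts)
    if (!is.null(x))
      stop(sprintf("contour is self-intersecting: segments %d and %d cross",
                   x[1], x[2]), call. = FALSE)
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  y1 <- pts[, 1]; y2 <- pts[c(2:n, 1), 1]
  x1 <- pts[, 2]; x2 <- pts[c(2:n, 1), 2]
  rows <- max(0, floor(min(y1))):min(shape[1] - 1, ceiling(max(y1)))
  for (r in rows) {
    cross <- (y1 > r) != (y2 > r)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (r - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- floor(xs[k]) + 1; c1 <- floor(xs[k + 1])
      c0 <- max(c0, 0); c1 <- min(c1, shape[2] - 1)
      if (c0 <= c1) mask[r + 1, (c0:c1) + 1] <- TRUE
    }
  }
  mask
}
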