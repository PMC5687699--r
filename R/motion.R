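# Sub-pixel rigid-translation tracking of an image region and its
# reduction to the 1-D pulse-motion signal M used as a phase chronometer
# (piglet cine) and as ventricle wall speed (human endoscopy).

# internal: point-in-polygon by ray casting; boundary counts as inside.
# pts: m x 2 (x, y); poly: k x 2, open or closed
point_in_polygon <- function(pts, poly) {
  poly <- as.matrix(poly)
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  on_edge <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(poly) - 1L)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]; x2 <- poly[k + 1, 1]; y2 <- poly[k + 1, 2]
    cross <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1 + (y2 == y1)) + x1)
    inside <- xor(inside, cross)
    # points on the segment (within tolerance) count as inside
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      tt <- pmin(pmax(((x - x1) * dx + (y - y1) * dy) / len2, 0), 1)
      d2 <- (x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2
      on_edge <- on_edge | d2 < 1e-18
    }
  }
  inside | on_edge
}

# internal: sub-pixel peak refinement on a 3-point neighborhood.
# Log-parabolic when all values are positive (exact for Gaussian peaks),
# plain parabolic otherwise.
refine_peak_1d <- function(vm, v0, vp) {
  if (vm > 0 && v0 > 0 && vp > 0) { vm <- log(vm); v0 <- log(v0); vp <- log(vp) }
  den <- vm - 2 * v0 + vp
  if (den >= 0) return(0)
  max(-1, min(1, 0.5 * (vm - vp) / den))
}

#' Frame-wise displacement of an image region
#'
#' Estimates the rigid 2-D translation of a region of interest in every
#' frame relative to the first, by windowed intensity cross-correlation
#' with sub-pixel (log-parabolic) peak interpolation.  By pooling the
#' hundreds of pixels inside the region, net displacements well below one
#' pixel per frame are measurable.
#'
#' @param cine a [cine_sequence()].
#' @param roi polygon (`k x 2` matrix, columns x and y in 0-based pixel
#'   coordinates) outlining the region to track; must contain at least
#'   `min_pixels` pixel centers and lie strictly inside the frame with a
#'   margin of at least `margin` pixels.
#' @param min_pixels minimum pixel count in the region (default 100).
#' @param margin required clearance between the region and the frame
#'   border, pixels (default 4; should exceed the expected excursion).
#' @param min_correlation normalized correlation-peak height below which
#'   tracking is declared divergent (default 0.3).
#' @return an object of class `displacement_series`: `dx`, `dy`
#'   (cumulative track, pixels, length T, first element 0), `ddx`, `ddy`
#'   (frame-to-frame deltas, length T - 1), `roi`, `fs`.
#' @export
track_region <- function(cine, roi, min_pixels = 100, margin = 4,
                         min_correlation = 0.3) {
  stopifnot(inherits(cine, "cine_sequence"))
  roi <- as.matrix(roi)
  d <- dim(cine$frames)
  h <- d[1]; w <- d[2]; nt <- d[3]
  if (min(roi[, 1]) < margin || max(roi[, 1]) > w - 1 - margin ||
      min(roi[, 2]) < margin || max(roi[, 2]) > h - 1 - margin)
    abort("`roi` must lie strictly inside the frame with a margin of ",
          margin, " pixels")
  cols <- floor(min(roi[, 1])):ceiling(max(roi[, 1]))
  rows <- floor(min(roi[, 2])):ceiling(max(roi[, 2]))
  pts <- cbind(rep(cols, each = length(rows)), rep(rows, times = length(cols)))
  npix <- sum(point_in_polygon(pts, roi))
  if (npix < min_pixels)
    abort("region of interest contains only ", npix,
          " pixels; at least ", min_pixels, " are required")

  sub <- cine$frames[rows + 1L, cols + 1L, , drop = FALSE]
  nr <- length(rows); nc <- length(cols)
  # sharp polygon mask after demeaning: a taper window would bias the
  # sub-pixel shift scale low, whereas the region is chosen so that its
  # boundary crosses only quiet background
  win <- matrix(as.numeric(point_in_polygon(pts, roi)), nr, nc)
  prep <- function(k) {
    a <- sub[, , k]
    (a - mean(a)) * win
  }
  ref <- prep(1L)
  Fref <- stats::fft(ref)
  nref <- sqrt(sum(ref^2))
  dx <- dy <- numeric(nt)
  for (k in 2:nt) {
    a <- prep(k)
    Fa <- stats::fft(a)
    cc <- Re(stats::fft(Fa * Conj(Fref), inverse = TRUE)) / (nr * nc)
    peak <- which.max(cc)
    pr <- (peak - 1L) %% nr; pc <- (peak - 1L) %/% nr
    qual <- cc[peak] / (nref * sqrt(sum(a^2)) + 1e-300)
    if (qual < min_correlation)
      abort("tracking divergence at frame ", k,
            ": correlation peak ", signif(qual, 3), " below threshold")
    ir <- function(i) ((i %% nr) + nr) %% nr + 1L
    ic <- function(j) ((j %% nc) + nc) %% nc + 1L
    fr <- refine_peak_1d(cc[ir(pr - 1), pc + 1L], cc[ir(pr), pc + 1L], cc[ir(pr + 1), pc + 1L])
    fc <- refine_peak_1d(cc[pr + 1L, ic(pc - 1)], cc[pr + 1L, ic(pc)], cc[pr + 1L, ic(pc + 1)])
    sr <- pr + fr; sc <- pc + fc
    if (sr > nr / 2) sr <- sr - nr
    if (sc > nc / 2) sc <- sc - nc
    dy[k] <- sr; dx[k] <- sc
  }
  structure(list(dx = dx, dy = dy, ddx = diff(dx), ddy = diff(dy),
                 roi = roi, fs = cine$fs, n_pixels = npix),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("<displacement_series> %d frames @ %g Hz, %d roi pixels; |d| max %.3f px\n",
              length(x$dx), x$fs, x$n_pixels, max(sqrt(x$dx^2 + x$dy^2))))
  invisible(x)
}

#' Reduce 2-D displacements to a 1-D pulse-motion signal
#'
#' Projects the mean-centred displacement vectors onto the leading
#' eigenvector of their 2 x 2 covariance matrix.  The axis sign is
#' canonicalized (first nonzero component positive) so the projected
#' signal has a deterministic sign.
#'
#' @param d a [track_region()] result.
#' @param use `"cumulative"` (default; the brain pulse-motion chronometer
#'   M) or `"delta"` (frame-to-frame wall speed, pixels/frame).
#' @param isotropy_tol relative eigenvalue gap below which the axis is
#'   declared ill-defined (default 0.01).
#' @return an object of class `pulse_motion`: `values` (projection,
#'   pixels or pixels/frame), `axis` (unit 2-vector),
#'   `explained_variance_fraction`, `fs`.
#' @export
project_principal <- function(d, use = c("cumulative", "delta"),
                              isotropy_tol = 0.01) {
  stopifnot(inherits(d, "displacement_series"))
  use <- match.arg(use)
  m <- if (use == "cumulative") cbind(d$dx, d$dy) else cbind(d$ddx, d$ddy)
  if (nrow(m) < 3L) abort("need at least 3 displacement samples")
  m <- sweep(m, 2L, colMeans(m))
  cv <- crossprod(m) / (nrow(m) - 1L)
  if (!all(is.finite(cv)) || sum(diag(cv)) == 0)
    abort("degenerate displacement covariance")
  eg <- eigen(cv, symmetric = TRUE)
  if ((eg$values[1] - eg$values[2]) < isotropy_tol * eg$values[1])
    abort("displacement covariance is isotropic; principal axis ill-defined")
  ax <- eg$vectors[, 1]
  nz <- which(abs(ax) > 1e-12)[1]
  if (ax[nz] < 0) ax <- -ax
  structure(list(values = as.numeric(m %*% ax), axis = ax,
                 explained_variance_fraction = eg$values[1] / sum(eg$values),
                 fs = d$fs, use = use),
            class = "pulse_motion")
}

#' @export
print.pulse_motion <- function(x, ...) {
  cat(sprintf("<pulse_motion> %d samples @ %g Hz along (%.3f, %.3f); %.1f%% variance\n",
              length(x$values), x$fs, x$axis[1], x$axis[2],
              100 * x$explained_variance_fraction))
  invisible(x)
}

#' Wall-motion scattergram
#'
#' Plots the magnified displacement endpoints over a background frame with
#' the principal axis drawn as a dashed double arrow, in the style used to
#' visualise ventricle wall excursions (default magnification 500x).
#'
#' @param d a [track_region()] result.
#' @param frame optional background frame (`H x W` matrix) drawn in
#'   grayscale.
#' @param magnification displacement magnification factor (default 500).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list with the plotted endpoint coordinates
#'   (`points`), the `axis` (from [project_principal()]) and the arrow
#'   endpoints (`arrow`).
#' @export
render_scattergram <- function(d, frame = NULL, magnification = 500, ...) {
  stopifnot(inherits(d, "displacement_series"))
  ctr <- colMeans(d$roi)
  mdx <- d$dx - mean(d$dx); mdy <- d$dy - mean(d$dy)
  px <- ctr[1] + magnification * mdx
  py <- ctr[2] + magnification * mdy
  pp <- tryCatch(project_principal(d), error = function(e) NULL)
  arrow <- if (!is.null(pp)) {
    half <- magnification * max(abs(pp$values))
    rbind(ctr - half * pp$axis, ctr + half * pp$axis)
  }
  if (!is.null(frame)) {
    h <- nrow(frame); w <- ncol(frame)
    graphics::plot(NA, xlim = c(0, w - 1), ylim = c(h - 1, 0), asp = 1,
                   xlab = "x (px)", ylab = "y (px)", ...)
    graphics::rasterImage(frame / max(frame, 1e-12), 0, h - 1, w - 1, 0)
  } else {
    graphics::plot(NA, xlim = range(px) + c(-1, 1), ylim = rev(range(py) + c(-1, 1)),
                   asp = 1, xlab = "x (px)", ylab = "y (px)", ...)
  }
  graphics::points(px, py, pch = 16, cex = 0.4, col = "orange")
  if (!is.null(arrow)) {
    graphics::arrows(arrow[1, 1], arrow[1, 2], arrow[2, 1], arrow[2, 2],
                     code = 3, lty = 2, length = 0.08)
  }
  invisible(list(points = cbind(x = px, y = py),
                 axis = if (!is.null(pp)) pp$axis, arrow = arrow))
}
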