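# Peri-ventricular polygon band: segmentation of a traced ventricular
# contour into 30 equal-arc-length segments, construction of the
# contiguous quadrilateral band, per-polygon complex CF series, the
# angiographic time-intensity curve, arterial/venous interval selection,
# and the arterial-venous and dorsal-ventral phase analyses.

# internal: do two open segments properly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# internal: does an open polyline self-intersect?
polyline_simple <- function(xy) {
  k <- nrow(xy) - 1L
  if (k < 3L) return(TRUE)
  for (i in seq_len(k - 2L)) {
    for (j in (i + 2L):k) {
      if (segments_intersect(xy[i, ], xy[i + 1L, ], xy[j, ], xy[j + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

# internal: signed polygon area (shoelace); vertices in order
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Segment a traced ventricular contour into equal arc lengths
#'
#' Divides an open, simple (non-self-intersecting) polyline into
#' `n_segments` segments of equal arc length, preserving a one-to-one
#' correspondence between position along the ventricular perimeter and
#' segment index.
#'
#' @param vertices ordered `k x 2` matrix of contour vertices, columns x
#'   and y, pixel coordinates (0-based, origin top-left, y down).
#' @param n_segments number of segments (default 30).
#' @return an object of class `segmented_contour`: `vertices` (as
#'   supplied), `endpoints` (`(n_segments + 1) x 2` equal-arc-length
#'   points), `seg_length` (common segment length, pixels), `n_segments`.
#' @export
segment_contour <- function(vertices, n_segments = 30L) {
  xy <- as.matrix(vertices)
  if (ncol(xy) != 2L || nrow(xy) < 2L) abort("`vertices` must be a k x 2 matrix with k >= 2")
  if (anyNA(xy)) abort("contour vertices must be finite")
  if (any(xy[1, ] != xy[nrow(xy), ]) == FALSE && nrow(xy) > 2L)
    abort("contour must be open (first and last vertex differ)")
  if (!polyline_simple(xy)) abort("contour must be simple (no self-intersection)")
  rs <- resample_polyline(xy, n = max(20L * n_segments, 600L))
  u <- seq(0, 1, length.out = n_segments + 1L)
  endpoints <- cbind(stats::approx(rs$u, rs$points[, 1], u)$y,
                     stats::approx(rs$u, rs$points[, 2], u)$y)
  colnames(endpoints) <- c("x", "y")
  structure(list(vertices = xy, endpoints = endpoints,
                 seg_length = rs$total / n_segments,
                 total_length = rs$total, n_segments = as.integer(n_segments)),
            class = "segmented_contour")
}

#' @export
print.segmented_contour <- function(x, ...) {
  cat(sprintf("<segmented_contour> %d segments of %.2f px (total %.1f px)\n",
              x$n_segments, x$seg_length, x$total_length))
  invisible(x)
}

# internal: zone labels - ventral at both contour ends, dorsal in the
# middle (segments 1-10 and 21-30 ventral, 11-20 dorsal for n = 30)
zone_labels <- function(n) {
  lo <- floor(n / 3); hi <- ceiling(2 * n / 3)
  z <- rep("ventral", n)
  z[(lo + 1):hi] <- "dorsal"
  z
}

#' Build the peri-ventricular polygon band
#'
#' Offsets the segmented contour by `thickness` along averaged outward
#' vertex normals to produce a band of contiguous quadrilaterals, one per
#' segment, with shared lateral edges.  Zone labels mark the ventral
#' (both contour ends) and dorsal (middle) thirds.
#'
#' @param contour a [segment_contour()] result.
#' @param thickness band thickness in pixels; default one segment length.
#' @param side +1 or -1, selecting which side of the open contour is
#'   "outward" (default +1: the left of the direction of travel, which is
#'   away from the curvature centre for the default synthetic contour).
#' @return an object of class `polygon_band`: `polygons` (list of
#'   `4 x 2` vertex matrices, inner edge first), `inner`, `outer`
#'   (endpoint matrices), `zones` (character vector), `thickness`,
#'   `contour`.
#' @export
build_band <- function(contour, thickness = NULL, side = 1) {
  stopifnot(inherits(contour, "segmented_contour"))
  if (is.null(thickness)) thickness <- contour$seg_length
  if (!is_number(thickness) || thickness <= 0) abort("`thickness` must be > 0")
  ep <- contour$endpoints
  np <- nrow(ep)
  tang <- rbind(ep[2, ] - ep[1, ], ep[-1, ] - ep[-np, ])  # one-sided at start
  tang_next <- rbind(ep[-1, ] - ep[-np, ], ep[np, ] - ep[np - 1, ])
  avg <- tang + tang_next
  avg <- avg / sqrt(rowSums(avg^2))
  nrm <- side * cbind(avg[, 2], -avg[, 1])
  outer_pts <- ep + thickness * nrm
  colnames(outer_pts) <- c("x", "y")
  if (!polyline_simple(outer_pts))
    abort("offset contour self-intersects; the contour is too concave for thickness ",
          signif(thickness, 4))
  n <- contour$n_segments
  polygons <- lapply(seq_len(n), function(i) {
    q <- rbind(ep[i, ], ep[i + 1, ], outer_pts[i + 1, ], outer_pts[i, ])
    rownames(q) <- NULL
    q
  })
  areas <- vapply(polygons, function(q) abs(polygon_area(q)), numeric(1))
  simple <- vapply(polygons, function(q) polyline_simple(rbind(q, q[1, ])), logical(1))
  if (any(areas <= 0) || !all(simple))
    abort("offset produces degenerate polygons; reduce `thickness` or flip `side`")
  structure(list(polygons = polygons, inner = ep, outer = outer_pts,
                 zones = zone_labels(n), thickness = thickness,
                 contour = contour),
            class = "polygon_band")
}

#' @export
print.polygon_band <- function(x, ...) {
  cat(sprintf("<polygon_band> %d quadrilaterals, thickness %.2f px (%d ventral, %d dorsal)\n",
              length(x$polygons), x$thickness,
              sum(x$zones == "ventral"), sum(x$zones == "dorsal")))
  invisible(x)
}

#' @export
plot.polygon_band <- function(x, ...) {
  allpts <- do.call(rbind, x$polygons)
  graphics::plot(NA, xlim = range(allpts[, 1]), ylim = rev(range(allpts[, 2])),
                 asp = 1, xlab = "x (px)", ylab = "y (px)", ...)
  cols <- ifelse(x$zones == "ventral", "orange", "turquoise3")
  for (i in seq_along(x$polygons))
    graphics::polygon(x$polygons[[i]], border = "grey30", col = cols[i])
  invisible(x)
}

#' Pixel mask covering the polygon band
#'
#' Logical `H x W` mask of the pixels whose centers fall inside any band
#' polygon; use it to restrict [cf_angiogram()] to the peri-ventricular
#' region instead of transforming every pixel in the frame.
#'
#' @param band a [build_band()] result.
#' @param dim frame size `c(H, W)`.
#' @return logical matrix.
#' @export
band_mask <- function(band, dim) {
  stopifnot(inherits(band, "polygon_band"))
  mask <- matrix(FALSE, dim[1], dim[2])
  for (q in band$polygons) {
    cols <- max(1L, floor(min(q[, 1])) + 1L):min(dim[2], ceiling(max(q[, 1])) + 1L)
    rows <- max(1L, floor(min(q[, 2])) + 1L):min(dim[1], ceiling(max(q[, 2])) + 1L)
    pts <- cbind(rep(cols - 1L, each = length(rows)),
                 rep(rows - 1L, times = length(cols)))
    inside <- point_in_polygon(pts, q)
    mask[rows, cols] <- mask[rows, cols] | matrix(inside, length(rows), length(cols))
  }
  mask
}

# internal: assign pixel centers of a field to polygons; first containing
# polygon wins (deterministic tie-break towards the lower index).
# Returns a list of field-row index vectors, one per polygon.
assign_pixels <- function(field, band) {
  lookup <- matrix(NA_integer_, field$dim[1], field$dim[2])
  lookup[field$pixels] <- seq_len(nrow(field$pixels))
  taken <- rep(FALSE, nrow(field$pixels))
  members <- vector("list", length(band$polygons))
  for (i in seq_along(band$polygons)) {
    q <- band$polygons[[i]]
    cols <- max(1L, floor(min(q[, 1])) + 1L):min(field$dim[2], ceiling(max(q[, 1])) + 1L)
    rows <- max(1L, floor(min(q[, 2])) + 1L):min(field$dim[1], ceiling(max(q[, 2])) + 1L)
    cand <- as.vector(lookup[rows, cols])
    cand <- cand[!is.na(cand)]
    cand <- cand[!taken[cand]]
    if (!length(cand)) { members[[i]] <- integer(0); next }
    # pixel centers in 0-based coordinates: (col - 1, row - 1)
    pts <- cbind(field$pixels[cand, 2] - 1, field$pixels[cand, 1] - 1)
    inside <- point_in_polygon(pts, q)
    members[[i]] <- cand[inside]
    taken[members[[i]]] <- TRUE
  }
  members
}

#' Per-polygon complex CF band series
#'
#' For each band polygon and time sample, the arithmetic mean (not the
#' sum: polygon areas are unequal) of the complex CF field over the
#' pixels whose centers fall inside the polygon.
#'
#' @param field a [cf_angiogram()] result covering the band's pixels.
#' @param band a [build_band()] result.
#' @return an object of class `band_series`: complex matrix `values`
#'   (`n_segments x T`), `n_pixels` per polygon, `zones`, `fs`,
#'   `cf_band`, `reference`.
#' @export
band_signal <- function(field, band) {
  stopifnot(inherits(field, "cf_field"), inherits(band, "polygon_band"))
  members <- assign_pixels(field, band)
  npx <- lengths(members)
  if (any(npx == 0L))
    abort("polygon(s) ", paste(which(npx == 0L), collapse = ", "),
          " contain no pixel centers")
  values <- t(vapply(members, function(idx) {
    if (length(idx) == 1L) field$values[idx, ]
    else colMeans(field$values[idx, , drop = FALSE])
  }, complex(ncol(field$values))))
  structure(list(values = values, n_pixels = npx, zones = band$zones,
                 fs = field$fs, cf_band = field$band,
                 reference = field$reference),
            class = "band_series")
}

#' @export
print.band_series <- function(x, ...) {
  cat(sprintf("<band_series> %d polygons x %d samples @ %g Hz (%s-referenced)\n",
              nrow(x$values), ncol(x$values), x$fs, x$reference))
  invisible(x)
}

#' Unfolded pulse-wave profile
#'
#' Renders the band series as the unfolded space-time profile: segment
#' index down the vertical axis (ventral-dorsal-ventral), time along the
#' horizontal, brightness the CF magnitude (99th-percentile normalised)
#' and hue the CF phase.  Zone color keys (orange ventral, turquoise
#' dorsal) are drawn in the margin.
#'
#' @param x a [band_signal()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the color matrix (`n_segments x T`) that was drawn.
#' @export
plot.band_series <- function(x, ...) {
  colors <- complex_raster(x$values)
  n <- nrow(x$values); nt <- ncol(x$values)
  graphics::plot(NA, xlim = c(0, nt / x$fs), ylim = c(n + 0.5, 0.5),
                 xlab = "time (s)", ylab = "segment", ...)
  graphics::rasterImage(grDevices::as.raster(colors), 0, n + 0.5, nt / x$fs, 0.5,
                        interpolate = FALSE)
  key <- ifelse(x$zones == "ventral", "orange", "turquoise3")
  graphics::points(rep(-0.01 * nt / x$fs, n), seq_len(n), col = key, pch = 15,
                   cex = 0.7, xpd = NA)
  invisible(colors)
}

#' Angiographic time-intensity curve over the band
#'
#' Mean raw cine intensity across all band pixels, per frame, with a
#' smoothed copy (moving average over one cardiac period) for peak
#' finding.
#'
#' @param cine a [cine_sequence()].
#' @param band a [build_band()] result.
#' @param cardiac_freq cardiac frequency (Hz) defining the smoothing
#'   window; `NULL` for no smoothing.
#' @return an object of class `tic`: `time`, `intensity`, `smooth`, `fs`.
#' @export
time_intensity_curve <- function(cine, band, cardiac_freq = NULL) {
  stopifnot(inherits(cine, "cine_sequence"), inherits(band, "polygon_band"))
  d <- dim(cine$frames)
  allq <- do.call(rbind, band$polygons)
  cols <- max(1L, floor(min(allq[, 1])) + 1L):min(d[2], ceiling(max(allq[, 1])) + 1L)
  rows <- max(1L, floor(min(allq[, 2])) + 1L):min(d[1], ceiling(max(allq[, 2])) + 1L)
  pts <- cbind(rep(cols - 1L, each = length(rows)), rep(rows - 1L, times = length(cols)))
  inside <- rep(FALSE, nrow(pts))
  for (q in band$polygons) inside <- inside | point_in_polygon(pts, q)
  if (!any(inside)) abort("band contains no pixels")
  X <- matrix(cine$frames[rows, cols, ], length(rows) * length(cols), d[3])
  tic <- colMeans(X[inside, , drop = FALSE])
  smooth <- tic
  if (!is.null(cardiac_freq)) {
    k <- max(1L, round(cine$fs / cardiac_freq))
    if (k %% 2L == 0L) k <- k + 1L
    smooth <- stats::filter(tic, rep(1 / k, k), sides = 2)
    smooth <- as.numeric(smooth)
    # shrink the window near the edges instead of returning NA
    half <- (k - 1L) %/% 2L
    for (i in which(is.na(smooth)))
      smooth[i] <- mean(tic[max(1L, i - half):min(length(tic), i + half)])
  }
  structure(list(time = (seq_len(d[3]) - 1) / cine$fs, intensity = tic,
                 smooth = smooth, fs = cine$fs),
            class = "tic")
}

#' @export
plot.tic <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "l", col = "grey60",
                 xlab = "time (s)", ylab = "mean intensity", ...)
  graphics::lines(x$time, x$smooth, lwd = 2)
  invisible(x)
}

#' Select arterial and venous intervals from the time-intensity curve
#'
#' The arterial interval is `n_beats` cardiac periods of bolus inflow
#' ending shortly before the smoothed-TIC peak; the venous interval is
#' the same length placed after the peak.  A guard gap of several beats
#' on the venous side keeps it clear of the arterial first pass, which
#' takes a couple of seconds to wash out after the peak while the
#' dispersed venous outflow builds up.  Both intervals must also clear
#' the edge-effect margin of the wavelet analysis.
#'
#' @param tic a [time_intensity_curve()] result.
#' @param cardiac_freq cardiac frequency, Hz.
#' @param n_beats interval length in heart beats (default 5).
#' @param gap_beats guard gaps in heart beats, `c(arterial, venous)`
#'   (default `c(0, 6)`: none on the arterial side, where the venous
#'   envelope has not yet arrived, and six beats on the venous side).
#' @param edge_margin seconds to keep clear of the record edges; default
#'   one e-folding time of the analysis band's largest scale.
#' @return list with `arterial` and `venous`, each `c(start, end)` in
#'   seconds, and `peak_time`.
#' @export
select_av_intervals <- function(tic, cardiac_freq, n_beats = 5,
                                gap_beats = c(0, 6), edge_margin = NULL) {
  stopifnot(inherits(tic, "tic"))
  if (is.null(edge_margin)) {
    b <- cf_band(cardiac_freq)
    edge_margin <- sqrt(2) * max(spec_scales(wavelet_spec(6), b$freqs))
  }
  gap_beats <- rep_len(gap_beats, 2L)
  dur <- max(tic$time)
  peak_time <- tic$time[which.max(tic$smooth)]
  len <- n_beats / cardiac_freq
  gap <- gap_beats / cardiac_freq
  arterial <- c(peak_time - gap[1] - len, peak_time - gap[1])
  venous <- c(peak_time + gap[2], peak_time + gap[2] + len)
  if (arterial[1] < edge_margin || venous[2] > dur - edge_margin)
    abort("recording too short for ", n_beats,
          "-beat arterial and venous intervals around the peak at ",
          signif(peak_time, 4), " s")
  list(arterial = arterial, venous = venous, peak_time = peak_time)
}

#' Arterial versus venous pulse-wave phase
#'
#' Averages the motion-referenced complex CF data of each band polygon
#' over the arterial and venous intervals; the phases of these averages
#' form two circular samples of `n_segments` angles each, summarised by
#' circular mean and SD and compared by Watson's two-sample test.
#'
#' @param bs a [band_signal()] result, built with the pulse-motion
#'   reference.
#' @param intervals a [select_av_intervals()] result.
#' @param n_permutations permutations for the Watson two-sample p-value.
#' @return an object of class `av_phase`: `arterial`, `venous` (circular
#'   sample vectors, radians), `summary_arterial`, `summary_venous`
#'   ([circ_summary()]), `watson` ([watson_two_sample()]).
#' @export
av_phase <- function(bs, intervals, n_permutations = 1e4) {
  stopifnot(inherits(bs, "band_series"))
  if (!identical(bs$reference, "motion"))
    abort("`bs` must be motion-referenced (build the field with `motion = `)")
  nt <- ncol(bs$values)
  idx <- function(iv) {
    i <- which((seq_len(nt) - 1) / bs$fs >= iv[1] & (seq_len(nt) - 1) / bs$fs <= iv[2])
    if (length(i) < 2L) abort("interval [", iv[1], ", ", iv[2], "] s lies outside the series")
    i
  }
  mean_phase <- function(i) {
    z <- rowMeans(bs$values[, i, drop = FALSE])
    if (all(Mod(z) < 1e-300)) abort("zero-magnitude band data; phase undefined")
    wrap_angle(Arg(z))
  }
  arterial <- mean_phase(idx(intervals$arterial))
  venous <- mean_phase(idx(intervals$venous))
  structure(list(arterial = arterial, venous = venous,
                 summary_arterial = circ_summary(arterial),
                 summary_venous = circ_summary(venous),
                 watson = watson_two_sample(arterial, venous,
                                            n_permutations = n_permutations)),
            class = "av_phase")
}

#' @export
print.av_phase <- function(x, ...) {
  cat("Arterial vs venous pulse-wave phase (relative to brain pulse motion)\n")
  cat(sprintf("  arterial: mean %.3f rad, sd %.3f rad (n = %d)\n",
              x$summary_arterial$mean, x$summary_arterial$sd, x$summary_arterial$n))
  cat(sprintf("  venous:   mean %.3f rad, sd %.3f rad (n = %d)\n",
              x$summary_venous$mean, x$summary_venous$sd, x$summary_venous$n))
  cat(sprintf("  Watson two-sample U2 = %.4f, permutation p %s\n",
              x$watson$statistic,
              format.pval(x$watson$p_value, digits = 3)))
  invisible(x)
}

#' Dorsal-ventral pulse-wave phase relationship
#'
#' Averages the complex band series separately over the dorsal and
#' ventral zone polygons to give the zone signals V_Dorsal and V_Ventral,
#' then forms the per-time dorsal-minus-ventral arrival-phase difference
#' from their conjugate product.  Positive values mean the pulse wave
#' reaches the ventral zone first (the dorsal zone lags), matching the
#' convention in which a ventral-to-dorsal traveling wave has positive
#' dorsoventral phase.  Valid interior samples are pooled into a circular
#' summary and tested against zero with Watson's one-sample test.
#'
#' @param bs a [band_signal()] result (motion-referenced).
#' @param efolds cone-of-influence margin, in e-folding times.
#' @param power_floor fraction of each zone's 90th-percentile magnitude
#'   below which a sample is discarded (default 0.5).  Phase is pooled
#'   only over the strong-magnitude support of the bolus passage; weak
#'   samples (bolus onset and washout transients, background) carry
#'   envelope-leakage phase rather than pulse-wave phase.
#' @return an object of class `dorsoventral_phase`: `v_dorsal`,
#'   `v_ventral` (complex zone series), `phase` (per-time difference,
#'   radians), `valid`, `summary` ([circ_summary()] of the valid
#'   samples), `watson` ([watson_one_sample()] against 0).
#' @export
dorsoventral_phase <- function(bs, efolds = 1, power_floor = 0.5) {
  stopifnot(inherits(bs, "band_series"))
  dorsal <- bs$zones == "dorsal"
  if (!any(dorsal) || all(dorsal)) abort("zone labels must include both zones")
  v_d <- colMeans(bs$values[dorsal, , drop = FALSE])
  v_v <- colMeans(bs$values[!dorsal, , drop = FALSE])
  nt <- length(v_d)
  coi <- coi_valid(nt, bs$fs, bs$cf_band)
  scale_ref <- min(stats::quantile(Mod(v_d)[coi], 0.9, names = FALSE),
                   stats::quantile(Mod(v_v)[coi], 0.9, names = FALSE))
  if (mean(Mod(v_d)[coi] < 1e-12 * scale_ref | Mod(v_v)[coi] < 1e-12) > 0.5 ||
      scale_ref <= 0)
    abort("zone magnitude is zero at more than half of the samples")
  ok <- Mod(v_d) > power_floor * scale_ref & Mod(v_v) > power_floor * scale_ref
  valid <- coi & ok
  if (sum(valid) < 10L) abort("fewer than 10 valid interior samples")
  # arrival-phase difference: theta_ventral - theta_dorsal in phasor terms
  # equals the dorsal arrival lag minus the ventral arrival lag
  phase <- wrap_angle(Arg(v_v * Conj(v_d)))
  smry <- circ_summary(phase[valid])
  structure(list(v_dorsal = v_d, v_ventral = v_v, phase = phase,
                 valid = valid, summary = smry,
                 watson = watson_one_sample(phase[valid], 0)),
            class = "dorsoventral_phase")
}

#' @export
print.dorsoventral_phase <- function(x, ...) {
  cat("Dorsal-minus-ventral CF pulse-wave phase\n")
  cat(sprintf("  pooled mean %.3f rad, sd %.3f rad over %d valid samples\n",
              x$summary$mean, x$summary$sd, x$summary$n))
  cat(sprintf("  Watson one-sample test vs 0 rad: p %s\n",
              format.pval(x$watson$p_value, digits = 3)))
  if (x$summary$mean > 0)
    cat("  (positive: the wave reaches the ventral zone first)\n")
  invisible(x)
}
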