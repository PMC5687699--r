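# Synthetic cine and physiology generators with known cardiac-frequency
# phase structure.  Every downstream stage of the package is validated by
# recovering the phase parameters these generators inject.
#
# Phase bookkeeping: a component written cos(2*pi*f*t + theta) carries
# phasor angle theta.  A larger theta peaks earlier ("leads").  All
# ground-truth offsets below are phasor-angle differences, matching the
# phase returned by the wavelet analysis chain.

# internal: run expr with a private RNG stream, restoring caller state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
  }
  force(expr)
}

#' Cine image sequence
#'
#' Time-ordered grayscale frame stack with its sampling rate.  Frames are
#' stored as an `H x W x T` array of non-negative intensities; each pixel
#' is a time signal at its spatial location.
#'
#' @param frames numeric `H x W x T` array, finite and >= 0.
#' @param fs frame rate in Hz.
#' @param pixel_size optional pixel edge length in mm.
#' @return an object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, fs, pixel_size = NULL) {
  d <- dim(frames)
  if (length(d) != 3L || d[3] < 2L) abort("`frames` must be an H x W x T array with T >= 2")
  if (!is_number(fs) || fs <= 0) abort("`fs` must be a positive frame rate")
  if (anyNA(frames) || !all(is.finite(frames)) || any(frames < 0))
    abort("frame intensities must be finite and non-negative")
  structure(list(frames = frames, fs = fs, pixel_size = pixel_size),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence> %d x %d pixels, %d frames @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$fs, d[3] / x$fs))
  invisible(x)
}

#' Uniformly sampled 1-D trace
#'
#' Minimal container pairing a numeric series with its sampling rate; used
#' for pulse-motion and pressure traces in clock alignment.
#'
#' @param values numeric vector.
#' @param fs sampling rate in Hz.
#' @return an object of class `pw_trace`.
#' @export
pw_trace <- function(values, fs) {
  if (!is_number(fs) || fs <= 0) abort("`fs` must be a positive sampling rate")
  structure(list(values = as.numeric(values), fs = fs), class = "pw_trace")
}

# internal: default open ventricular contour - a semicircular arc with its
# apex dorsal (towards the top of the frame) and both ends ventral, so the
# band's zone layout (ends ventral, middle dorsal) matches the 1-10/21-30
# vs 11-20 segment convention.  Coordinates are (x, y), y down, 0-based.
default_contour <- function(dim) {
  h <- dim[1]; w <- dim[2]
  r <- 0.32 * min(h, w)
  cx <- (w - 1) / 2; cy <- 0.58 * (h - 1)
  ang <- seq(pi, 0, length.out = 181)
  cbind(x = cx + r * cos(ang), y = cy - r * sin(ang))
}

# internal: gamma-variate bolus envelope, unit peak at t0 + alpha*beta
gamma_variate <- function(t, t0, alpha, beta) {
  u <- (t - t0) / beta
  env <- ifelse(u > 0, (u / alpha)^alpha * exp(alpha - u), 0)
  env[!is.finite(env)] <- 0
  env
}

# internal: resample a polyline by arc length; returns points and their
# normalized arc-length parameter u in [0, 1]
resample_polyline <- function(xy, n = 600L) {
  seg <- sqrt(rowSums(diff(xy)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) abort("contour has zero length")
  s <- seq(0, total, length.out = n)
  list(points = cbind(stats::approx(cum, xy[, 1], s)$y,
                      stats::approx(cum, xy[, 2], s)$y),
       u = s / total, total = total)
}

# internal: for query points (m x 2), nearest point index on a resampled
# contour; chunked to bound memory
nearest_on_contour <- function(pts, contour_pts) {
  m <- nrow(pts)
  idx <- integer(m)
  dist <- numeric(m)
  step <- max(1L, floor(2e6 / nrow(contour_pts)))
  for (start in seq(1L, m, by = step)) {
    i <- start:min(start + step - 1L, m)
    d2 <- outer(pts[i, 1], contour_pts[, 1], "-")^2 +
          outer(pts[i, 2], contour_pts[, 2], "-")^2
    idx[i] <- max.col(-d2, ties.method = "first")
    dist[i] <- sqrt(d2[cbind(seq_along(i), idx[i])])
  }
  list(index = idx, dist = dist)
}

#' Generate a synthetic angiographic cine with known CF phase structure
#'
#' Emulates contrast-bolus cine imaging of the peri-ventricular region: a
#' gamma-variate bolus envelope modulated at the cardiac frequency, with
#' distinct arterial and venous compartments (the venous envelope trails
#' the arterial by a transit delay), a configurable ventral-to-dorsal
#' phase gradient along a ventricular contour, a deterministic oscillating
#' bright blob for motion tracking, and additive Gaussian noise.
#'
#' Compartment pixels carry the signal
#' `background + A(t) * (1 + m * cos(2*pi*f_c*t + theta(x, y)))` with
#' `theta = motion_phase + compartment_offset + gradient_profile(u)`,
#' where `u` is the pixel's arc-length position along the contour and the
#' gradient profile falls linearly from 0 at the ventral ends to
#' `-ventral_dorsal_gradient` at the dorsal midpoint (so the ventral zone
#' leads the dorsal zone by the configured gradient).
#'
#' @param dim frame size `c(H, W)` in pixels.
#' @param fs frame rate, Hz.
#' @param duration recording length, seconds.
#' @param cardiac_freq cardiac frequency, Hz (must be below `fs/2`).
#' @param bolus list with `t0` (appearance time, s), `alpha`, `beta`
#'   (gamma-variate shape/scale) and `amplitude`.  Defaults place the
#'   arterial peak near mid-recording.
#' @param arterial_offset,venous_offset compartment CF phasor angle minus
#'   the pulse-motion phasor angle, radians in (-pi, pi].
#' @param ventral_dorsal_gradient phase lead of the ventral over the
#'   dorsal contour zone, radians in (-pi, pi].
#' @param contour open polyline (`n x 2`, columns x and y in pixel
#'   coordinates, y down) tracing the ventricular surface; default a
#'   semicircular arc with dorsal apex.
#' @param band_width width of the vascular band around the contour,
#'   pixels; default one thirtieth of the contour length.
#' @param venous_delay venous envelope transit delay, seconds (default
#'   five cardiac periods, the cerebral arteriovenous transit scale).
#' @param modulation fractional CF modulation depth of the envelope.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param background baseline intensity.
#' @param blob list with `center` (x, y), `sigma`, `amplitude`,
#'   `motion_amp` (pixels), `axis` (unit 2-vector) and `phase` for the
#'   trackable oscillating object; default placed in the lower left
#'   quadrant away from the band.
#' @param arterial_mask,venous_mask optional logical `H x W` masks
#'   overriding the default inner/outer split of the band; must not
#'   overlap.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return list with `cine` (a [cine_sequence()]), `truth` (class
#'   `cine_ground_truth`: the configured parameters, compartment masks,
#'   bolus peak time, contour, and the noise-free pulse-motion reference
#'   as a [pw_trace()]), and `blob_roi` (a rectangle polygon around the
#'   trackable object, for [track_region()]).
#' @export
generate_cine <- function(dim = c(128, 128), fs = 30, duration = 20,
                          cardiac_freq = 2.5,
                          bolus = list(),
                          arterial_offset = 0.5, venous_offset = -0.5,
                          ventral_dorsal_gradient = 0.7,
                          contour = NULL, band_width = NULL,
                          venous_delay = 5 / cardiac_freq,
                          modulation = 0.2, noise_sd = 2,
                          background = 10, blob = list(),
                          arterial_mask = NULL, venous_mask = NULL,
                          seed = 1L) {
  if (length(dim) != 2L || any(dim < 8) || any(dim != round(dim)))
    abort("`dim` must be two positive integers (H, W)")
  if (!is_number(cardiac_freq) || cardiac_freq >= fs / 2)
    abort("`cardiac_freq` must be below the Nyquist frequency fs/2")
  if (duration * cardiac_freq < 10)
    abort("recording must span at least 10 cardiac periods")
  for (p in c(arterial_offset, venous_offset, ventral_dorsal_gradient))
    if (!is_number(p) || p <= -pi || p > pi)
      abort("phase offsets must lie in (-pi, pi]")
  h <- dim[1]; w <- dim[2]
  nt <- round(duration * fs)
  t <- (seq_len(nt) - 1) / fs

  if (is.null(contour)) contour <- default_contour(dim)
  rs <- resample_polyline(as.matrix(contour))
  if (is.null(band_width)) band_width <- rs$total / 30

  # sharp first-pass arterial bolus peaking just before mid-recording; the
  # venous envelope is the arterial one delayed by the arteriovenous
  # transit time and dispersed by capillary transit (3x wider, smaller
  # peak), which keeps the combined time-intensity curve single-peaked
  bol <- utils::modifyList(
    list(t0 = 0.45 * duration, alpha = 6, beta = 1 / 3, amplitude = 100,
         venous_dispersion = 2, venous_fraction = 0.85),
    bolus)
  if (bol$t0 + bol$alpha * bol$beta >= duration)
    abort("bolus peak time must fall inside the recording")

  # pixel grid (x = col, y = row, 0-based)
  px <- cbind(x = rep(0:(w - 1), each = h), y = rep(0:(h - 1), times = w))
  near <- nearest_on_contour(px, rs$points)

  if (is.null(arterial_mask) != is.null(venous_mask))
    abort("supply both `arterial_mask` and `venous_mask`, or neither")
  if (is.null(arterial_mask)) {
    # vascular band on the outward (peri-ventricular) side of the contour,
    # matching the side build_band() offsets to: arterial vessels in the
    # inner half of the band, venous in the outer half
    tang <- rbind(rs$points[2, ] - rs$points[1, ], diff(rs$points))
    tang <- tang / sqrt(rowSums(tang^2))
    nrm <- cbind(tang[, 2], -tang[, 1])
    side <- rowSums((px - rs$points[near$index, , drop = FALSE]) *
                      nrm[near$index, , drop = FALSE])
    in_band <- side >= 0 & near$dist <= band_width
    amask <- matrix(in_band & side <= band_width / 2, h, w)
    vmask <- matrix(in_band & side > band_width / 2, h, w)
  } else {
    amask <- arterial_mask; vmask <- venous_mask
    if (any(amask & vmask)) abort("arterial and venous masks must not overlap")
  }
  if (any(amask & vmask)) abort("arterial and venous masks must not overlap")

  blob <- utils::modifyList(
    list(center = NULL, sigma = 2.5, amplitude = 120,
         motion_amp = 0.4, axis = c(1, 0), phase = 0), blob)
  blob$axis <- blob$axis / sqrt(sum(blob$axis^2))
  roi_half <- ceiling(3 * blob$sigma + blob$motion_amp + 2)
  if (is.null(blob$center)) {
    clamp <- function(v, n) min(max(v, roi_half + 6), n - 1 - roi_half - 6)
    blob$center <- c(clamp(0.2 * w, w), clamp(0.75 * h, h))
  }

  omega <- 2 * pi * cardiac_freq
  env_a <- bol$amplitude * gamma_variate(t, bol$t0, bol$alpha, bol$beta)
  env_v <- bol$venous_fraction * bol$amplitude *
    gamma_variate(t, bol$t0 + venous_delay, bol$alpha,
                  bol$beta * bol$venous_dispersion)
  # ground-truth TIC peak: pixel-count-weighted combined envelope maximum
  n_art <- sum(amask); n_ven <- sum(vmask)
  peak_time <- if (n_art + n_ven > 0)
    t[which.max(n_art * env_a + n_ven * env_v)] else bol$t0 + bol$alpha * bol$beta
  carrier_c <- cos(omega * t); carrier_s <- sin(omega * t)

  # Phase profile along the contour: ventral plateaus at the two ends,
  # dorsal plateau in the middle third, linear interpolation across a
  # 2-segment-wide transition at each zone boundary.  The configured
  # gradient is the ventral-vs-dorsal ZONE-mean contrast; plateaus make
  # that contrast insensitive to how pixel magnitude is distributed
  # along the band, and the amplitude is scaled so the zone means differ
  # by exactly the configured value.
  # transition half-width gw/2 in u on each side of the zone boundaries;
  # zone-mean contrast of the profile = 1 - 1.125*gw, compensated below
  gw <- 1 / 15
  gscale <- 1 / (1 - 1.125 * gw)
  grad_profile <- function(u) {
    s <- pmin(1, pmax(0, (abs(2 * u - 1) - (1 / 3 - gw)) / (2 * gw)))
    -gscale * ventral_dorsal_gradient * (1 - s)
  }

  frames <- array(background, c(h, w, nt))
  add_compartment <- function(mask, offset, env) {
    sel <- which(mask)
    if (!length(sel)) return()
    theta <- blob$phase + offset + grad_profile(rs$u[near$index[sel]])
    # basis decomposition: env + m*env*(cos(theta)cos(wt) - sin(theta)sin(wt))
    basis <- rbind(env, modulation * env * carrier_c, -modulation * env * carrier_s)
    coef <- cbind(1, cos(theta), sin(theta))
    vals <- coef %*% basis                       # |sel| x nt
    idx <- rep(sel, nt) + rep((seq_len(nt) - 1L) * h * w, each = length(sel))
    frames[idx] <<- frames[idx] + as.vector(vals)
  }
  add_compartment(amask, arterial_offset, env_a)
  add_compartment(vmask, venous_offset, env_v)

  # oscillating trackable blob, in phase with the returned motion reference
  disp <- blob$motion_amp * cos(omega * t + blob$phase)
  win <- ceiling(4 * blob$sigma + blob$motion_amp + 1)
  bx <- blob$center[1]; by <- blob$center[2]
  cols <- max(0, floor(bx - win)):min(w - 1, ceiling(bx + win))
  rows <- max(0, floor(by - win)):min(h - 1, ceiling(by + win))
  for (k in seq_len(nt)) {
    cxk <- bx + disp[k] * blob$axis[1]
    cyk <- by + disp[k] * blob$axis[2]
    g <- blob$amplitude *
      exp(-(outer((rows - cyk)^2, (cols - cxk)^2, "+")) / (2 * blob$sigma^2))
    frames[rows + 1L, cols + 1L, k] <- frames[rows + 1L, cols + 1L, k] + g
  }

  frames <- with_seed(seed, {
    if (noise_sd > 0) frames <- frames + stats::rnorm(length(frames), 0, noise_sd)
    frames
  })
  frames[frames < 0] <- 0

  compartments <- matrix("background", h, w)
  compartments[amask] <- "arterial"
  compartments[vmask] <- "venous"

  truth <- structure(list(
    cardiac_freq = cardiac_freq,
    arterial_phase_offset = wrap_angle(arterial_offset),
    venous_phase_offset = wrap_angle(venous_offset),
    ventral_dorsal_gradient = wrap_angle(ventral_dorsal_gradient),
    bolus_peak_time = peak_time,
    compartment_masks = compartments,
    contour = rs$points[seq(1, nrow(rs$points), length.out = 61), ],
    band_width = band_width,
    motion_reference = pw_trace(disp, fs),
    motion_axis = blob$axis,
    modulation = modulation
  ), class = "cine_ground_truth")

  blob_roi <- cbind(x = bx + c(-1, 1, 1, -1) * roi_half,
                    y = by + c(-1, -1, 1, 1) * roi_half)

  list(cine = cine_sequence(frames, fs), truth = truth, blob_roi = blob_roi)
}

#' Physiological waveform record
#'
#' Uniformly sampled multichannel waveform table: CSF pressure, arterial
#' blood pressure and ECG, with a recording-site label and epoch metadata.
#'
#' @param time numeric vector of sample times, seconds, uniformly spaced.
#' @param csf_mmHg,abp_mmHg,ecg_au channel vectors matching `time`.
#' @param site one of `"lateral_ventricle"` (dorsal) or
#'   `"third_ventricle"` (ventral).
#' @param interpolated optional logical vector flagging gap-filled samples.
#' @return an object of class `physiology_record` (a data frame with
#'   attributes `fs`, `site`, `epoch_start`).
#' @export
physiology_record <- function(time, csf_mmHg, abp_mmHg, ecg_au,
                              site = c("lateral_ventricle", "third_ventricle"),
                              interpolated = NULL) {
  site <- match.arg(site)
  n <- length(time)
  if (n < 2L) abort("record must contain at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) abort("`time` must be strictly increasing")
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
    abort("sampling must be uniform (jitter below 1% of the interval)")
  rec <- data.frame(time_s = time, csf_mmHg = csf_mmHg,
                    abp_mmHg = abp_mmHg, ecg_au = ecg_au)
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  attr(rec, "fs") <- 1 / stats::median(dt)
  attr(rec, "site") <- site
  attr(rec, "epoch_start") <- time[1]
  attr(rec, "interpolated") <- interpolated
  class(rec) <- c("physiology_record", "data.frame")
  rec
}

#' @export
print.physiology_record <- function(x, ...) {
  cat(sprintf("<physiology_record> %s: %d samples @ %g Hz, epoch start %.2f s\n",
              attr(x, "site"), nrow(x), attr(x, "fs"), attr(x, "epoch_start")))
  invisible(x)
}

#' Generate paired CSF-pressure records with a known inter-site phase lag
#'
#' Emulates the intra-operative physiology acquisition: CSF pressure at a
#' ventral (Third Ventricle) and a dorsal (Lateral Ventricle) site,
#' recorded as separate epochs minutes apart, each with concurrent ABP and
#' ECG references driven by a common cardiac clock.  The dorsal site's CF
#' pressure component is delayed by `site_phase_lag` radians relative to
#' the ventral site (positive lag = ventral leads), which is what the
#' cross-wavelet pipeline must recover as the dorsal-minus-ventral phase.
#'
#' @param fs sampling rate, Hz.
#' @param duration epoch length, seconds.
#' @param cardiac_freq,respiratory_freq component frequencies, Hz; both
#'   must be below Nyquist and distinct.
#' @param site_phase_lag dorsal-minus-ventral CF phase lag, radians in
#'   (-pi, pi].
#' @param amplitudes list overriding component amplitudes: `csf_base`,
#'   `csf_cf`, `csf_resp` (mmHg), `abp_base`, `abp_cf` (mmHg), `ecg`
#'   (a.u.).
#' @param noise_sd additive Gaussian noise SD (mmHg / a.u.).
#' @param epoch_starts start times (s) of the ventral and dorsal epochs on
#'   the shared absolute clock; distinct by default so that cardiac
#'   synchronization is actually exercised.
#' @param csf_phasor phasor angle of the ventral CSF CF component at
#'   absolute time 0 (radians); arbitrary, cancels in differencing.
#' @param seed integer RNG seed.
#' @return list with `ventral` and `dorsal` ([physiology_record()]s) and
#'   `truth` (class `physio_ground_truth`).
#' @export
generate_physio <- function(fs = 100, duration = 20, cardiac_freq = 1.2,
                            respiratory_freq = 0.25, site_phase_lag = 0.8,
                            amplitudes = list(), noise_sd = 0.1,
                            epoch_starts = c(0, 153.2), csf_phasor = 0.4,
                            seed = 1L) {
  if (!is_number(site_phase_lag) || site_phase_lag <= -pi || site_phase_lag > pi)
    abort("`site_phase_lag` must lie in (-pi, pi]")
  if (cardiac_freq >= fs / 2 || respiratory_freq >= fs / 2)
    abort("component frequencies must be below the Nyquist frequency")
  if (abs(cardiac_freq - respiratory_freq) < 1e-6)
    abort("cardiac and respiratory frequencies must be distinct")
  amp <- utils::modifyList(
    list(csf_base = 10, csf_cf = 2, csf_resp = 1,
         abp_base = 80, abp_cf = 40, ecg = 1), amplitudes)
  omega <- 2 * pi * cardiac_freq

  make_epoch <- function(t0, theta_csf, site) {
    t <- t0 + (seq_len(round(duration * fs)) - 1) / fs
    # ECG: narrow Gaussian pulse train at the cardiac frequency; its CF
    # fundamental has phasor angle 0 on the absolute clock
    beat_phase <- (t * cardiac_freq) %% 1
    beat_dist <- pmin(beat_phase, 1 - beat_phase) / cardiac_freq
    ecg <- amp$ecg * exp(-beat_dist^2 / (2 * 0.02^2))
    csf <- amp$csf_base + amp$csf_resp * sin(2 * pi * respiratory_freq * t) +
      amp$csf_cf * cos(omega * t + theta_csf)
    abp <- amp$abp_base + amp$abp_cf * cos(omega * t - 0.3) +
      2 * sin(2 * pi * respiratory_freq * t)
    list(t = t, csf = csf, abp = abp, ecg = ecg, site = site)
  }
  ev <- make_epoch(epoch_starts[1], csf_phasor, "third_ventricle")
  ed <- make_epoch(epoch_starts[2], csf_phasor - site_phase_lag, "lateral_ventricle")

  recs <- with_seed(seed, {
    lapply(list(ev, ed), function(e) {
      n <- length(e$t)
      physiology_record(e$t,
                        e$csf + stats::rnorm(n, 0, noise_sd),
                        e$abp + stats::rnorm(n, 0, noise_sd),
                        e$ecg + stats::rnorm(n, 0, noise_sd / 4),
                        site = e$site)
    })
  })

  truth <- structure(list(cardiac_freq = cardiac_freq,
                          site_phase_lag = wrap_angle(site_phase_lag),
                          clock_offset = 0,
                          flick_time = NA_real_,
                          epoch_starts = epoch_starts),
                     class = "physio_ground_truth")
  list(ventral = recs[[1]], dorsal = recs[[2]], truth = truth)
}

#' Generate a synchronized motion/pressure pair with a finger-flick transient
#'
#' Emulates the deliberate catheter tap used to align the unsynchronized
#' video and pressure clocks: the motion trace (video clock) carries a
#' step-plus-decay transient at `flick_time`, the pressure trace (pressure
#' clock) a sharp spike at `flick_time + clock_offset`; both ride on a
#' cardiac-frequency background plus noise.
#'
#' @param frame_rate video sampling rate, Hz.
#' @param pressure_rate pressure sampling rate, Hz.
#' @param duration trace length, seconds (both clocks).
#' @param clock_offset pressure-clock reading minus video-clock reading of
#'   the same physical event, seconds.
#' @param flick_time flick time on the video clock, seconds.
#' @param cardiac_freq background CF oscillation frequency, Hz.
#' @param flick_amp transient amplitude as a multiple of the CF background
#'   amplitude (set to 0 to produce a degenerate no-transient pair).
#' @param noise_sd additive Gaussian noise SD relative to the CF amplitude.
#' @param seed integer RNG seed.
#' @return list with `motion` and `pressure` ([pw_trace()]s) and `truth`
#'   (class `physio_ground_truth` carrying `clock_offset` and `flick_time`).
#' @export
generate_flick_pair <- function(frame_rate = 30, pressure_rate = 100,
                                duration = 30, clock_offset = 2.4,
                                flick_time = duration / 2, cardiac_freq = 1.2,
                                flick_amp = 12, noise_sd = 0.15, seed = 1L) {
  if (flick_time <= 1 || flick_time >= duration - 1)
    abort("`flick_time` must fall inside the video recording (1 s margin)")
  tp_flick <- flick_time + clock_offset
  if (tp_flick <= 1 || tp_flick >= duration - 1)
    abort("`clock_offset` pushes the flick outside the pressure recording")
  omega <- 2 * pi * cardiac_freq
  tv <- (seq_len(round(duration * frame_rate)) - 1) / frame_rate
  tp <- (seq_len(round(duration * pressure_rate)) - 1) / pressure_rate
  m <- cos(omega * tv) +
    flick_amp * ifelse(tv >= flick_time, exp(-(tv - flick_time) / 0.4), 0)
  p <- 10 + 2 * cos(omega * tp + 0.7) +
    2 * flick_amp * ifelse(tp >= tp_flick, exp(-(tp - tp_flick) / 0.12), 0)
  out <- with_seed(seed, {
    list(motion = pw_trace(m + stats::rnorm(length(tv), 0, noise_sd), frame_rate),
         pressure = pw_trace(p + stats::rnorm(length(tp), 0, 2 * noise_sd), pressure_rate))
  })
  truth <- structure(list(cardiac_freq = cardiac_freq,
                          site_phase_lag = NA_real_,
                          clock_offset = clock_offset,
                          flick_time = flick_time),
                     class = "physio_ground_truth")
  c(out, list(truth = truth))
}

#' Write a physiology record to CSV
#'
#' Plain-text round-trip companion to [load_physio()]: columns `time_s`,
#' `csf_mmHg`, `abp_mmHg`, `ecg_au`.
#'
#' @param rec a [physiology_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_physio <- function(rec, path) {
  stopifnot(inherits(rec, "physiology_record"))
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}
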