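# Complex continuous wavelet machinery: analytic Gabor/Morlet transforms,
# cardiac-band selection, band-limited inverse reconstruction and
# cross-wavelet phase differencing.
#
# Conventions used throughout the package
# ---------------------------------------
# A real tone cos(2*pi*f*t + theta) transforms to coefficients proportional
# to exp(i*(2*pi*f*t + theta)) at the matching scale, i.e. the coefficient
# angle is the instantaneous phasor angle of the tone.  Consequently
# cross_wavelet_phase(a, b) = Arg(W_a * Conj(W_b)) = theta_a - theta_b,
# which grows by +2*pi*f*dt when b is a copy of a delayed by dt.  All
# downstream phase differences inherit their sign from this rule.

#' Fourier transform of the zero-mean-corrected analytic Gabor/Morlet wavelet
#'
#' The mother wavelet is psi(t) propto (exp(i*w0*t) - exp(-w0^2/2)) *
#' exp(-t^2/2).  The Gaussian correction term enforces admissibility
#' (zero mean), which matters for the low time-bandwidth variant w0 = 1;
#' for w0 = 6 it is numerically negligible.  Normalisation constants are
#' omitted: every consumer in the package either takes a phase (constants
#' cancel) or is explicitly calibrated.
#'
#' @param omega angular frequency (radians per unit time), any real vector.
#' @param omega0 dimensionless centre-frequency parameter of the wavelet.
#' @return real vector, the wavelet's Fourier transform at `omega`.
#' @keywords internal
morlet_fourier <- function(omega, omega0) {
  exp(-(omega - omega0)^2 / 2) - exp(-omega0^2 / 2) * exp(-omega^2 / 2)
}

# internal: angular frequency at which |psihat| peaks, per omega0 (cached).
# Defines the scale <-> pseudo-frequency map s(f) = peak_omega / (2*pi*f).
peak_omega_env <- new.env(parent = emptyenv())
peak_omega <- function(omega0) {
  key <- format(omega0, digits = 15)
  if (!is.null(peak_omega_env[[key]])) return(peak_omega_env[[key]])
  opt <- stats::optimize(function(w) morlet_fourier(w, omega0),
                         interval = c(1e-3, omega0 + 6), maximum = TRUE)
  peak_omega_env[[key]] <- opt$maximum
  opt$maximum
}

#' Wavelet analysis specification
#'
#' Bundles the centre-frequency parameter of the analytic Gabor/Morlet
#' wavelet with its derived scale map.  Two canonical variants are used:
#' `omega0 = 6` (high frequency resolution, the default analysis wavelet)
#' and `omega0 = 1` (high temporal resolution, used for the per-pixel
#' transform in the angiographic cross product).
#'
#' @param omega0 dimensionless centre-frequency parameter (> 0).
#' @return an object of class `wavelet_spec`.
#' @examples
#' wavelet_spec(6)
#' wavelet_spec(1)
#' @export
wavelet_spec <- function(omega0 = 6) {
  if (!is_number(omega0) || omega0 <= 0) abort("`omega0` must be a positive number")
  structure(list(omega0 = omega0, peak_omega = peak_omega(omega0)),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> analytic Gabor/Morlet, omega0 = %g (peak at %0.4f rad)\n",
              x$omega0, x$peak_omega))
  invisible(x)
}

# internal: scales (time units) for a spec at given frequencies (Hz)
spec_scales <- function(spec, freqs) spec$peak_omega / (2 * pi * freqs)

#' Cardiac-frequency scale band
#'
#' A geometric grid of analysis frequencies centred on the cardiac
#' frequency.  All band-limited operations (angiography, CF filtering,
#' cross-wavelet phase) run over this grid on a shared frequency axis, so
#' that coefficients from the omega0 = 1 and omega0 = 6 wavelets can be
#' multiplied bin by bin.
#'
#' @param center centre frequency in Hz (the cardiac frequency).
#' @param width_oct total band width in octaves (default 1, i.e. +/- half
#'   an octave around the centre).
#' @param voices voices per octave (default 12; at least 8).
#' @return an object of class `cf_band` with fields `freqs`, `center`,
#'   `voices`, `width_oct`.
#' @export
cf_band <- function(center, width_oct = 1, voices = 12) {
  if (!is_number(center) || center <= 0) abort("`center` must be a positive frequency (Hz)")
  if (!is_number(voices) || voices < 8) abort("`voices` must be >= 8 per octave")
  if (!is_number(width_oct) || width_oct <= 0) abort("`width_oct` must be > 0")
  k <- ceiling(width_oct * voices / 2)
  freqs <- center * 2^(seq(-k, k) / voices)
  structure(list(freqs = freqs, center = center, voices = voices,
                 width_oct = width_oct), class = "cf_band")
}

#' @export
print.cf_band <- function(x, ...) {
  cat(sprintf("<cf_band> %d voices over %.2f-%.2f Hz (center %.3f Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$center))
  invisible(x)
}

# internal: FFT-domain CWT of the columns of a real matrix X (time down the
# rows).  Returns a list of complex matrices, one per frequency in `freqs`.
# Columns are demeaned and zero-padded to damp circular wrap-around.
cwt_cols <- function(X, fs, spec, freqs) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) abort("signals must have length >= 2")
  if (anyNA(X) || !all(is.finite(X))) abort("signals must be finite and free of NA (interpolate gaps first)")
  X <- sweep(X, 2L, colMeans(X))
  m <- stats::nextn(ceiling(1.5 * n), c(2, 3, 5))
  Xp <- rbind(X, matrix(0, m - n, ncol(X)))
  FX <- stats::mvfft(Xp)
  omega <- 2 * pi * c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / (m / fs)
  scales <- spec_scales(spec, freqs)
  lapply(scales, function(s) {
    # analytic: positive-frequency support only.  The zero-mean-corrected
    # form is exactly zero at DC, but its correction Gaussian would
    # otherwise reintroduce a counter-rotating negative-frequency
    # response (substantial for omega0 = 1).
    kern <- sqrt(s) * morlet_fourier(s * omega, spec$omega0) * (omega > 0)
    W <- stats::mvfft(FX * kern, inverse = TRUE) / m
    W[seq_len(n), , drop = FALSE]
  })
}

#' Continuous wavelet transform of a uniformly sampled series
#'
#' Analytic Gabor/Morlet CWT evaluated on the frequency grid of a
#' [cf_band()] (or any strictly positive frequency vector).  The transform
#' is linear: `cwt(a*x + b*y)` equals `a*cwt(x) + b*cwt(y)` element-wise.
#'
#' @param x numeric vector, uniformly sampled, no NAs.
#' @param fs sampling rate in Hz.
#' @param band a [cf_band()] or numeric vector of analysis frequencies (Hz).
#' @param spec a [wavelet_spec()]; default the high-frequency-resolution
#'   wavelet (`omega0 = 6`).
#' @return an object of class `wavelet_coefficients`: complex matrix
#'   `values` (frequencies in rows, time in columns), plus `freqs`, `fs`
#'   and the `spec` used.
#' @export
cwt <- function(x, fs, band, spec = wavelet_spec(6)) {
  if (length(x) < 2L) abort("`x` must have length >= 2")
  if (!is_number(fs) || fs <= 0) abort("`fs` must be a positive sampling rate")
  freqs <- if (inherits(band, "cf_band")) band$freqs else as.numeric(band)
  if (!length(freqs) || any(!is.finite(freqs)) || any(freqs <= 0))
    abort("analysis frequencies must be positive and finite")
  Ws <- cwt_cols(matrix(as.numeric(x), ncol = 1L), fs, spec, freqs)
  values <- t(vapply(Ws, function(W) W[, 1L], complex(length(x))))
  structure(list(values = values, freqs = freqs, fs = fs, spec = spec),
            class = "wavelet_coefficients")
}

#' @export
print.wavelet_coefficients <- function(x, ...) {
  cat(sprintf("<wavelet_coefficients> %d frequencies x %d samples @ %g Hz (omega0 = %g)\n",
              nrow(x$values), ncol(x$values), x$fs, x$spec$omega0))
  invisible(x)
}

# internal: band-summed reconstruction gain Sum_j psihat(s_j * omega) at a
# given angular frequency; approximately flat in omega for a log grid.
band_gain <- function(spec, freqs, omega) {
  sum(morlet_fourier(spec_scales(spec, freqs) * omega, spec$omega0))
}

#' Cone-of-influence validity mask
#'
#' Marks samples far enough from either record edge that wavelet edge
#' effects at the band's largest scale have decayed.  The e-folding time of
#' the Gaussian wavelet envelope at scale s is sqrt(2)*s; samples within
#' `efolds` e-folding times of an edge are flagged invalid and excluded
#' from pooled statistics.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param band a [cf_band()] or frequency vector (Hz).
#' @param spec wavelet spec whose scales define the envelope (default omega0 = 6).
#' @param efolds number of e-folding times to exclude (default 1).
#' @return logical vector of length `n`; TRUE where valid.
#' @export
coi_valid <- function(n, fs, band, spec = wavelet_spec(6), efolds = 1) {
  freqs <- if (inherits(band, "cf_band")) band$freqs else as.numeric(band)
  tau <- sqrt(2) * max(spec_scales(spec, freqs)) * efolds
  k <- ceiling(tau * fs)
  valid <- rep(TRUE, n)
  if (k > 0) {
    valid[seq_len(min(k, n))] <- FALSE
    valid[seq.int(max(1L, n - k + 1L), n)] <- FALSE
  }
  valid
}

#' Band-limited inverse reconstruction (complex analytic output)
#'
#' Delta-method linear reconstruction over the band: the coefficient rows
#' are summed and rescaled so that the real part reproduces the in-band
#' component of the original signal.  Because the wavelet is analytic the
#' output is a complex analytic series: `Re` is the band-passed signal and
#' `Arg` its instantaneous phase.
#'
#' @param w a `wavelet_coefficients` object.
#' @return complex vector of length `ncol(w$values)`.
#' @export
icwt_band <- function(w) {
  stopifnot(inherits(w, "wavelet_coefficients"))
  g <- band_gain(w$spec, w$freqs, 2 * pi * geomean(w$freqs))
  2 * colSums(w$values / sqrt(spec_scales(w$spec, w$freqs))) / g
}

#' Cardiac-frequency filter
#'
#' Wavelet-filters a 1-D physiological or image-derived signal for
#' cardiac-frequency phenomena: CWT over the cardiac band followed by
#' band-limited inverse reconstruction, keeping the complex analytic
#' values.  `Re(cf_filter(x, ...))` reproduces the CF component of `x`;
#' `Arg` gives its instantaneous CF phase.
#'
#' @inheritParams cwt
#' @return complex vector the length of `x`.
#' @export
cf_filter <- function(x, fs, band, spec = wavelet_spec(6)) {
  icwt_band(cwt(x, fs, band, spec))
}

#' Cross-wavelet phase difference of two series
#'
#' Per time sample, the angle of the band sum of one signal's coefficients
#' times the complex conjugate of the other's:
#' `Arg(sum_band W_a * Conj(W_b))`.  Under the package convention this is
#' the phasor angle of `a` minus that of `b`; delaying `b` by `dt`
#' increases the result by `2*pi*f*dt`.  Swapping arguments negates it.
#'
#' @param a,b numeric vectors of equal length, same sampling rate.
#' @param fs sampling rate (Hz).
#' @param band a [cf_band()] (or frequency vector) around the cardiac
#'   frequency.
#' @param spec wavelet spec (default `omega0 = 6`).
#' @param efolds cone-of-influence width used for the validity flags.
#' @param power_floor fraction of the median cross-power below which a
#'   sample is flagged invalid (default 0.05).
#' @return list with `phase` (radians in (-pi, pi], per sample), `valid`
#'   (logical: inside the cone of influence and above the power floor),
#'   `power` (cross-magnitude per sample), `fs`, `band`.
#' @export
cross_wavelet_phase <- function(a, b, fs, band, spec = wavelet_spec(6),
                                efolds = 1, power_floor = 0.05) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length")
  Wa <- cwt(a, fs, band, spec)
  Wb <- cwt(b, fs, band, spec)
  cross <- colSums(Wa$values * Conj(Wb$values))
  phase <- wrap_angle(Arg(cross))
  power <- Mod(cross)
  valid <- coi_valid(length(a), fs, band, spec, efolds) &
    power > power_floor * stats::median(power)
  list(phase = phase, valid = valid, power = power, fs = fs,
       band = if (inherits(band, "cf_band")) band else cf_band(geomean(band)))
}

#' Locate the cardiac frequency in a reference signal
#'
#' Scans a geometric frequency grid over a physiological search range
#' (with half-octave margins), integrates wavelet power over time (cone
#' of influence excluded) at each frequency, and returns a [cf_band()]
#' centred on the strongest prominent interior local maximum.  A slowly
#' varying background - an angiographic bolus envelope, say - contributes
#' a monotone power profile with no interior local maximum, so the
#' cardiac bump is identified even when the background carries more raw
#' power.  A peak qualifies when it exceeds `min_prominence` times the
#' higher of its two flanking power troughs; if none qualifies (white
#' noise, flat channels) an error asks for an explicit `f_hint`.
#'
#' @param x reference signal (should span at least 10 cardiac periods).
#' @param fs sampling rate (Hz).
#' @param f_hint optional known cardiac frequency (Hz); skips the search.
#' @param search physiological frequency range searched, Hz (default 0.5-5).
#' @param voices voices per octave of the returned band (default 12).
#' @param width_oct width of the returned band in octaves (default 1).
#' @param min_prominence required ratio of peak power to the higher
#'   flanking trough (default 2.5).
#' @return a [cf_band()] centred on the cardiac frequency.
#' @export
select_cardiac_scale <- function(x, fs, f_hint = NULL, search = c(0.5, 5),
                                 voices = 12, width_oct = 1,
                                 min_prominence = 2.5) {
  if (!is.null(f_hint)) {
    if (!is_number(f_hint) || f_hint <= 0 || f_hint >= fs / 2)
      abort("`f_hint` must be positive and below the Nyquist frequency")
    return(cf_band(f_hint, width_oct, voices))
  }
  search <- sort(search)
  hi <- min(search[2], fs / 2 * 0.95)
  grid <- 2^seq(log2(search[1] / sqrt(2)), log2(hi * sqrt(2)), by = 1 / voices)
  # prewhiten by first differencing: suppresses the slowly varying
  # background (bolus envelope, baseline drift) relative to the cardiac
  # bump without moving the power peak's frequency
  W <- cwt(diff(as.numeric(x)), fs, grid)
  pw <- vapply(seq_along(grid), function(j) {
    v <- coi_valid(ncol(W$values), fs, grid[j], W$spec)
    if (!any(v)) return(NA_real_)
    sum(Mod(W$values[j, v])^2)
  }, numeric(1))
  if (anyNA(pw) || length(pw) < 5L)
    abort("record too short to resolve the physiological band; supply `f_hint`")
  n <- length(pw)
  is_max <- c(FALSE, pw[2:(n - 1)] > pw[1:(n - 2)] & pw[2:(n - 1)] >= pw[3:n], FALSE)
  cand <- which(is_max & grid >= search[1] & grid <= hi)
  prom <- vapply(cand, function(j) {
    left <- if (j > 1) min(pw[1:(j - 1)]) else pw[j]
    right <- if (j < n) min(pw[(j + 1):n]) else pw[j]
    # trough between this peak and any higher ground on each side
    lo <- 1:(j - 1); hi_i <- (j + 1):n
    ltr <- min(pw[seq(max(c(lo[pw[lo] > pw[j]], 1)), j - 1)])
    rtr <- min(pw[seq(j + 1, min(c(hi_i[pw[hi_i] > pw[j]], n)))])
    pw[j] / max(ltr, rtr)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand))
    abort("no clear cardiac-frequency power peak in ", search[1], "-", hi,
          " Hz; supply an explicit `f_hint`")
  fc <- grid[cand[which.max(pw[cand])]]
  if (length(x) / fs < 10 / fc)
    abort("reference spans fewer than 10 cardiac periods at ", signif(fc, 3), " Hz")
  cf_band(fc, width_oct, voices)
}
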