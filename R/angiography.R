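# Cross-wavelet angiography: per-pixel cardiac-frequency state fields.
#
# Each pixel's signal is transformed with the high-temporal-resolution
# wavelet (omega0 = 1) and cross-multiplied, bin by bin on the shared
# frequency grid, with the conjugated high-frequency-resolution
# (omega0 = 6) transform of a reference signal - the global angiographic
# signal C (spatial mean) or the brain pulse-motion chronometer M.  The
# band-summed product is a slowly varying complex phasor per pixel:
# magnitude maps pulse-wave strength, angle the pixel's CF phase relative
# to the reference (a pixel delayed by dt relative to the reference
# carries angle -2*pi*f_c*dt).

#' Global angiographic reference signal
#'
#' Spatial mean of the pixel signals over a mask (default: the whole
#' frame), the aggregate signal C against which per-pixel CF phase is
#' referenced.
#'
#' @param cine a [cine_sequence()].
#' @param mask optional logical `H x W` matrix selecting the pixels to
#'   average.
#' @return numeric vector of length T.
#' @export
global_reference <- function(cine, mask = NULL) {
  stopifnot(inherits(cine, "cine_sequence"))
  d <- dim(cine$frames)
  X <- matrix(cine$frames, d[1] * d[2], d[3])
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) abort("`mask` must match the frame size")
    X <- X[as.vector(mask), , drop = FALSE]
    if (!nrow(X)) abort("`mask` selects no pixels")
  }
  colMeans(X)
}

#' Cardiac-frequency angiographic field
#'
#' Computes the complex-valued CF state of every (selected) pixel: the
#' high-temporal-resolution wavelet coefficients of the pixel signal are
#' multiplied element-wise by the conjugated high-frequency-resolution
#' coefficients of the reference - the global signal C, or the pulse-motion
#' signal M when `motion` is supplied (motion-referenced mode, used for
#' the arterial/venous and dorsoventral phase comparisons) - restricted to
#' the cardiac band and summed over scales.
#'
#' @param cine a [cine_sequence()].
#' @param band a [cf_band()] centred on the cardiac frequency (from
#'   [select_cardiac_scale()]).
#' @param motion optional pulse-motion chronometer: a [pw_trace()] or
#'   [project_principal()] result sharing the cine's sampling rate and
#'   epoch.  When given, it replaces the global signal as phase reference.
#' @param mask optional logical `H x W` matrix restricting the field to a
#'   subset of pixels (the peri-ventricular band, say); unselected pixels
#'   are absent from the result.
#' @param reference_mask optional mask for the global reference average.
#' @param spec_pixel,spec_reference wavelet variants for the pixel and
#'   reference transforms (defaults omega0 = 1 and omega0 = 6).
#' @return an object of class `cf_field`: complex matrix `values`
#'   (pixels x time), integer matrix `pixels` (row, col, 1-based),
#'   `dim`, `fs`, `band`, `reference` ("global" or "motion").
#' @export
cf_angiogram <- function(cine, band, motion = NULL, mask = NULL,
                         reference_mask = NULL,
                         spec_pixel = wavelet_spec(1),
                         spec_reference = wavelet_spec(6)) {
  stopifnot(inherits(cine, "cine_sequence"), inherits(band, "cf_band"))
  d <- dim(cine$frames)
  h <- d[1]; w <- d[2]; nt <- d[3]

  if (is.null(motion)) {
    ref <- global_reference(cine, reference_mask)
    ref_kind <- "global"
  } else {
    ref <- if (inherits(motion, "pw_trace") || inherits(motion, "pulse_motion"))
      motion$values else as.numeric(motion)
    if (!is.null(motion$fs) && abs(motion$fs - cine$fs) > 1e-9)
      abort("`motion` and `cine` must share a sampling rate")
    ref_kind <- "motion"
  }
  if (length(ref) != nt) abort("reference length must match the frame count")

  if (is.null(mask)) {
    sel <- seq_len(h * w)
  } else {
    if (!identical(dim(mask), d[1:2])) abort("`mask` must match the frame size")
    sel <- which(as.vector(mask))
    if (!length(sel)) abort("`mask` selects no pixels")
  }
  X <- matrix(cine$frames, h * w, nt)[sel, , drop = FALSE]

  # shared padded FFT setup
  n <- nt
  m <- stats::nextn(ceiling(1.5 * n), c(2, 3, 5))
  omega <- 2 * pi * c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / (m / cine$fs)
  pad <- function(v) c(v - mean(v), rep(0, m - n))
  FX <- stats::mvfft(apply(X, 1L, pad))           # m x P (pixels in columns)
  FR <- stats::fft(pad(ref))

  # High-pass gate on the pixel transform: the omega0 = 1 wavelet is
  # broadband enough to leak the bolus envelope's low-frequency content
  # into the cardiac scales, where it would beat against the reference.
  # The gate removes everything below 0.4 f_c with a cosine ramp ending
  # at 0.75 f_c, leaving the cardiac band itself untouched.
  fhz <- omega / (2 * pi)
  lo <- 0.4 * band$center; hi <- 0.75 * band$center
  hp <- ifelse(fhz <= lo, 0,
               ifelse(fhz >= hi, 1, 0.5 * (1 - cos(pi * (fhz - lo) / (hi - lo)))))

  s_pix <- spec_scales(spec_pixel, band$freqs)
  s_ref <- spec_scales(spec_reference, band$freqs)
  acc <- matrix(0+0i, nrow = ncol(FX), ncol = n)
  for (j in seq_along(band$freqs)) {
    kp <- sqrt(s_pix[j]) * morlet_fourier(s_pix[j] * omega, spec_pixel$omega0) *
      (omega > 0) * hp
    kr <- sqrt(s_ref[j]) * morlet_fourier(s_ref[j] * omega, spec_reference$omega0) *
      (omega > 0)
    Wp <- stats::mvfft(FX * kp, inverse = TRUE)[seq_len(n), , drop = FALSE] / m
    Wr <- stats::fft(FR * kr, inverse = TRUE)[seq_len(n)] / m
    acc <- acc + t(Wp * Conj(Wr)) / sqrt(s_pix[j] * s_ref[j])
  }
  pixels <- cbind(row = (sel - 1L) %% h + 1L, col = (sel - 1L) %/% h + 1L)
  structure(list(values = acc, pixels = pixels, dim = c(h, w), fs = cine$fs,
                 band = band, reference = ref_kind),
            class = "cf_field")
}

#' @export
print.cf_field <- function(x, ...) {
  cat(sprintf("<cf_field> %d pixels x %d samples @ %g Hz, %s-referenced, CF %.3g Hz\n",
              nrow(x$values), ncol(x$values), x$fs, x$reference, x$band$center))
  invisible(x)
}

#' Brightness-hue rendering of complex CF data
#'
#' Maps a complex matrix to colors: magnitude (clipped at its 99th
#' percentile) becomes brightness, phase becomes hue on a cyclic scale.
#'
#' @param z complex matrix.
#' @param mag_quantile clip quantile for the magnitude normalisation.
#' @return character matrix of R colors, same shape as `z`.
#' @export
complex_raster <- function(z, mag_quantile = 0.99) {
  mg <- Mod(z)
  top <- stats::quantile(mg, mag_quantile, names = FALSE)
  v <- pmin(mg / max(top, 1e-300), 1)
  hue <- (Arg(z) + pi) / (2 * pi)
  hue[hue >= 1] <- 0
  out <- grDevices::hsv(h = hue, s = 1, v = v)
  dim(out) <- dim(z)
  out
}
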