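# CSF-pressure pipeline: loading physiological waveform CSVs, aligning
# the unsynchronized video and pressure clocks via the finger-flick
# transient, cardiac-referencing each recording epoch, and pooling
# dorsal-minus-ventral CF phase differences of CSF pressure.

#' Load a physiological waveform CSV
#'
#' Reads a CSV with time, CSF pressure, ABP and ECG columns into a
#' [physiology_record()].  Column names can be remapped for dialect
#' differences; integer-encoded channels can be rescaled.  Small gaps in
#' the time base are filled by linear interpolation and flagged.
#'
#' @param path CSV file path.
#' @param site recording site label: `"lateral_ventricle"` (dorsal) or
#'   `"third_ventricle"` (ventral).
#' @param column_map named list mapping the canonical names `time`,
#'   `csf`, `abp`, `ecg` to the file's column names; defaults to
#'   `time_s`, `csf_mmHg`, `abp_mmHg`, `ecg_au`.
#' @param scale named list of multiplicative rescaling factors applied to
#'   `csf`, `abp`, `ecg` (for integer-encoded channels).
#' @param max_gap_fraction maximum tolerated fraction of interpolated
#'   samples (default 0.05).
#' @return a [physiology_record()] with attribute `interpolated` marking
#'   gap-filled samples.
#' @export
load_physio <- function(path, site = c("lateral_ventricle", "third_ventricle"),
                        column_map = list(), scale = list(),
                        max_gap_fraction = 0.05) {
  site <- match.arg(site)
  cm <- utils::modifyList(list(time = "time_s", csf = "csf_mmHg",
                               abp = "abp_mmHg", ecg = "ecg_au"), column_map)
  df <- utils::read.csv(path)
  missing_cols <- setdiff(unlist(cm), names(df))
  if (length(missing_cols))
    abort("missing column(s): ", paste(missing_cols, collapse = ", "))
  tt <- df[[cm$time]]
  if (any(diff(tt) <= 0)) abort("time column must be strictly increasing")
  dt <- stats::median(diff(tt))
  # rebuild a uniform time base and flag samples that had to be interpolated
  grid <- seq(tt[1], tt[length(tt)] + dt / 4, by = dt)
  near <- vapply(grid, function(g) min(abs(tt - g)), numeric(1))
  interpolated <- near > 0.01 * dt
  if (mean(interpolated) > max_gap_fraction)
    abort("more than ", 100 * max_gap_fraction, "% of samples missing from the time base")
  sc <- utils::modifyList(list(csf = 1, abp = 1, ecg = 1), scale)
  chan <- function(name, s) s * stats::approx(tt, df[[cm[[name]]]], grid, rule = 2)$y
  physiology_record(grid, chan("csf", sc$csf), chan("abp", sc$abp),
                    chan("ecg", sc$ecg), site = site,
                    interpolated = interpolated)
}

# internal: locate a single dominant transient in a trace.  Candidates are
# runs of |x - median| above median + k * MAD, merged when closer than
# `merge_s` seconds.  Returns the onset time: the first crossing of half
# the peak excursion, linearly interpolated between samples.
find_transient <- function(x, fs, k = 8, merge_s = 1) {
  med <- stats::median(x)
  dev <- abs(x - med)
  thr <- stats::median(dev) + k * stats::mad(dev)
  above <- which(dev > thr)
  if (!length(above)) abort("no transient found (nothing exceeds median + ", k, " * MAD)")
  gaps <- which(diff(above) > merge_s * fs)
  starts <- above[c(1L, gaps + 1L)]
  ends <- above[c(gaps, length(above))]
  if (length(starts) > 1L)
    abort("multiple candidate transients at ",
          paste(signif(starts / fs, 4), collapse = ", "),
          " s; cannot pick silently")
  seg <- starts:min(ends + round(fs), length(x))
  peak_idx <- seg[which.max(dev[seg])]
  half <- dev[peak_idx] / 2
  i <- peak_idx
  while (i > 1L && dev[i - 1L] > half) i <- i - 1L
  # linear interpolation of the half-height crossing between i-1 and i
  if (i > 1L) {
    frac <- (half - dev[i - 1L]) / (dev[i] - dev[i - 1L])
    onset <- (i - 2L + frac) / fs
  } else onset <- (i - 1L) / fs
  onset
}

#' Align the video and pressure clocks via the finger-flick transient
#'
#' Locates the single flick transient in the motion trace (video clock)
#' and in the pressure trace (pressure clock) and returns the clock
#' offset as (pressure transient onset) - (motion transient onset), with
#' an uncertainty of about one video frame.  Zero or multiple candidate
#' transients in either trace raise an error (no silent pick).
#'
#' @param motion_trace a [pw_trace()] on the video clock.
#' @param pressure_trace a [pw_trace()] on the pressure clock.
#' @param k MAD multiplier of the transient detection threshold
#'   (default 8).
#' @return list with `offset_s`, `uncertainty_s` (one video frame),
#'   `motion_onset_s`, `pressure_onset_s`.
#' @export
align_clocks <- function(motion_trace, pressure_trace, k = 8) {
  stopifnot(inherits(motion_trace, "pw_trace"), inherits(pressure_trace, "pw_trace"))
  m_on <- find_transient(motion_trace$values, motion_trace$fs, k)
  p_on <- find_transient(pressure_trace$values, pressure_trace$fs, k)
  list(offset_s = p_on - m_on,
       uncertainty_s = 1 / motion_trace$fs,
       motion_onset_s = m_on, pressure_onset_s = p_on)
}

#' Cardiac-frequency reference series from ABP or ECG
#'
#' CF-filters the chosen reference channel of a record into a complex
#' analytic series used for cardiac synchronization.  Errors when the
#' channel carries no cardiac-frequency power.
#'
#' @param rec a [physiology_record()].
#' @param channel `"ecg"` or `"abp"`.
#' @param band a [cf_band()]; by default located with
#'   [select_cardiac_scale()] on the channel itself.
#' @return complex vector (one value per sample of `rec`), with the band
#'   attached as attribute `band`.
#' @export
cardiac_reference_phase <- function(rec, channel = c("ecg", "abp"), band = NULL) {
  stopifnot(inherits(rec, "physiology_record"))
  channel <- match.arg(channel)
  x <- if (channel == "ecg") rec$ecg_au else rec$abp_mmHg
  fs <- attr(rec, "fs")
  if (stats::sd(x) < 1e-12) abort("reference channel `", channel, "` is flat")
  if (is.null(band)) band <- select_cardiac_scale(x, fs)
  z <- cf_filter(x, fs, band)
  v <- coi_valid(length(x), fs, band)
  if (sqrt(mean(Mod(z[v])^2)) < 1e-6 * stats::sd(x))
    abort("no cardiac-frequency power in channel `", channel, "`")
  attr(z, "band") <- band
  z
}

# internal: R-peak style beat onsets from the ECG channel (indices)
detect_beats <- function(ecg, fs, cardiac_freq) {
  thr <- stats::median(ecg) + 0.5 * (max(ecg) - stats::median(ecg))
  cand <- which(ecg > thr)
  if (!length(cand)) return(integer(0))
  gaps <- which(diff(cand) > 0.5 * fs / cardiac_freq)
  starts <- cand[c(1L, gaps + 1L)]
  ends <- cand[c(gaps, length(cand))]
  vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(ecg[seg])]
  }, integer(1))
}

#' Dorsal-minus-ventral CF phase of CSF pressure
#'
#' For each record (dorsal Lateral Ventricle epoch, ventral Third
#' Ventricle epoch) the CSF pressure's CF phase is measured relative to
#' the concurrent cardiac reference (ECG or ABP) by the cross-wavelet
#' method: per time sample, the phase lag of CSF pressure behind the
#' reference.  Because the two epochs are recorded minutes apart, samples
#' cannot be paired directly in time: one relative-phase value is taken
#' per detected cardiac cycle (circular mean of the valid samples within
#' the beat), and all dorsal-beat minus ventral-beat differences are
#' pooled.  A positive pooled mean means the ventral site's pressure
#' peaks earlier (ventral leads).
#'
#' @param rec_dorsal,rec_ventral [physiology_record()]s carrying the same
#'   reference channel type.
#' @param channel cardiac reference channel, `"ecg"` (default) or
#'   `"abp"`.
#' @param f_hint optional cardiac frequency hint (Hz) for band location.
#' @param min_beats minimum number of usable beats per record (default 3).
#' @return an object of class `csf_phase`: `samples` (pooled
#'   dorsal-minus-ventral differences, radians), `beats_dorsal`,
#'   `beats_ventral` (per-beat relative phases), `summary`
#'   ([circ_summary()]), `watson` ([watson_one_sample()] against 0).
#' @export
dorsoventral_csf_phase <- function(rec_dorsal, rec_ventral,
                                   channel = c("ecg", "abp"),
                                   f_hint = NULL, min_beats = 3L) {
  channel <- match.arg(channel)
  stopifnot(inherits(rec_dorsal, "physiology_record"),
            inherits(rec_ventral, "physiology_record"))

  beat_phases <- function(rec) {
    fs <- attr(rec, "fs")
    ref_ch <- if (channel == "ecg") rec$ecg_au else rec$abp_mmHg
    band <- select_cardiac_scale(ref_ch, fs, f_hint = f_hint)
    # lag of CSF pressure behind the cardiac reference, per sample
    cw <- cross_wavelet_phase(ref_ch, rec$csf_mmHg, fs, band)
    beats <- detect_beats(rec$ecg_au, fs, band$center)
    if (length(beats) < 2L) abort("too few cardiac cycles detected in the ECG channel")
    vapply(seq_len(length(beats) - 1L), function(i) {
      idx <- beats[i]:(beats[i + 1L] - 1L)
      idx <- idx[cw$valid[idx]]
      if (length(idx) < 2L) return(NA_real_)
      circ_summary(cw$phase[idx])$mean
    }, numeric(1))
  }
  bd <- beat_phases(rec_dorsal)
  bv <- beat_phases(rec_ventral)
  bd <- bd[!is.na(bd)]; bv <- bv[!is.na(bv)]
  if (length(bd) < min_beats || length(bv) < min_beats)
    abort("fewer than ", min_beats, " valid beats in a record")
  samples <- wrap_angle(as.vector(outer(bd, bv, "-")))
  smry <- circ_summary(samples)
  # Watson-style large-sample test of the dorsal-minus-ventral mean
  # direction against 0.  The pooled all-pairs differences are heavily
  # dependent (each beat enters many pairs), so the variance is that of a
  # difference of two mean directions: delta_d/n_d + delta_v/n_v, with
  # delta the circular dispersion of each record's per-beat phases.
  # per-record variance of the mean direction: circular dispersion over an
  # autocorrelation-adjusted effective beat count (adjacent beats are
  # positively correlated through the wavelet smoothing time and the
  # respiratory cycle)
  mean_var <- function(th) {
    s <- circ_summary(th)
    rho2 <- mean(cos(2 * (th - s$mean)))
    disp <- (1 - rho2) / (2 * s$rbar^2)
    u <- sin(th - s$mean)
    n <- length(th)
    r1 <- if (n > 3 && stats::sd(u) > 0) stats::cor(u[-1], u[-n]) else 0
    r1 <- min(max(r1, 0), 0.95)
    n_eff <- max(2, n * (1 - r1) / (1 + r1))
    disp / n_eff
  }
  se2 <- mean_var(bd) + mean_var(bv)
  z <- wrap_angle(smry$mean) / sqrt(se2)
  watson <- structure(list(
    statistic = z, p_value = max(2 * stats::pnorm(-abs(z)), 1e-16),
    n = length(samples), n_dorsal = length(bd), n_ventral = length(bv),
    mu0 = 0, mean = smry$mean,
    method = "Watson large-sample test of mean direction (two-epoch form)"),
    class = "watson_test")
  structure(list(samples = samples, beats_dorsal = bd, beats_ventral = bv,
                 summary = smry, watson = watson, channel = channel),
            class = "csf_phase")
}

#' @export
print.csf_phase <- function(x, ...) {
  cat("Dorsal-minus-ventral CF phase of CSF pressure (", x$channel,
      "-referenced)\n", sep = "")
  cat(sprintf("  %d dorsal x %d ventral beats -> %d pooled differences\n",
              length(x$beats_dorsal), length(x$beats_ventral), length(x$samples)))
  cat(sprintf("  pooled mean %.3f rad, sd %.3f rad\n", x$summary$mean, x$summary$sd))
  cat(sprintf("  Watson one-sample test vs 0 rad: p %s\n",
              format.pval(x$watson$p_value, digits = 3)))
  if (x$summary$mean > 0)
    cat("  (positive: ventral CSF pressure peaks first)\n")
  invisible(x)
}
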