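# End-to-end peri-ventricular analysis: one call from cine + traced
# contour + motion ROI to the dorsoventral and arteriovenous phase
# results.

#' Peri-ventricular pulse-wave phase analysis
#'
#' Runs the full analysis chain on a cine sequence: brain pulse motion is
#' tracked in `motion_roi` and reduced to the 1-D chronometer M; the
#' cardiac band is located in the global angiographic signal; the
#' motion-referenced complex CF field is computed over the
#' peri-ventricular band built from the traced contour; and the
#' dorsal-ventral and (optionally) arterial-venous phase comparisons are
#' evaluated.
#'
#' @param cine a [cine_sequence()].
#' @param contour_vertices ordered contour vertex matrix (`k x 2`,
#'   pixel coordinates) tracing the ventricular surface.
#' @param motion_roi polygon for [track_region()] around a trackable
#'   object.
#' @param n_segments number of contour segments (default 30).
#' @param thickness band thickness in pixels (default one segment
#'   length).
#' @param f_hint optional cardiac frequency hint for
#'   [select_cardiac_scale()].
#' @param arteriovenous compute the arterial/venous interval comparison
#'   (requires a recording long enough for both intervals).
#' @param n_beats,n_permutations forwarded to [select_av_intervals()]
#'   and [av_phase()].
#' @return an object of class `periventricular_analysis` with elements
#'   `band` (the [cf_band()]), `motion`, `contour`, `polygons`,
#'   `band_series`, `tic`, `intervals`, `dorsoventral`
#'   ([dorsoventral_phase()]) and `arteriovenous` ([av_phase()] or
#'   `NULL`).
#' @export
periventricular_analysis <- function(cine, contour_vertices, motion_roi,
                                     n_segments = 30L, thickness = NULL,
                                     f_hint = NULL, arteriovenous = TRUE,
                                     n_beats = 5, n_permutations = 1e4) {
  stopifnot(inherits(cine, "cine_sequence"))
  sc <- segment_contour(contour_vertices, n_segments)
  pb <- build_band(sc, thickness = thickness)
  pm <- project_principal(track_region(cine, motion_roi))
  band <- select_cardiac_scale(global_reference(cine), cine$fs, f_hint = f_hint)
  fld <- cf_angiogram(cine, band, motion = pm,
                      mask = band_mask(pb, dim(cine$frames)[1:2]))
  bs <- band_signal(fld, pb)
  tic <- time_intensity_curve(cine, pb, cardiac_freq = band$center)
  av <- NULL
  intervals <- NULL
  if (arteriovenous) {
    intervals <- select_av_intervals(tic, band$center, n_beats = n_beats)
    av <- av_phase(bs, intervals, n_permutations = n_permutations)
  }
  structure(list(band = band, motion = pm, contour = sc, polygons = pb,
                 band_series = bs, tic = tic, intervals = intervals,
                 dorsoventral = dorsoventral_phase(bs),
                 arteriovenous = av),
            class = "periventricular_analysis")
}

#' @export
print.periventricular_analysis <- function(x, ...) {
  cat("Peri-ventricular CF pulse-wave phase analysis\n")
  cat(sprintf("  cardiac frequency: %.3f Hz\n", x$band$center))
  cat(sprintf("  pulse motion axis: (%.2f, %.2f), %.0f%% variance\n",
              x$motion$axis[1], x$motion$axis[2],
              100 * x$motion$explained_variance_fraction))
  print(x$dorsoventral)
  if (!is.null(x$arteriovenous)) print(x$arteriovenous)
  invisible(x)
}
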