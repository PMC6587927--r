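#' Build a parietal evoked-component template
#'
#' The simulated P300 is a Gaussian-windowed positive deflection with a
#' spatially Gaussian scalp topography centred on a parietal channel. Only
#' its amplitude, latency, width and topography matter to the downstream
#' analyses, so no attempt is made to copy an empirical ERP shape.
#'
#' @param peak_latency_s Latency of the waveform maximum, seconds post event.
#' @param width_s Temporal standard deviation of the Gaussian bump, seconds.
#' @param amplitude Peak amplitude at the topography maximum (arbitrary
#'   microvolt-scale units).
#' @param montage A `montage_spec` (default [standard_montage_64()]).
#' @param roi_center Channel label at which the spatial Gaussian is centred.
#' @param jitter_sd_s Default per-trial latency jitter SD carried with the
#'   template, seconds.
#' @param spatial_sd Spatial SD of the topography Gaussian in head-disk units.
#' @return An `erp_template` with fields `peak_latency_s`, `width_s`,
#'   `amplitude`, `topography` (named 64-vector, max gain 1 at `roi_center`),
#'   `jitter_sd_s`.
#' @export
make_template <- function(peak_latency_s = 0.5, width_s = 0.08, amplitude = 1,
                          montage = standard_montage_64(), roi_center = "Pz",
                          jitter_sd_s = 0, spatial_sd = 0.35) {
  stopifnot(is.finite(peak_latency_s), is.finite(width_s), width_s > 0,
            is.finite(amplitude), amplitude >= 0, jitter_sd_s >= 0,
            spatial_sd > 0)
  validate_montage(montage)
  i <- match(roi_center, montage$channel)
  if (is.na(i))
    stop("roi_center channel not in montage: ", roi_center)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  topo <- exp(-d2 / (2 * spatial_sd^2))
  topo <- topo / max(topo)
  names(topo) <- montage$channel
  structure(list(peak_latency_s = peak_latency_s, width_s = width_s,
                 amplitude = amplitude, topography = topo,
                 jitter_sd_s = jitter_sd_s, roi_center = roi_center),
            class = "erp_template")
}

#' Evaluate a template waveform on a time grid
#'
#' @param template An `erp_template`.
#' @param times_s Time points (seconds relative to event onset).
#' @param latency_s Actual peak latency for this trial (defaults to the
#'   template's nominal latency).
#' @param amplitude Actual peak amplitude (defaults to the template's).
#' @return Numeric vector of the waveform at `times_s`.
#' @export
template_waveform <- function(template, times_s,
                              latency_s = template$peak_latency_s,
                              amplitude = template$amplitude) {
  amplitude * exp(-(times_s - latency_s)^2 / (2 * template$width_s^2))
}

#' @export
print.erp_template <- function(x, ...) {
  cat(sprintf("<erp_template> peak %.3f s, width (sd) %.3f s, amplitude %.3g, centred at %s\n",
              x$peak_latency_s, x$width_s, x$amplitude, x$roi_center))
  invisible(x)
}
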