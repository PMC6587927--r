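#' Pipeline defaults
#'
#' All fixed analysis constants in one place: the conditioning band and rate,
#' the epoch length the decoder expects, the sliding-window grid, the decoder
#' hyperparameters, and the parietal region of interest used for amplitude
#' measurement. Functions take these as defaults; nothing in the logic
#' hard-codes them.
#'
#' @return A named list of defaults.
#' @export
p300_defaults <- function() {
  list(
    bandpass_low_hz  = 0.3,
    bandpass_high_hz = 50,
    sample_rate_hz   = 128,
    epoch_window_s   = c(0.0, 1.0),
    slide_span_s     = c(-1.0, 1.0),
    slide_stride_samples = 4L,   # gives 65 outputs over [-1, 1] s at 128 Hz
    slide_n_outputs  = 65L,
    dropout_p        = 0.25,
    n_iterations     = 100L,
    batch_size       = 64L,
    roi_channels     = c("Pz", "P1", "P2", "CP1", "CP2", "CPz"),
    amplitude_window_s = c(0.400, 0.850),
    n_reps_downselect  = 100L
  )
}

#' Parietal region of interest
#' @return Channel labels of the parietal ROI.
#' @export
roi_channels <- function() p300_defaults()$roi_channels
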