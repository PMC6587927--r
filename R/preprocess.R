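#' Squared-magnitude response of the zero-phase bandpass
#'
#' The conditioning filter is a 4th-order Butterworth bandpass applied
#' forward and backward (zero phase), realized spectrally: each channel is
#' reflect-padded, transformed, multiplied by the squared magnitude response
#' of the digital (bilinear, prewarped) Butterworth design, and inverted.
#' This is the frequency response a forward-backward IIR pass would apply,
#' without its edge transients. The returned value is the amplitude gain of
#' the whole zero-phase operation at frequency `f`.
#'
#' @param f Frequencies, Hz.
#' @param low_hz,high_hz Band edges, Hz.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth order per band edge (default 4).
#' @return Amplitude gain in `[0, 1]` at each `f`.
#' @export
bandpass_gain <- function(f, low_hz, high_hz, fs, order = 4) {
  prewarp <- function(fr) 2 * fs * tan(pi * fr / fs)
  wl <- prewarp(low_hz); wh <- prewarp(high_hz)
  w <- prewarp(pmin(f, fs / 2))
  w0sq <- wl * wh; b <- wh - wl
  g <- numeric(length(f))
  pos <- is.finite(w) & w > 0
  x <- (w[pos]^2 - w0sq) / (b * w[pos])
  g[pos] <- 1 / (1 + x^(2 * order))
  g
}

#' Zero-phase bandpass filter
#'
#' Bandpass filters a recording between `low_hz` and `high_hz` with the
#' zero-phase 4th-order Butterworth response (see [bandpass_gain()]). DC is
#' removed exactly; shape and sampling rate are unchanged.
#'
#' @param rec A `recording`.
#' @param low_hz,high_hz Band edges, Hz; must satisfy
#'   `low_hz < high_hz < fs / 2`.
#' @return The filtered `recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 0.3, high_hz = 50) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate_hz
  if (!(low_hz < high_hz))
    stop("low_hz must be below high_hz")
  if (high_hz >= fs / 2)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g)",
                 high_hz, fs / 2))
  x <- rec$data
  n <- ncol(x)
  pad <- min(n - 1L, as.integer(round(10 * fs)))
  # odd (point-symmetric) reflection padding to suppress wraparound edges
  xp <- cbind(2 * x[, 1] - x[, (pad + 1):2, drop = FALSE],
              x,
              2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE])
  # zero-extend to a 2-3-5-smooth FFT length (fast transform); the zeros sit
  # beyond the reflection pad and never touch the retained samples
  np_s <- stats::nextn(ncol(xp), c(2L, 3L, 5L))
  if (np_s > ncol(xp))
    xp <- cbind(xp, matrix(0, nrow(xp), np_s - ncol(xp)))
  np <- ncol(xp)
  freqs <- seq(0, fs, length.out = np + 1)[1:np]
  freqs <- pmin(freqs, fs - freqs)
  gain <- bandpass_gain(freqs, low_hz, high_hz, fs)
  X <- stats::mvfft(t(xp))
  y <- Re(stats::mvfft(X * gain, inverse = TRUE)) / np
  rec$data <- t(y)[, pad + seq_len(n), drop = FALSE]
  rec
}

#' Downsample a recording (Fourier method)
#'
#' Fourier-domain resampling: the spectrum is truncated to the target band
#' and inverted at the new length, preserving duration to within one sample.
#' Event onsets are stored in seconds and need no adjustment. Upsampling is
#' out of scope.
#'
#' @param rec A `recording`.
#' @param target_hz Target rate; must not exceed the current rate.
#' @return The resampled `recording`.
#' @export
resample_recording <- function(rec, target_hz = 128) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate_hz
  if (target_hz > fs)
    stop("upsampling is not supported (target_hz > sample_rate_hz)")
  if (target_hz == fs) return(rec)
  n0 <- ncol(rec$data)
  m0 <- as.integer(round(n0 * target_hz / fs))
  # zero-extend to a smooth FFT length when the rate ratio allows it, then
  # crop back after inversion; keeps both transforms fast
  n <- stats::nextn(n0, c(2L, 3L, 5L))
  if ((n * target_hz) %% fs != 0) n <- n0
  m <- as.integer(round(n * target_hz / fs))
  x <- rec$data
  if (n > n0) x <- cbind(x, matrix(0, nrow(x), n - n0))
  X <- stats::mvfft(t(x))  # n x C
  Y <- matrix(0 + 0i, m, ncol(X))
  kmax <- (m - 1L) %/% 2L
  Y[1, ] <- X[1, ]
  if (kmax >= 1) {
    ks <- seq_len(kmax)
    Y[ks + 1, ] <- X[ks + 1, , drop = FALSE]
    Y[m - ks + 1, ] <- X[n - ks + 1, , drop = FALSE]
  }
  if (m %% 2L == 0L)
    Y[m / 2 + 1, ] <- X[m / 2 + 1, , drop = FALSE] +
      X[n - m / 2 + 1, , drop = FALSE]
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  rec$data <- t(y)[, seq_len(m0), drop = FALSE]
  rec$sample_rate_hz <- target_hz
  rec
}

#' Median-absolute-deviation normalization
#'
#' Divides a subject-experiment recording by its MAD,
#' `median(|x - median(x)|)` over all channels and time points jointly (no
#' consistency constant). This puts heterogeneous experiments on a common
#' robust scale; the MAD of the output is exactly 1.
#'
#' @param rec A `recording`.
#' @return The normalized `recording`.
#' @export
mad_normalize <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  m <- stats::median(abs(rec$data - stats::median(rec$data)))
  if (m == 0)
    stop(sprintf("degenerate recording %s/%s: MAD is zero",
                 rec$experiment, rec$subject))
  rec$data <- rec$data / m
  rec
}

#' Full conditioning pipeline for one recording
#'
#' Applies, in the fixed order the analysis requires: bandpass filter,
#' resample to `rate_hz`, MAD normalization (computed after resampling).
#'
#' @param rec A `recording`.
#' @param low_hz,high_hz Band edges, Hz.
#' @param rate_hz Target rate, Hz.
#' @return The conditioned `recording`.
#' @export
preprocess_recording <- function(rec, low_hz = 0.3, high_hz = 50,
                                 rate_hz = 128) {
  mad_normalize(resample_recording(bandpass_filter(rec, low_hz, high_hz),
                                   rate_hz))
}

#' Epoch a recording around events
#'
#' Extracts half-open sample windows `[round((onset + start) * fs), ...)` of
#' exactly `round((end - start) * fs)` samples per event (nearest-sample
#' rounding of fractional offsets), and assigns binary labels: target and
#' distractor events map to class 1 (the P300 class), background to class 0.
#' Events whose window would leave the recording are skipped with a warning;
#' the skipped count is available as `attr(, "n_skipped")`.
#'
#' @param rec A conditioned `recording`.
#' @param events Event table (data.frame with at least `onset_s`, `label`).
#' @param window `c(start_s, end_s)` relative to event onset.
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `labels` (0/1), `window`, `sample_rate_hz`, `channel_names`,
#'   `meta` (the retained event rows).
#' @export
epoch_events <- function(rec, events, window = c(0.0, 1.0)) {
  stopifnot(inherits(rec, "recording"), is.data.frame(events),
            length(window) == 2, window[1] < window[2])
  bad <- setdiff(unique(events$label),
                 c("target", "distractor", "background"))
  if (length(bad))
    stop("unknown event label(s): ", paste(bad, collapse = ", "))
  fs <- rec$sample_rate_hz
  n <- ncol(rec$data)
  len <- as.integer(round((window[2] - window[1]) * fs))
  s0 <- as.integer(round((events$onset_s + window[1]) * fs))  # 0-based
  ok <- s0 >= 0L & (s0 + len) <= n
  n_skip <- sum(!ok)
  if (n_skip > 0)
    warning(sprintf("skipped %d event(s) whose window leaves the recording",
                    n_skip))
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nrow(rec$data), len))
  for (i in seq_along(keep))
    dat[i, , ] <- rec$data[, s0[keep[i]] + seq_len(len), drop = FALSE]
  meta <- events[keep, , drop = FALSE]
  rownames(meta) <- NULL
  out <- structure(list(
    data = dat,
    labels = as.integer(meta$label %in% c("target", "distractor")),
    window = window, sample_rate_hz = fs,
    channel_names = rec$channel_names, meta = meta),
    class = "epoch_set")
  attr(out, "n_skipped") <- n_skip
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d ch x %d samples @ %g Hz; %d in P300 class\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sample_rate_hz,
    sum(x$labels)))
  invisible(x)
}

#' Combine epoch sets
#'
#' Row-binds epoch sets sharing a window, rate and montage (e.g. across
#' subjects or experiments).
#' @param sets List of `epoch_set`.
#' @return One `epoch_set`.
#' @export
combine_epochs <- function(sets) {
  sets <- Filter(function(s) dim(s$data)[1] > 0, sets)
  stopifnot(length(sets) >= 1)
  ref <- sets[[1]]
  for (s in sets[-1])
    stopifnot(identical(s$window, ref$window),
              s$sample_rate_hz == ref$sample_rate_hz,
              identical(s$channel_names, ref$channel_names))
  ntr <- vapply(sets, function(s) dim(s$data)[1], integer(1))
  dat <- array(0, dim = c(sum(ntr), dim(ref$data)[2], dim(ref$data)[3]))
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[1]
    dat[at + seq_len(k), , ] <- s$data
    at <- at + k
  }
  structure(list(data = dat,
                 labels = unlist(lapply(sets, `[[`, "labels"),
                                 use.names = FALSE),
                 window = ref$window, sample_rate_hz = ref$sample_rate_hz,
                 channel_names = ref$channel_names,
                 meta = do.call(rbind, lapply(sets, `[[`, "meta"))),
            class = "epoch_set")
}

#' Condition and epoch a simulated database
#'
#' Runs [preprocess_recording()] on every subject recording, epochs that
#' subject's events, and combines the result across subjects.
#'
#' @param db A `simulated_database`.
#' @param window Epoch window in seconds.
#' @param low_hz,high_hz,rate_hz Conditioning parameters.
#' @return A combined `epoch_set` (with per-trial `meta`).
#' @export
prepare_epochs <- function(db, window = c(0.0, 1.0), low_hz = 0.3,
                           high_hz = 50, rate_hz = 128) {
  stopifnot(inherits(db, "simulated_database"))
  sets <- lapply(db$recordings, function(rec) {
    ev <- db$events[db$events$subject == rec$subject, , drop = FALSE]
    epoch_events(preprocess_recording(rec, low_hz, high_hz, rate_hz),
                 ev, window)
  })
  combine_epochs(sets)
}
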