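#' Sliding-window time grid
#'
#' Start times of the decoding windows: from 1 s before to 1 s after event
#' onset. At 128 Hz a 4-sample stride yields the canonical 65 outputs; each
#' output at time T summarizes the epoch `[T, T + 1)` s and is labeled by
#' the epoch's first sample.
#'
#' @param fs Sampling rate, Hz.
#' @param stride Window stride in samples.
#' @param span_s `c(before, after)` span of window start times, seconds.
#' @return Numeric vector of window start times.
#' @export
slide_times <- function(fs = 128, stride = 4L,
                        span_s = c(-1.0, 1.0)) {
  n_steps <- round((span_s[2] - span_s[1]) * fs / stride)
  span_s[1] + (0:n_steps) * stride / fs
}

#' Decode one trial with a sliding window
#'
#' Applies the trained decoder to 1 s epochs starting at every grid time
#' (see [slide_times()]) around a single event, producing the probability
#' trace of the P300 class.
#'
#' @param decoder A trained `p300_decoder`.
#' @param rec A conditioned `recording` at the decoder's sampling rate.
#' @param onset_s Event onset, seconds.
#' @param stride Stride in samples.
#' @param event_meta Optional one-row data.frame carried with the trace.
#' @return A `decode_trace`: list with `times_s`, `probs`, `event_meta`.
#' @export
sliding_decode <- function(decoder, rec, onset_s, stride = 4L,
                           event_meta = NULL) {
  stopifnot(inherits(decoder, "p300_decoder"), inherits(rec, "recording"))
  fs <- rec$sample_rate_hz
  tw <- decoder$config$n_samples / fs  # window length, s
  times <- slide_times(fs, stride)
  need_lo <- onset_s + times[1]
  need_hi <- onset_s + times[length(times)] + tw
  dur <- ncol(rec$data) / fs
  if (need_lo < 0 || need_hi > dur)
    stop(sprintf(
      "sliding decode needs samples in [%.3f, %.3f] s but recording spans [0, %.3f] s",
      need_lo, need_hi, dur))
  L <- decoder$config$n_samples
  X <- array(0, dim = c(length(times), nrow(rec$data), L))
  s0 <- round((onset_s + times) * fs)
  for (i in seq_along(times))
    X[i, , ] <- rec$data[, s0[i] + seq_len(L), drop = FALSE]
  probs <- predict_decoder(decoder, X)
  structure(list(times_s = times, probs = probs, event_meta = event_meta),
            class = "decode_trace")
}

#' @export
print.decode_trace <- function(x, ...) {
  cat(sprintf("<decode_trace> %d outputs over [%g, %g] s; peak %.3f at %+.3f s\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              max(x$probs), x$times_s[which.max(x$probs)]))
  invisible(x)
}

#' Sliding-window decode a set of events
#'
#' Conditions every subject recording of a simulated database, then decodes
#' each selected event with the sliding window, batching all windows through
#' the network for speed.
#'
#' @param decoder A trained `p300_decoder`.
#' @param db A `simulated_database`.
#' @param events Subset of `db$events` rows to decode (default all).
#' @param stride Stride in samples.
#' @param low_hz,high_hz,rate_hz Conditioning parameters.
#' @return A `trace_set`: list with `times_s` (shared grid), `probs`
#'   (trials x times matrix), `meta` (event rows).
#' @export
decode_traces <- function(decoder, db, events = db$events, stride = 4L,
                          low_hz = 0.3, high_hz = 50, rate_hz = 128) {
  stopifnot(inherits(db, "simulated_database"))
  times <- slide_times(rate_hz, stride)
  L <- decoder$config$n_samples
  n_ev <- nrow(events)
  probs <- matrix(NA_real_, n_ev, length(times))
  for (subj in unique(events$subject)) {
    rec <- preprocess_recording(db$recordings[[subj]], low_hz, high_hz,
                                rate_hz)
    rows <- which(events$subject == subj)
    # batch windows through the network, chunked to bound memory
    for (chunk in split(rows, ceiling(seq_along(rows) / 16))) {
      X <- array(0,
                 dim = c(length(chunk) * length(times), nrow(rec$data), L))
      k <- 0L
      for (r in chunk) {
        s0 <- round((events$onset_s[r] + times) * rate_hz)
        for (i in seq_along(times)) {
          k <- k + 1L
          X[k, , ] <- rec$data[, s0[i] + seq_len(L), drop = FALSE]
        }
      }
      p <- predict_decoder(decoder, X)
      probs[chunk, ] <- matrix(p, ncol = length(times), byrow = TRUE)
    }
  }
  structure(list(times_s = times, probs = probs, meta = events),
            class = "trace_set")
}

#' Probability at a given window start time
#'
#' @param traces A `trace_set`.
#' @param t0 Window start time on the trace grid (default 0: the epoch
#'   `[0, 1]` s).
#' @return Numeric vector, one probability per trial.
#' @export
trace_at <- function(traces, t0 = 0) {
  j <- which(abs(traces$times_s - t0) < 1e-9)
  if (!length(j))
    stop("time ", t0, " is not on the trace grid")
  traces$probs[, j]
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d trials x %d outputs over [%g, %g] s\n",
              nrow(x$probs), length(x$times_s), min(x$times_s),
              max(x$times_s)))
  invisible(x)
}

#' Subset a trace set
#' @param traces A `trace_set`.
#' @param i Trial indices or logical mask.
#' @return The subset `trace_set`.
#' @export
subset_traces <- function(traces, i) {
  structure(list(times_s = traces$times_s,
                 probs = traces$probs[i, , drop = FALSE],
                 meta = traces$meta[i, , drop = FALSE]),
            class = "trace_set")
}

#' Average traces with standard errors
#'
#' Pointwise mean and standard error of the mean, optionally grouped by a
#' metadata column.
#'
#' @param traces A `trace_set`, or a list of `decode_trace` sharing a grid.
#' @param group_by Optional name of a `meta` column to group by.
#' @return A data.frame with `group`, `time_s`, `mean`, `sem`, `n`.
#' @export
average_traces <- function(traces, group_by = NULL) {
  if (!inherits(traces, "trace_set")) {
    grids <- lapply(traces, `[[`, "times_s")
    for (g in grids[-1])
      if (!isTRUE(all.equal(g, grids[[1]])))
        stop("traces do not share a common time grid")
    traces <- structure(list(
      times_s = grids[[1]],
      probs = do.call(rbind, lapply(traces, `[[`, "probs")),
      meta = NULL), class = "trace_set")
  }
  groups <- if (is.null(group_by)) rep("all", nrow(traces$probs))
            else as.character(traces$meta[[group_by]])
  out <- lapply(unique(groups), function(g) {
    m <- traces$probs[groups == g, , drop = FALSE]
    n <- nrow(m)
    data.frame(group = g, time_s = traces$times_s,
               mean = colMeans(m),
               sem = if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else 0,
               n = n)
  })
  do.call(rbind, out)
}

#' Re-index trace times to epoch centers
#'
#' Trace times are stored as epoch start times; for plotting against ERP
#' waveforms it is sometimes convenient to index by the epoch center
#' instead.
#' @param traces A `trace_set`.
#' @param window_len_s Decoder input length, seconds.
#' @return The `trace_set` with shifted times.
#' @export
center_trace_times <- function(traces, window_len_s = 1.0) {
  traces$times_s <- traces$times_s + window_len_s / 2
  traces
}
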