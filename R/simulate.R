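#' Condition specification for the synthetic generator
#'
#' A condition describes one experimental manipulation cell: how the evoked
#' component's amplitude and latency are modulated, the class mix, the event
#' rate, and whether events are stimulus- or fixation-locked.
#'
#' @param name Condition label.
#' @param amplitude_scale Multiplier on the template amplitude (>= 0).
#' @param latency_shift_s Additive shift of the component latency, seconds.
#' @param jitter_sd_s Per-trial latency jitter SD, seconds; `NA` means use the
#'   template's own `jitter_sd_s`.
#' @param class_ratio Named positive proportions for
#'   `c(target, distractor, background)`.
#' @param locking `"stimulus"` or `"fixation"`.
#' @param similarity Distractor amplitude as a fraction (< 1) of the target
#'   amplitude (perceptual-similarity factor).
#' @param isi_s Inter-event interval, seconds.
#' @param tti_model Optional list `list(tau_s = ...)`: amplitude saturates
#'   with the realized target-to-target interval as
#'   `A(tti) = A * (1 - exp(-tti / tau_s))`, near-asymptotic by 6-8 s for the
#'   default `tau_s = 2.5`.
#' @param fixation_latency Lognormal parameters
#'   `list(meanlog = , sdlog = )` for the stimulus-to-fixation latency drawn
#'   when `locking == "fixation"`.
#' @return A `condition_spec`.
#' @export
condition_spec <- function(name = "default", amplitude_scale = 1,
                           latency_shift_s = 0, jitter_sd_s = NA_real_,
                           class_ratio = c(target = 1, distractor = 1,
                                           background = 14),
                           locking = c("stimulus", "fixation"),
                           similarity = 0.6, isi_s = 1.0, tti_model = NULL,
                           fixation_latency = list(meanlog = -1.517,
                                                   sdlog = 0.4)) {
  locking <- match.arg(locking)
  stopifnot(amplitude_scale >= 0, is.finite(latency_shift_s),
            similarity >= 0, similarity < 1, isi_s > 0)
  if (length(class_ratio) != 3L || any(class_ratio < 0) ||
      sum(class_ratio) <= 0)
    stop("class_ratio must be 3 non-negative proportions with positive sum")
  names(class_ratio) <- c("target", "distractor", "background")
  if (!is.null(tti_model)) {
    if (is.null(tti_model$tau_s) || tti_model$tau_s <= 0)
      stop("tti_model$tau_s must be > 0")
  }
  structure(list(name = name, amplitude_scale = amplitude_scale,
                 latency_shift_s = latency_shift_s, jitter_sd_s = jitter_sd_s,
                 class_ratio = class_ratio, locking = locking,
                 similarity = similarity, isi_s = isi_s,
                 tti_model = tti_model, fixation_latency = fixation_latency),
            class = "condition_spec")
}

#' Experiment specification for the synthetic generator
#'
#' @param experiment_id Unique experiment label.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_trials_per_subject Events per subject, split evenly over
#'   conditions.
#' @param sample_rate_hz Recording rate, >= 128 Hz.
#' @param conditions List of [condition_spec()] objects.
#' @param noise Background model: `onef_exponent` (1/f PSD slope),
#'   `onef_sd`, `osc_freq_hz`, `osc_amp`, `white_sd`, in template-amplitude
#'   units.
#' @param seed Integer RNG seed for this experiment's stream.
#' @param duration_s Optional fixed recording duration per subject; an error
#'   is raised if the trial schedule does not fit.
#' @return An `experiment_spec`.
#' @export
experiment_spec <- function(experiment_id, n_subjects = 1,
                            n_trials_per_subject = 100,
                            sample_rate_hz = 128,
                            conditions = list(condition_spec()),
                            noise = noise_spec(), seed,
                            duration_s = NULL) {
  stopifnot(n_subjects >= 1, n_trials_per_subject >= 1,
            sample_rate_hz >= 128, length(conditions) >= 1)
  if (missing(seed) || !is.finite(seed))
    stop("experiment_spec requires an integer seed")
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  structure(list(experiment_id = experiment_id,
                 n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 sample_rate_hz = sample_rate_hz, conditions = conditions,
                 noise = noise, seed = as.integer(seed),
                 duration_s = duration_s),
            class = "experiment_spec")
}

#' Background noise parameters
#'
#' Defaults give an EEG-like background: 1/f spectrum (exponent 1), a 10 Hz
#' oscillation whose phase is re-drawn every second, and broadband white
#' noise at 20% of the default template amplitude.
#' @param onef_exponent Log-log PSD slope magnitude of the 1/f component.
#' @param onef_sd,osc_amp,white_sd Component scales (template-amplitude
#'   units).
#' @param osc_freq_hz Oscillation frequency, Hz.
#' @return A named list.
#' @export
noise_spec <- function(onef_exponent = 1.0, onef_sd = 0.5, osc_freq_hz = 10,
                       osc_amp = 0.5, white_sd = 0.2) {
  list(onef_exponent = onef_exponent, onef_sd = onef_sd,
       osc_freq_hz = osc_freq_hz, osc_amp = osc_amp, white_sd = white_sd)
}

#' Construct a recording object
#' @param data channels x samples numeric matrix.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param channel_names Channel labels, length `nrow(data)`.
#' @param subject,experiment Identifiers.
#' @return A `recording`.
#' @export
recording <- function(data, sample_rate_hz, channel_names, subject = "s01",
                      experiment = "EXP1") {
  stopifnot(is.matrix(data), length(channel_names) == nrow(data),
            !anyNA(data))
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 channel_names = channel_names, subject = subject,
                 experiment = experiment),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$experiment, x$subject, nrow(x$data), ncol(x$data),
              x$sample_rate_hz, ncol(x$data) / x$sample_rate_hz))
  invisible(x)
}

# 1/f-spectrum noise, one channel, sd scaled to `sd`
onef_noise <- function(n, exponent, sd, fs) {
  if (sd <= 0) return(numeric(n))
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  gain <- pmax(freqs, 0.1)^(-exponent / 2)
  gain[1] <- 0
  x <- stats::rnorm(n)
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  sd * y / stats::sd(y)
}

# sinusoid with phase re-drawn every `block_s`, raised-cosine crossfaded
osc_noise <- function(n_ch, n, freq, amp, fs, block_s = 1, fade_s = 0.125) {
  if (amp <= 0) return(matrix(0, n_ch, n))
  tt <- (seq_len(n) - 1) / fs
  starts <- seq(0, tt[n], by = block_s)
  out <- matrix(0, n_ch, n)
  fade <- max(fade_s, 2 / fs)
  for (b in seq_along(starts)) {
    t0 <- starts[b]
    t1 <- if (b < length(starts)) starts[b + 1] else tt[n] + fade
    idx <- which(tt >= t0 & tt < t1 + fade)
    if (!length(idx)) next
    w <- rep(1, length(idx))
    if (b > 1) {
      up <- tt[idx] < t0 + fade
      w[up] <- 0.5 - 0.5 * cos(pi * (tt[idx][up] - t0) / fade)
    }
    dn <- tt[idx] >= t1
    w[dn] <- 0.5 + 0.5 * cos(pi * (tt[idx][dn] - t1) / fade)
    phases <- stats::runif(n_ch, 0, 2 * pi)
    s <- sin(outer(phases, 2 * pi * freq * tt[idx], `+`))
    out[, idx] <- out[, idx] + amp * s * rep(w, each = n_ch)
  }
  out
}

#' Simulate one experiment
#'
#' Generates, per subject, a continuous recording consisting of 1/f-spectrum
#' noise, a narrowband oscillation with per-second random phase, white noise,
#' and the evoked template added at every target and distractor event.
#' Distractors receive the target amplitude scaled by the condition's
#' perceptual-similarity factor. Per-trial component latency is
#' `peak_latency_s + latency_shift_s + Normal(0, jitter_sd_s)`; reaction time
#' for targets is that latency plus a lognormal residual
#' (`meanlog = -1.2`, `sdlog = 0.5`). Identical seeds give identical output.
#'
#' @param spec An [experiment_spec()].
#' @param template An [make_template()] result.
#' @param montage A `montage_spec` matching the template topography.
#' @return A `simulated_database` with fields `recordings` (list of
#'   `recording`, one per subject), `events` (data.frame event table),
#'   `ground_truth` (data.frame aligned one-to-one with `events`).
#' @export
simulate_experiment <- function(spec, template,
                                montage = standard_montage_64()) {
  stopifnot(inherits(spec, "experiment_spec"),
            inherits(template, "erp_template"))
  validate_montage(montage)
  set.seed(spec$seed)
  fs <- spec$sample_rate_hz
  lead_in <- max(2 * template$width_s, 1.5)
  tail_s <- max(2 * template$width_s, 2.5)
  n_cond <- length(spec$conditions)
  per_cond <- diff(round(seq(0, spec$n_trials_per_subject,
                             length.out = n_cond + 1)))

  recs <- vector("list", spec$n_subjects)
  ev_list <- list(); gt_list <- list()
  for (s in seq_len(spec$n_subjects)) {
    subject <- sprintf("s%02d", s)
    onset <- numeric(0); label <- character(0); condition <- character(0)
    amp <- numeric(0); latency <- numeric(0); rt <- numeric(0)
    fixlat <- numeric(0)
    t_cursor <- lead_in
    for (ci in seq_len(n_cond)) {
      cond <- spec$conditions[[ci]]
      n_ev <- per_cond[ci]
      if (n_ev == 0) next
      p <- cond$class_ratio / sum(cond$class_ratio)
      counts <- floor(p * n_ev)
      rem <- n_ev - sum(counts)
      if (rem > 0) {
        extra <- order(p * n_ev - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      labs <- sample(rep(names(p), counts))
      ons <- t_cursor + (seq_len(n_ev) - 1) * cond$isi_s
      t_cursor <- ons[n_ev] + cond$isi_s + 2.0  # gap between condition blocks
      jit <- if (is.na(cond$jitter_sd_s)) template$jitter_sd_s else
        cond$jitter_sd_s
      lat <- template$peak_latency_s + cond$latency_shift_s +
        stats::rnorm(n_ev, 0, jit)
      a <- numeric(n_ev)
      is_t <- labs == "target"; is_d <- labs == "distractor"
      base_amp <- template$amplitude * cond$amplitude_scale
      a[is_t] <- base_amp
      a[is_d] <- base_amp * cond$similarity
      if (!is.null(cond$tti_model)) {
        t_ons <- ons[is_t]
        tti <- c(Inf, diff(t_ons))
        a[is_t] <- a[is_t] * (1 - exp(-tti / cond$tti_model$tau_s))
      }
      r <- rep(NA_real_, n_ev)
      r[is_t] <- lat[is_t] + stats::rlnorm(sum(is_t), -1.2, 0.5)
      fl <- rep(NA_real_, n_ev)
      if (cond$locking == "fixation")
        fl <- stats::rlnorm(n_ev, cond$fixation_latency$meanlog,
                            cond$fixation_latency$sdlog)
      onset <- c(onset, ons); label <- c(label, labs)
      condition <- c(condition, rep(cond$name, n_ev))
      amp <- c(amp, a); latency <- c(latency, lat); rt <- c(rt, r)
      fixlat <- c(fixlat, fl)
    }
    duration <- max(onset) + tail_s
    if (!is.null(spec$duration_s)) {
      if (spec$duration_s < duration)
        stop(sprintf(
          "trial schedule for %s/%s needs %.1f s but duration_s is %.1f s",
          spec$experiment_id, subject, duration, spec$duration_s))
      duration <- spec$duration_s
    }
    # round the length up to a 2-3-5-smooth sample count so that all
    # spectral operations (noise synthesis, filtering, resampling) use fast
    # FFT lengths
    n_samp <- stats::nextn(ceiling(duration * fs), c(2L, 3L, 5L))
    dat <- matrix(0, nrow(montage), n_samp)
    nz <- spec$noise
    if (nz$onef_sd > 0)
      for (ch in seq_len(nrow(dat)))
        dat[ch, ] <- onef_noise(n_samp, nz$onef_exponent, nz$onef_sd, fs)
    dat <- dat + osc_noise(nrow(dat), n_samp, nz$osc_freq_hz, nz$osc_amp, fs)
    if (nz$white_sd > 0)
      dat <- dat + matrix(stats::rnorm(length(dat), 0, nz$white_sd),
                          nrow(dat))
    # add the evoked component at each non-background event
    half <- 4 * template$width_s
    for (i in which(label != "background")) {
      if (amp[i] == 0) next
      s0 <- max(1L, floor((onset[i] + latency[i] - half) * fs) + 1L)
      s1 <- min(n_samp, ceiling((onset[i] + latency[i] + half) * fs) + 1L)
      tt <- (seq(s0, s1) - 1) / fs - onset[i]
      wave <- template_waveform(template, tt, latency_s = latency[i],
                                amplitude = amp[i])
      dat[, s0:s1] <- dat[, s0:s1] + outer(template$topography, wave)
    }
    recs[[s]] <- recording(dat, fs, montage$channel, subject,
                           spec$experiment_id)
    ev_list[[s]] <- data.frame(
      onset_s = onset, label = label, subject = subject,
      experiment = spec$experiment_id, condition = condition, rt_s = rt,
      fixation_latency_s = fixlat, stringsAsFactors = FALSE)
    gt_list[[s]] <- data.frame(
      subject = subject, experiment = spec$experiment_id,
      condition = condition, onset_s = onset, label = label,
      true_amplitude = amp, true_latency_s = latency,
      stringsAsFactors = FALSE)
  }
  names(recs) <- vapply(recs, function(r) r$subject, character(1))
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  gt <- do.call(rbind, gt_list)
  rownames(gt) <- NULL
  structure(list(recordings = recs, events = events, ground_truth = gt,
                 template = template, montage = montage, spec = spec),
            class = "simulated_database")
}

#' Simulate a multi-experiment database
#'
#' Each experiment uses its own seed, so streams are independent and the
#' result is reproducible experiment-by-experiment. Heterogeneous sample
#' rates and class ratios across experiments are preserved.
#'
#' @param specs List of [experiment_spec()] with unique `experiment_id`s.
#' @param template,montage Shared component template and montage.
#' @return List of `simulated_database`, named by experiment id.
#' @export
simulate_database <- function(specs, template = make_template(),
                              montage = standard_montage_64()) {
  if (!length(specs)) return(list())
  ids <- vapply(specs, function(s) s$experiment_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate experiment_id: ", ids[duplicated(ids)][1])
  out <- lapply(specs, simulate_experiment, template = template,
                montage = montage)
  names(out) <- ids
  out
}

#' @export
print.simulated_database <- function(x, ...) {
  cat(sprintf("<simulated_database> %s: %d subject(s), %d events @ %g Hz\n",
              x$spec$experiment_id, length(x$recordings), nrow(x$events),
              x$spec$sample_rate_hz))
  invisible(x)
}
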