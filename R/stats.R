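#' ROI-averaged potential per trial
#'
#' Unweighted mean over the parietal region of interest (Pz, P1, P2, CP1,
#' CP2, CPz) at each time point of every epoch.
#'
#' @param epochs An `epoch_set`.
#' @param roi Channel labels of the region of interest.
#' @return A `roi_trace_set`: list with `times_s` (epoch grid), `values`
#'   (trials x samples matrix), `meta`.
#' @export
roi_average <- function(epochs, roi = roi_channels()) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- match(roi, epochs$channel_names)
  if (anyNA(idx))
    stop("missing ROI channel(s): ", paste(roi[is.na(idx)], collapse = ", "))
  L <- dim(epochs$data)[3]
  vals <- apply(epochs$data[, idx, , drop = FALSE], c(1, 3), mean)
  vals <- matrix(vals, nrow = dim(epochs$data)[1])
  structure(list(
    times_s = epochs$window[1] + (seq_len(L) - 1) / epochs$sample_rate_hz,
    values = vals, meta = epochs$meta, labels = epochs$labels),
    class = "roi_trace_set")
}

#' Per-trial window mean
#'
#' Mean of the ROI trace over samples whose time lies in `window`
#' (closed on both ends), the standard 400-850 ms amplitude measure.
#'
#' @param traces A `roi_trace_set` (or a list with `times_s` and `values`).
#' @param window `c(start_s, end_s)` in seconds post onset.
#' @return Numeric vector, one mean per trial.
#' @export
window_mean <- function(traces, window = c(0.400, 0.850)) {
  tt <- traces$times_s
  sel <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
  if (!any(sel))
    stop(sprintf("window [%g, %g] s is outside the trace grid [%g, %g] s",
                 window[1], window[2], min(tt), max(tt)))
  rowMeans(traces$values[, sel, drop = FALSE])
}

# Per-subject baselining: subtract each subject's mean background value
# from that subject's target values, then pool.
baseline_by_subject <- function(values, subjects, bg_values, bg_subjects) {
  out <- numeric(length(values))
  for (s in unique(subjects)) {
    bg <- bg_values[bg_subjects == s]
    if (!length(bg))
      stop("subject lacking background trials: ", s)
    out[subjects == s] <- values[subjects == s] - mean(bg)
  }
  out
}

# Shared contrast engine over a per-trial value data.frame with columns
# value, subject, condition, label (1 = P300 class, 0 = background).
pooled_contrast <- function(df, cond_a, cond_b,
                            alternative = "greater") {
  stopifnot(all(c("value", "subject", "condition", "label") %in% names(df)))
  bg <- df[df$label == 0, , drop = FALSE]
  tg <- df[df$label == 1 & df$condition %in% c(cond_a, cond_b), ,
           drop = FALSE]
  if (!nrow(tg)) stop("no target trials in the requested conditions")
  tg$value <- baseline_by_subject(tg$value, tg$subject, bg$value,
                                  bg$subject)
  va <- tg$value[tg$condition == cond_a]
  vb <- tg$value[tg$condition == cond_b]
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least 2 trials per condition")
  tt <- stats::t.test(va, vb, alternative = alternative,
                      var.equal = FALSE)
  structure(list(cond_a = cond_a, cond_b = cond_b, values_a = va,
                 values_b = vb, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 n = c(a = length(va), b = length(vb)),
                 alternative = alternative),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> %s (n=%d) vs %s (n=%d): Welch t=%.3f, df=%.1f, one-tailed p=%.4g\n",
    x$cond_a, x$n["a"], x$cond_b, x$n["b"], x$t, x$df, x$p))
  invisible(x)
}

#' Amplitude-based condition contrast
#'
#' The standard ERP amplitude test: ROI average, per-trial 400-850 ms window
#' mean, per-subject background baselining, pooling across subjects, and a
#' one-tailed Welch t-test between the two conditions (alternative: `cond_a`
#' larger, by default).
#'
#' @param epochs An `epoch_set` containing both P300-class and background
#'   trials of the conditions involved.
#' @param cond_a,cond_b Condition names to compare.
#' @param window Amplitude window, seconds.
#' @param roi ROI channel labels.
#' @param alternative Direction of the one-tailed test.
#' @return A `contrast_result`.
#' @export
amplitude_contrast <- function(epochs, cond_a, cond_b,
                               window = c(0.400, 0.850),
                               roi = roi_channels(),
                               alternative = "greater") {
  tr <- roi_average(epochs, roi)
  df <- data.frame(value = window_mean(tr, window),
                   subject = tr$meta$subject,
                   condition = tr$meta$condition,
                   label = tr$labels, stringsAsFactors = FALSE)
  pooled_contrast(df, cond_a, cond_b, alternative)
}

#' Decoder-output condition contrast
#'
#' Identical procedure to [amplitude_contrast()], except the per-trial value
#' is the decoder probability at window start time T = 0 s (the epoch
#' `[0, 1]` s) instead of a time-space amplitude mean.
#'
#' @param traces A `trace_set` containing P300-class and background trials.
#' @param cond_a,cond_b Condition names to compare.
#' @param alternative Direction of the one-tailed test.
#' @return A `contrast_result`.
#' @export
decode_contrast <- function(traces, cond_a, cond_b,
                            alternative = "greater") {
  df <- data.frame(value = trace_at(traces, 0),
                   subject = traces$meta$subject,
                   condition = traces$meta$condition,
                   label = as.integer(traces$meta$label %in%
                                        c("target", "distractor")),
                   stringsAsFactors = FALSE)
  pooled_contrast(df, cond_a, cond_b, alternative)
}

#' Trial-downselection power curves
#'
#' Randomly downselects trials per subject (within each condition-by-class
#' cell), runs both the amplitude contrast and the decoder contrast on the
#' *same* selected trials, and repeats. Summarizes the p-value per
#' (fraction, method) by mean and median over repetitions.
#'
#' @param trials A data.frame with one row per trial and columns `subject`,
#'   `condition`, `label` (1 = P300 class, 0 = background), `amp_value`
#'   (400-850 ms ROI window mean) and `dec_value` (decoder output at T = 0).
#' @param cond_a,cond_b Conditions contrasted (one-tailed, `cond_a` larger).
#' @param fractions Fractions of trials to retain, in `(0, 1]`.
#' @param n_reps Repetitions per fraction.
#' @param seed RNG seed.
#' @param alternative Direction of the one-tailed test.
#' @return A `power_curve`: list with `curve` (summary data.frame:
#'   `fraction`, `method`, `mean_p`, `median_p`) and `reps` (per-repetition
#'   data.frame).
#' @export
downselect_power_curve <- function(trials, cond_a, cond_b,
                                   fractions = seq(0.1, 1.0, by = 0.1),
                                   n_reps = 100, seed = 1,
                                   alternative = "greater") {
  stopifnot(all(c("subject", "condition", "label", "amp_value",
                  "dec_value") %in% names(trials)),
            all(fractions > 0), all(fractions <= 1))
  keep <- trials$label == 0 | trials$condition %in% c(cond_a, cond_b)
  trials <- trials[keep, , drop = FALSE]
  cell <- paste(trials$subject, trials$condition, trials$label,
                sep = "\r")
  cell_rows <- split(seq_len(nrow(trials)), cell)
  tg_cells <- vapply(cell_rows, function(r) trials$label[r[1]] == 1,
                     logical(1))
  set.seed(seed)
  rows <- list()
  for (f in fractions) {
    sizes <- vapply(cell_rows, function(r) round(f * length(r)), numeric(1))
    if (any(sizes[tg_cells] < 2)) {
      warning(sprintf(
        "fraction %.2f skipped: fewer than 2 target trials per condition per subject",
        f))
      next
    }
    for (rep_i in seq_len(n_reps)) {
      sel <- unlist(lapply(cell_rows, function(r)
        if (length(r) == 1) r else sample(r, max(1, round(f * length(r))))),
        use.names = FALSE)
      sel <- sort(sel)  # original row order; fraction 1.0 is then exact
      sub <- trials[sel, , drop = FALSE]
      p_amp <- tryCatch(pooled_contrast(
        data.frame(value = sub$amp_value, subject = sub$subject,
                   condition = sub$condition, label = sub$label),
        cond_a, cond_b, alternative)$p, error = function(e) NA_real_)
      p_dec <- tryCatch(pooled_contrast(
        data.frame(value = sub$dec_value, subject = sub$subject,
                   condition = sub$condition, label = sub$label),
        cond_a, cond_b, alternative)$p, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <-
        data.frame(fraction = f, rep = rep_i,
                   method = c("amplitude", "decode"),
                   p = c(p_amp, p_dec))
    }
  }
  if (!length(rows)) {
    empty <- data.frame(fraction = numeric(0), method = character(0),
                        p = numeric(0))
    return(structure(list(curve = empty, reps = empty, cond_a = cond_a,
                          cond_b = cond_b), class = "power_curve"))
  }
  reps <- do.call(rbind, rows)
  curve <- do.call(rbind, lapply(split(
    reps, list(reps$fraction, reps$method), drop = TRUE), function(d)
      data.frame(fraction = d$fraction[1], method = d$method[1],
                 mean_p = mean(d$p, na.rm = TRUE),
                 median_p = stats::median(d$p, na.rm = TRUE),
                 n_reps = nrow(d))))
  rownames(curve) <- NULL
  structure(list(curve = curve, reps = reps, cond_a = cond_a,
                 cond_b = cond_b), class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat("<power_curve>", x$cond_a, "vs", x$cond_b, "\n")
  print(x$curve)
  invisible(x)
}

#' Reaction-time tertiles
#'
#' Splits trials into fast / medium / slow groups at the 33rd and 66th
#' percentiles (linear-interpolation percentiles): fast `rt < q33`, medium
#' `q33 <= rt < q66`, slow `rt >= q66`.
#'
#' @param rts Finite reaction times, seconds.
#' @return List with index vectors `fast`, `medium`, `slow` and the
#'   `cutoffs`.
#' @export
rt_tertiles <- function(rts) {
  if (length(rts) < 3) stop("need at least 3 reaction times")
  if (any(!is.finite(rts))) stop("non-finite reaction times")
  q <- stats::quantile(rts, c(0.33, 0.66), names = FALSE, type = 7)
  if (q[1] == q[2])
    warning("degenerate RT cutoffs; groups will be unbalanced")
  list(fast = which(rts < q[1]),
       medium = which(rts >= q[1] & rts < q[2]),
       slow = which(rts >= q[2]),
       cutoffs = q)
}

#' Mode of a fitted lognormal latency distribution
#'
#' Maximum-likelihood lognormal fit to raw latencies; returns the density
#' mode `exp(mu - sigma^2)`, the most common stimulus-to-fixation latency.
#'
#' @param latencies Positive latencies, seconds.
#' @return The mode, seconds.
#' @export
lognormal_mode <- function(latencies) {
  if (any(!is.finite(latencies)) || any(latencies <= 0))
    stop("latencies must be positive and finite")
  lx <- log(latencies)
  mu <- mean(lx)
  sigma2 <- mean((lx - mu)^2)  # MLE variance
  exp(mu - sigma2)
}

#' Split traces by fixation latency
#'
#' Short latencies are strictly below the threshold; long latencies are
#' greater than or equal to it.
#'
#' @param traces A `trace_set`.
#' @param latencies One latency per trace, seconds.
#' @param threshold_s Split threshold, seconds.
#' @return List with `short` and `long` `trace_set`s and `sizes`.
#' @export
latency_split <- function(traces, latencies, threshold_s) {
  stopifnot(inherits(traces, "trace_set"))
  if (length(latencies) != nrow(traces$probs))
    stop("need one latency per trace")
  if (anyNA(latencies)) stop("missing latencies")
  short <- latencies < threshold_s
  if (!any(short)) warning("threshold below all latencies; short group empty")
  if (all(short)) warning("threshold above all latencies; long group empty")
  list(short = subset_traces(traces, short),
       long = subset_traces(traces, !short),
       sizes = c(short = sum(short), long = sum(!short)))
}

#' Per-trial values for the downselection analysis
#'
#' Convenience builder: computes, for the same trials, the 400-850 ms ROI
#' amplitude value from `epochs` and the T = 0 decoder output from
#' `traces`, which must be aligned row-for-row.
#'
#' @param epochs An `epoch_set`.
#' @param traces The matching `trace_set` (same trial order).
#' @param window Amplitude window, seconds.
#' @param roi ROI channels.
#' @return A data.frame suitable for [downselect_power_curve()].
#' @export
trial_values <- function(epochs, traces, window = c(0.400, 0.850),
                         roi = roi_channels()) {
  stopifnot(nrow(traces$probs) == dim(epochs$data)[1])
  tr <- roi_average(epochs, roi)
  data.frame(subject = epochs$meta$subject,
             condition = epochs$meta$condition,
             label = epochs$labels,
             amp_value = window_mean(tr, window),
             dec_value = trace_at(traces, 0),
             stringsAsFactors = FALSE)
}
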