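#' Write / read an event table
#'
#' Tab-separated with columns `onset_s`, `label`, `subject`, `experiment`,
#' `condition`, `rt_s`, `fixation_latency_s`.
#'
#' @param events Event data.frame.
#' @param path Output path.
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(ev$label), c("target", "distractor", "background"))
  if (length(bad))
    stop("unknown event label(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  if (any(ev$onset_s < 0)) stop("negative onsets in ", path)
  ev
}

#' Write / read a recording container
#'
#' Stores the channels x samples array as little-endian float64 binary with
#' a JSON sidecar (`<path>.json`) carrying `sample_rate_hz`,
#' `channel_names`, `subject`, `experiment` and the array shape.
#'
#' @param rec A `recording`.
#' @param path Path of the binary payload (sidecar is `<path>.json`).
#' @return `path`, invisibly (writer); a `recording` (reader).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  meta <- list(sample_rate_hz = rec$sample_rate_hz,
               channel_names = rec$channel_names,
               subject = rec$subject, experiment = rec$experiment,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  recording(matrix(x, meta$n_channels, meta$n_samples),
            meta$sample_rate_hz, meta$channel_names, meta$subject,
            meta$experiment)
}

#' Write decode traces as a long TSV
#'
#' One row per trial-window: trial metadata plus `time_s` and `prob`.
#' @param traces A `trace_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces_tsv <- function(traces, path) {
  n <- nrow(traces$probs); m <- length(traces$times_s)
  keep <- intersect(c("subject", "experiment", "condition", "label"),
                    names(traces$meta))
  long <- cbind(traces$meta[rep(seq_len(n), each = m), keep, drop = FALSE],
                data.frame(time_s = rep(traces$times_s, n),
                           prob = as.vector(t(traces$probs))))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a decoder checkpoint
#'
#' JSON container embedding the model configuration, all weights and
#' batchnorm statistics, and the training manifest.
#'
#' @param decoder A `p300_decoder`.
#' @param path Output path.
#' @return `path`, invisibly (writer); a `p300_decoder` (reader).
#' @export
write_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "p300_decoder"))
  obj <- list(config = unclass(decoder$config),
              params = decoder$params, state = decoder$state,
              manifest = decoder$manifest)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config,
                 obj$config[c("n_channels", "n_samples",
                              "n_temporal_filters", "temporal_kernel_len",
                              "depth_multiplier", "separable_kernel_len",
                              "pool1", "pool2", "dropout_p", "n_classes")])
  params <- lapply(obj$params, function(p)
    if (is.matrix(p)) p else as.numeric(p))
  state <- lapply(obj$state, as.numeric)
  structure(list(config = cfg, params = params, state = state,
                 manifest = obj$manifest),
            class = "p300_decoder")
}
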