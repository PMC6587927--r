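#' Scenario configuration
#'
#' A scenario is a runnable preset mirroring one of the classic P300
#' manipulations on synthetic data: `similarity` (target vs distractor
#' amplitude ordering), `tti` (saturating amplitude vs target-to-target
#' interval), `workload` (amplitude drop with dual-task load), `snr_power`
#' (trial-downselection power curves for both measures), `rt_groups`
#' (reaction-time tertiles and jitter), `fixation_split` (latency split of
#' fixation-locked traces).
#'
#' @param scenario One of the six scenario names.
#' @param seed Mandatory integer seed for the whole run.
#' @param n_subjects Subjects per experiment.
#' @param n_train_trials Events per subject in each of the three training
#'   experiments.
#' @param n_test_trials Events per subject in the held-out experiment.
#' @param n_iterations Training passes over the pool.
#' @param stride Sliding-window stride, samples.
#' @param fractions Downselection fractions (snr_power only).
#' @param n_reps Downselection repetitions per fraction (snr_power only).
#' @param tau_s Saturation time constant of the TTI amplitude rule, seconds.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(scenario = c("similarity", "tti", "workload",
                                         "snr_power", "rt_groups",
                                         "fixation_split"),
                            seed = NULL, n_subjects = 2,
                            n_train_trials = 200, n_test_trials = 300,
                            n_iterations = 20, stride = 4L,
                            fractions = c(0.1, 0.25, 0.5, 0.75, 1.0),
                            n_reps = 100, tau_s = 2.5) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, seed = seed, n_subjects = n_subjects,
                 n_train_trials = n_train_trials,
                 n_test_trials = n_test_trials,
                 n_iterations = n_iterations, stride = as.integer(stride),
                 fractions = fractions, n_reps = n_reps, tau_s = tau_s),
            class = "scenario_config")
}

#' Validate a scenario configuration
#'
#' Schema and invariant violations are reported as findings, not raised;
#' an empty result means the configuration is runnable.
#'
#' @param config A `scenario_config` (or bare list).
#' @return Character vector of findings (empty if valid).
#' @export
validate_config <- function(config) {
  findings <- character(0)
  note <- function(msg) findings <<- c(findings, msg)
  allowed <- c("similarity", "tti", "workload", "snr_power", "rt_groups",
               "fixation_split")
  if (is.null(config$scenario) || !config$scenario %in% allowed)
    note(paste0("scenario: must be one of ",
                paste(allowed, collapse = ", ")))
  if (is.null(config$seed) || !is.finite(config$seed))
    note("seed: seed required")
  if (!is.null(config$tau_s) && config$tau_s <= 0)
    note("tau_s: TTI time constant must be > 0")
  for (fld in c("n_subjects", "n_train_trials", "n_test_trials"))
    if (!is.null(config[[fld]]) && config[[fld]] < 1)
      note(paste0(fld, ": must be >= 1"))
  if (!is.null(config$fractions) &&
      (any(config$fractions <= 0) || any(config$fractions > 1)))
    note("fractions: must lie in (0, 1]")
  if (!is.null(config$stride) && config$stride < 1)
    note("stride: must be >= 1")
  findings
}

# three heterogeneous training experiments (class mixes spanning the
# sparse ratios typical of RSVP target detection)
training_specs <- function(config) {
  ratios <- list(c(1, 1, 10), c(1, 0, 22), c(1, 0, 9))
  lapply(1:3, function(i)
    experiment_spec(paste0("EXP", i), n_subjects = config$n_subjects,
                    n_trials_per_subject = config$n_train_trials,
                    conditions = list(condition_spec(
                      name = "train", class_ratio = ratios[[i]],
                      jitter_sd_s = 0.04, isi_s = 1.0)),
                    seed = (config$seed %% 100003) * 13 + i))
}

heldout_spec <- function(config) {
  seed4 <- (config$seed %% 100003) * 13 + 4
  ns <- config$n_subjects; nt <- config$n_test_trials
  switch(config$scenario,
    similarity = experiment_spec("EXP4", ns, nt,
      conditions = list(condition_spec("similarity",
        class_ratio = c(1, 1, 2), similarity = 0.6, jitter_sd_s = 0.04,
        isi_s = 1.5)), seed = seed4),
    tti = experiment_spec("EXP4", ns, nt,
      conditions = lapply(c(1.8, 2.2, 2.8, 3.9, 6.5, 17.4), function(tti)
        condition_spec(sprintf("tti%.1f", tti), class_ratio = c(1, 0, 0),
                       isi_s = tti, jitter_sd_s = 0.04,
                       tti_model = list(tau_s = config$tau_s))),
      seed = seed4),
    workload = ,
    snr_power = experiment_spec("EXP4", ns, nt,
      conditions = list(
        condition_spec("Silent", amplitude_scale = 1.0,
                       class_ratio = c(1, 0, 2), jitter_sd_s = 0.05,
                       isi_s = 1.5),
        condition_spec("2-Back", amplitude_scale = 0.7,
                       latency_shift_s = 0.03, class_ratio = c(1, 0, 2),
                       jitter_sd_s = 0.05, isi_s = 1.5)),
      seed = seed4),
    rt_groups = experiment_spec("EXP4", ns, nt,
      conditions = list(condition_spec("rt", class_ratio = c(1, 0, 2),
                                       jitter_sd_s = 0.1, isi_s = 1.5)),
      seed = seed4),
    fixation_split = experiment_spec("EXP4", ns, nt,
      conditions = list(
        condition_spec("fixlock", latency_shift_s = 0,
                       class_ratio = c(1, 0, 2), jitter_sd_s = 0.04,
                       locking = "fixation", isi_s = 1.5,
                       fixation_latency = list(meanlog = -2.2,
                                               sdlog = 0.3)),
        condition_spec("stimlock", latency_shift_s = 0.2,
                       class_ratio = c(1, 0, 2), jitter_sd_s = 0.04,
                       locking = "fixation", isi_s = 1.5,
                       fixation_latency = list(meanlog = -1.0,
                                               sdlog = 0.3))),
      seed = seed4))
}

config_fingerprint <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' Run a scenario end to end
#'
#' Simulates the scenario's four-experiment database, trains the decoder
#' leave-one-experiment-out (experiment 4 held out), sliding-decodes the
#' held-out events, runs the scenario's analysis, and writes a report
#' bundle: `traces.tsv`, scenario result tables, and `manifest.json`
#' (package version, scenario, seed, config fingerprint) sufficient to
#' reproduce the run.
#'
#' @param config A valid [scenario_config()].
#' @param outdir Output directory (created if needed).
#' @param decoder Optional pre-trained decoder to reuse (skips training).
#' @return The report bundle as a list (`scenario`, `manifest`, `results`,
#'   `files`).
#' @export
run_scenario <- function(config, outdir, decoder = NULL) {
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid config: ", paste(findings, collapse = "; "))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)

  specs <- c(training_specs(config), list(heldout_spec(config)))
  dbs <- simulate_database(specs)
  if (is.null(decoder))
    decoder <- train_leave_one_experiment_out(
      dbs, "EXP4", n_iterations = config$n_iterations,
      seed = config$seed)
  test_db <- dbs$EXP4
  traces <- decode_traces(decoder, test_db, stride = config$stride)
  write_traces_tsv(traces, file.path(outdir, "traces.tsv"))

  results <- list()
  lab <- traces$meta$label
  if (config$scenario == "similarity") {
    traces$meta$class <- traces$meta$label
    avg <- average_traces(traces, "class")
    t0 <- trace_at(traces, 0)
    m <- tapply(t0, traces$meta$label, mean)
    results$mean_traces <- avg
    results$t0_means <- m
    results$ordering_ok <- isTRUE(m[["target"]] > m[["distractor"]] &&
                                    m[["distractor"]] > m[["background"]])
    utils::write.table(avg, file.path(outdir, "mean_traces.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (config$scenario == "tti") {
    t0 <- trace_at(traces, 0)
    m <- tapply(t0[lab == "target"], traces$meta$condition[lab == "target"],
                mean)
    ttis <- as.numeric(sub("^tti", "", names(m)))
    results$t0_by_tti <- data.frame(tti_s = ttis, mean_t0 = as.numeric(m))
    results$spearman_rho <- stats::cor(ttis, as.numeric(m),
                                       method = "spearman")
    utils::write.table(results$t0_by_tti,
                       file.path(outdir, "tti_means.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (config$scenario %in% c("workload", "snr_power")) {
    ep <- prepare_epochs(test_db)
    ctr_amp <- amplitude_contrast(ep, "Silent", "2-Back")
    ctr_dec <- decode_contrast(traces, "Silent", "2-Back")
    ctab <- data.frame(method = c("amplitude", "decode"),
                       cond_a = "Silent", cond_b = "2-Back",
                       t = c(ctr_amp$t, ctr_dec$t),
                       p = c(ctr_amp$p, ctr_dec$p),
                       n_a = c(ctr_amp$n["a"], ctr_dec$n["a"]),
                       n_b = c(ctr_amp$n["b"], ctr_dec$n["b"]))
    utils::write.table(ctab, file.path(outdir, "contrast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$contrasts <- ctab
    if (config$scenario == "snr_power") {
      tv <- trial_values(ep, traces)
      pc <- downselect_power_curve(tv, "Silent", "2-Back",
                                   fractions = config$fractions,
                                   n_reps = config$n_reps,
                                   seed = config$seed)
      utils::write.table(pc$curve, file.path(outdir, "power.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$power_curve <- pc
    }
  } else if (config$scenario == "rt_groups") {
    tg <- subset_traces(traces, lab == "target")
    grp <- rt_tertiles(tg$meta$rt_s)
    tg$meta$rt_group <- NA_character_
    for (g in c("fast", "medium", "slow"))
      tg$meta$rt_group[grp[[g]]] <- g
    avg <- average_traces(tg, "rt_group")
    utils::write.table(avg, file.path(outdir, "rt_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$rt_cutoffs <- grp$cutoffs
    results$group_traces <- avg
  } else if (config$scenario == "fixation_split") {
    tg <- subset_traces(traces, lab == "target")
    thr <- lognormal_mode(
      tg$meta$fixation_latency_s[tg$meta$condition == "fixlock"])
    sp <- latency_split(tg, tg$meta$fixation_latency_s, thr)
    peak_of <- function(ts) {
      a <- average_traces(ts)
      a$time_s[which.max(a$mean)]
    }
    results$threshold_s <- thr
    results$sizes <- sp$sizes
    results$peak_short_s <- peak_of(sp$short)
    results$peak_long_s <- peak_of(sp$long)
    utils::write.table(
      data.frame(group = c("short", "long"),
                 n = as.integer(sp$sizes),
                 peak_s = c(results$peak_short_s, results$peak_long_s),
                 threshold_s = thr),
      file.path(outdir, "fixation_split.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  manifest <- list(
    package = "p300decode",
    version = as.character(utils::packageVersion("p300decode")),
    scenario = config$scenario, seed = config$seed,
    config = unclass(config),
    config_fingerprint = config_fingerprint(config),
    stride = config$stride,
    decoder_manifest = decoder$manifest,
    n_events_decoded = nrow(traces$meta))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scenario = config$scenario, manifest = manifest,
                 results = results,
                 files = list.files(outdir, full.names = TRUE),
                 decoder = decoder, traces = traces))
}
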