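# Shared, lazily built fixtures. The cross-experiment decoder is expensive
# to train, so every test that needs a trained network reuses the same one;
# the synthetic databases are small enough to rebuild but are memoised too
# so the suite stays inside its time budget. All seeds are fixed.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]]))
    assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

fix_template <- function() fixture("template", function()
  make_template(jitter_sd_s = 0.04))

# four-experiment world: three heterogeneous training experiments plus a
# perceptual-similarity test experiment with 300 trials per class
# (target : distractor : background = 1 : 1 : 2 over 2 x 600 events)
fix_config <- function() scenario_config("similarity", seed = 101,
                                         n_subjects = 2,
                                         n_train_trials = 260,
                                         n_test_trials = 600,
                                         n_iterations = 20)

fix_dbs <- function() fixture("dbs", function() {
  cfg <- fix_config()
  simulate_database(c(p300decode:::training_specs(cfg),
                      list(p300decode:::heldout_spec(cfg))),
                    template = fix_template())
})

fix_decoder <- function() fixture("decoder", function()
  train_leave_one_experiment_out(fix_dbs(), "EXP4", n_iterations = 20,
                                 seed = 101))

fix_sim_epochs <- function() fixture("sim_epochs", function()
  prepare_epochs(fix_dbs()$EXP4))

fix_sim_t0 <- function() fixture("sim_t0", function()
  predict_decoder(fix_decoder(), fix_sim_epochs()))

# target-to-target-interval experiment: six all-target conditions whose
# amplitudes follow the saturating recovery rule
fix_ttis <- function() c(1.8, 2.2, 2.8, 3.9, 6.5, 17.4)

fix_tti_db <- function() fixture("tti_db", function() {
  spec <- experiment_spec("TTI", 2, 300,
    conditions = lapply(fix_ttis(), function(tti) condition_spec(
      sprintf("tti%.1f", tti), class_ratio = c(1, 0, 0), isi_s = tti,
      jitter_sd_s = 0.04, tti_model = list(tau_s = 2.5))), seed = 707)
  simulate_experiment(spec, fix_template())
})

# latency-shift / jitter experiment (equal amplitudes):
#   base:   shift 0 s,    jitter sd 0.031 s
#   shift:  shift +0.1 s, jitter sd 0.031 s
#   jitter: shift 0 s,    jitter sd 0.135 s
fix_shift_db <- function() fixture("shift_db", function() {
  spec <- experiment_spec("SH", 2, 450,
    conditions = list(
      condition_spec("base", latency_shift_s = 0, jitter_sd_s = 0.031,
                     class_ratio = c(1, 0, 1), isi_s = 1.5),
      condition_spec("shift", latency_shift_s = 0.1, jitter_sd_s = 0.031,
                     class_ratio = c(1, 0, 1), isi_s = 1.5),
      condition_spec("jitter", latency_shift_s = 0, jitter_sd_s = 0.135,
                     class_ratio = c(1, 0, 1), isi_s = 1.5)),
    seed = 808)
  simulate_experiment(spec, fix_template())
})

fix_shift_traces <- function() fixture("shift_traces", function() {
  db <- fix_shift_db()
  decode_traces(fix_decoder(), db,
                db$events[db$events$label == "target", ])
})

# workload experiment (Silent amplitude 1.0 vs 2-Back amplitude 0.7)
fix_wl_db <- function() fixture("wl_db", function() {
  spec <- experiment_spec("WL", 2, 300,
    conditions = list(
      condition_spec("Silent", amplitude_scale = 1.0,
                     class_ratio = c(1, 0, 2), jitter_sd_s = 0.05,
                     isi_s = 1.5),
      condition_spec("2-Back", amplitude_scale = 0.7,
                     latency_shift_s = 0.03, class_ratio = c(1, 0, 2),
                     jitter_sd_s = 0.05, isi_s = 1.5)),
    seed = 909)
  simulate_experiment(spec, fix_template())
})

fix_wl_epochs <- function() fixture("wl_epochs", function()
  prepare_epochs(fix_wl_db()))

fix_wl_traces <- function() fixture("wl_traces", function()
  decode_traces(fix_decoder(), fix_wl_db()))

fix_trial_values <- function() fixture("trial_values", function()
  trial_values(fix_wl_epochs(), fix_wl_traces()))

fix_power_curve <- function() fixture("power_curve", function()
  downselect_power_curve(fix_trial_values(), "Silent", "2-Back",
                         fractions = c(0.1, 0.25, 0.5, 0.75, 1.0),
                         n_reps = 100, seed = 11))

# rank-based AUC
auc_score <- function(p, y) {
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# tiny noiseless world for cheap exact checks
noiseless_db <- function(n_trials = 40, jitter = 0, seed = 3,
                         ratio = c(1, 0, 1), isi = 3) {
  spec <- experiment_spec("E1", 1, n_trials,
    conditions = list(condition_spec(class_ratio = ratio, isi_s = isi,
                                     jitter_sd_s = jitter)),
    noise = noise_spec(onef_sd = 0, osc_amp = 0, white_sd = 0), seed = seed)
  simulate_experiment(spec, fix_template())
}
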