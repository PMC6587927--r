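# Decoder: architecture contracts, sample weighting, training behaviour.

rand_epochs <- function(n, labels, cfg = model_config(), sd = 1,
                        experiment = "E1", seed = 1) {
  set.seed(seed)
  structure(list(
    data = array(rnorm(n * cfg$n_channels * cfg$n_samples, sd = sd),
                 dim = c(n, cfg$n_channels, cfg$n_samples)),
    labels = labels, window = c(0, 1), sample_rate_hz = 128,
    channel_names = sprintf("ch%02d", seq_len(cfg$n_channels)),
    meta = data.frame(experiment = rep(experiment, n),
                      subject = "s01")), class = "epoch_set")
}

small_cfg <- model_config(n_channels = 8, n_samples = 32,
                          n_temporal_filters = 2, temporal_kernel_len = 16,
                          depth_multiplier = 2, separable_kernel_len = 8,
                          pool1 = 4, pool2 = 8)

test_that("architecture: softmax outputs, compact parameter count, F1 scaling", {
  dec <- build_model(model_config(), seed = 2)
  X <- array(rnorm(5 * 64 * 128), dim = c(64, 128, 5))
  res <- p300decode:::eegnet_pass(X, integer(0), numeric(0), dec$params,
                                  dec$state, unclass(dec$config), FALSE,
                                  FALSE, 0, 0.99, 1L)
  expect_true(all(res$probs >= 0 & res$probs <= 1))
  expect_equal(colSums(res$probs), rep(1, 5))

  # hand count of the stated layer stack at 64 channels:
  # 4*64 conv + 2*(4) bn + 8*64 spatial + 2*8 bn + 8*16 + 8*8 separable
  # + 2*8 bn + (2*32 + 2) dense = 1066
  expect_equal(n_params(dec), 1066L)
  expect_lt(n_params(dec), 5000)

  dec2 <- build_model(model_config(n_temporal_filters = 8), seed = 2)
  expect_equal(nrow(dec2$params$W1), 2L * nrow(dec$params$W1))

  expect_error(model_config(temporal_kernel_len = 256), "exceed")
})

test_that("sample weights: printed example, identity, two-experiment cell sums", {
  w <- compute_sample_weights(rep(c(1, 0), c(100, 400)))
  expect_equal(sort(unique(w)), c(1, 4))

  wb <- compute_sample_weights(rep(c(1, 0), each = 50))
  expect_true(all(wb == 1))

  lab <- c(rep(c(1, 0), c(200, 800)), rep(c(1, 0), c(100, 400)))
  exps <- rep(c("A", "B"), c(1000, 500))
  w2 <- compute_sample_weights(lab, exps)
  sums <- tapply(w2, paste(lab, exps), sum)
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-9)

  # class 0 exists in experiment A but is empty in experiment B
  expect_error(compute_sample_weights(c(1, 0, 1), c("A", "A", "B")),
               "empty \\(class, experiment\\) cell")
})

test_that("training: zero iterations is identity, single class errors, seeded determinism", {
  ep <- rand_epochs(64, rep(c(0L, 1L), 32), small_cfg, seed = 4)
  dec <- build_model(small_cfg, seed = 3)
  same <- train_decoder(dec, ep, n_iterations = 0, seed = 1)
  expect_identical(same$params, dec$params)

  ep1 <- rand_epochs(20, rep(1L, 20), small_cfg)
  expect_error(train_decoder(dec, ep1, n_iterations = 1), "single class")

  a <- train_decoder(dec, ep, n_iterations = 3, seed = 11)
  b <- train_decoder(dec, ep, n_iterations = 3, seed = 11)
  expect_equal(a$manifest$loss_trajectory, b$manifest$loss_trajectory,
               tolerance = 1e-12)
  expect_identical(a$params, b$params)
})

test_that("weighted loss decreases in trend on the real training pool", {
  traj <- fix_decoder()$manifest$loss_trajectory
  expect_lt(mean(tail(traj, 3)), mean(head(traj, 3)))
})

test_that("pure-noise pool with random labels decodes at chance", {
  set.seed(12)
  n <- 360
  labs <- sample(rep(c(0L, 1L), n / 2))
  ep <- rand_epochs(n, labs, seed = 13)
  dec <- build_model(model_config(), seed = 14)
  dec <- train_decoder(dec, ep, n_iterations = 2, seed = 15)
  test <- rand_epochs(120, sample(rep(c(0L, 1L), 60)), seed = 16)
  acc <- mean((predict_decoder(dec, test) > 0.5) == (test$labels == 1))
  expect_lt(abs(acc - 0.5), 2.58 * sqrt(0.25 / 120) + 0.05)
})

test_that("leave-one-experiment-out excludes the held-out experiment", {
  db1 <- noiseless_db(30, seed = 71)
  spec2 <- experiment_spec("E2", 1, 30,
    conditions = list(condition_spec(class_ratio = c(1, 0, 1), isi_s = 3)),
    noise = noise_spec(onef_sd = 0, osc_amp = 0, white_sd = 0.1),
    seed = 72)
  db2 <- simulate_experiment(spec2, fix_template())
  dec <- train_leave_one_experiment_out(list(db1, db2), "E2",
                                        n_iterations = 1, seed = 1)
  expect_identical(dec$manifest$experiments, "E1")
  expect_identical(dec$manifest$heldout, "E2")
  expect_error(train_leave_one_experiment_out(list(db1, db2), "E9"),
               "E9")
  expect_error(train_leave_one_experiment_out(list(db1), "E1"),
               "at least 2")
})

test_that("trained decoder tolerates small temporal jitter of the epoch", {
  db <- fix_dbs()$EXP4
  rec <- preprocess_recording(db$recordings[[1]])
  ev <- db$events[db$events$subject == "s01" &
                    db$events$label == "target", ][1:60, ]
  p0 <- predict_decoder(fix_decoder(), epoch_events(rec, ev))
  shift <- ev; shift$onset_s <- shift$onset_s + 4 / 128
  p_plus <- predict_decoder(fix_decoder(), epoch_events(rec, shift))
  shift$onset_s <- ev$onset_s - 4 / 128
  p_minus <- predict_decoder(fix_decoder(), epoch_events(rec, shift))
  expect_lt(mean(abs(p_plus - p0)), 0.15)
  expect_lt(mean(abs(p_minus - p0)), 0.15)
})

test_that("cross-experiment transfer separates classes on easy synthetic data", {
  ep <- fix_sim_epochs()
  expect_gt(auc_score(fix_sim_t0(), ep$labels), 0.9)
})

test_that("backpropagation matches finite differences on a tiny network", {
  cfg <- model_config(n_channels = 4, n_samples = 32,
                      n_temporal_filters = 2, temporal_kernel_len = 8,
                      depth_multiplier = 2, separable_kernel_len = 4,
                      pool1 = 4, pool2 = 8, dropout_p = 0)
  dec <- build_model(cfg, seed = 7)
  set.seed(42)
  X <- array(rnorm(4 * 32 * 5), dim = c(4, 32, 5))
  y <- c(0L, 1L, 0L, 1L, 1L)
  w <- runif(5, 0.5, 2)
  lossfn <- function(params)
    p300decode:::eegnet_pass(X, y, w, params, dec$state, unclass(cfg),
                             TRUE, FALSE, 0, 0.99, 1L)$loss
  g <- p300decode:::eegnet_pass(X, y, w, dec$params, dec$state,
                                unclass(cfg), TRUE, TRUE, 0, 0.99,
                                1L)$grads
  eps <- 1e-6
  for (nm in c("W1", "W2", "g2", "W3", "W4", "b3", "W5")) {
    i <- sample(length(dec$params[[nm]]), 1)
    pp <- dec$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- dec$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
    expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
  }
})
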