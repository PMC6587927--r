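#' Decoder configuration
#'
#' Hyperparameters of the compact convolutional decoder: `F1` temporal
#' filters of length `temporal_kernel_len` samples, `depth_multiplier`
#' spatial filters per temporal filter (so `F2 = F1 * D` separable filters),
#' average pooling by 4 then 8, a 1 x 16 separable kernel, ELU
#' nonlinearities, and dropout 0.25 on both pooled stages.
#'
#' @param n_channels Number of EEG channels.
#' @param n_samples Epoch length in samples (128 for a 1 s epoch at 128 Hz).
#' @param n_temporal_filters `F1`.
#' @param temporal_kernel_len Temporal kernel length in samples.
#' @param depth_multiplier `D`, spatial filters per temporal filter.
#' @param separable_kernel_len Separable (depthwise temporal) kernel length.
#' @param pool1,pool2 Average-pooling widths after the two conv blocks.
#' @param dropout_p Dropout probability for all dropout layers.
#' @param n_classes Number of output classes.
#' @return A `model_config`.
#' @export
model_config <- function(n_channels = 64, n_samples = 128,
                         n_temporal_filters = 4, temporal_kernel_len = 64,
                         depth_multiplier = 2, separable_kernel_len = 16,
                         pool1 = 4, pool2 = 8, dropout_p = 0.25,
                         n_classes = 2) {
  if (temporal_kernel_len > n_samples)
    stop("temporal_kernel_len must not exceed n_samples")
  if (n_samples %% pool1 != 0 || (n_samples / pool1) %% pool2 != 0)
    stop("n_samples must be divisible by pool1 * pool2")
  cfg <- list(n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              n_temporal_filters = as.integer(n_temporal_filters),
              temporal_kernel_len = as.integer(temporal_kernel_len),
              depth_multiplier = as.integer(depth_multiplier),
              n_separable_filters = as.integer(n_temporal_filters *
                                                 depth_multiplier),
              separable_kernel_len = as.integer(separable_kernel_len),
              pool1 = as.integer(pool1), pool2 = as.integer(pool2),
              dropout_p = dropout_p, n_classes = as.integer(n_classes))
  class(cfg) <- "model_config"
  cfg
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained decoder
#'
#' Initializes all weights (Glorot-uniform convolutions, unit batchnorm
#' scales, zero biases). The untrained network already emits valid softmax
#' probabilities.
#'
#' @param config A [model_config()].
#' @param seed RNG seed for the initialization.
#' @return A `p300_decoder` (fields `config`, `params`, `state`,
#'   `manifest`).
#' @export
build_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  F1 <- config$n_temporal_filters; K <- config$temporal_kernel_len
  F2 <- config$n_separable_filters; C <- config$n_channels
  K2 <- config$separable_kernel_len
  T3 <- config$n_samples / config$pool1 / config$pool2
  params <- list(
    W1 = glorot(F1, K, K, F1 * K),
    g1 = rep(1, F1), b1 = rep(0, F1),
    W2 = glorot(F2, C, C, C * config$depth_multiplier),
    g2 = rep(1, F2), b2 = rep(0, F2),
    W3 = glorot(F2, K2, K2, K2),
    W4 = glorot(F2, F2, F2, F2),
    g3 = rep(1, F2), b3 = rep(0, F2),
    W5 = glorot(config$n_classes, F2 * T3, F2 * T3, config$n_classes),
    b5 = rep(0, config$n_classes))
  state <- list(rm1 = rep(0, F1), rv1 = rep(1, F1),
                rm2 = rep(0, F2), rv2 = rep(1, F2),
                rm3 = rep(0, F2), rv3 = rep(1, F2))
  structure(list(config = config, params = params, state = state,
                 manifest = NULL),
            class = "p300_decoder")
}

#' Number of trainable parameters
#' @param decoder A `p300_decoder`.
#' @return Integer parameter count.
#' @export
n_params <- function(decoder) {
  sum(vapply(decoder$params, length, integer(1)))
}

#' @export
print.p300_decoder <- function(x, ...) {
  cat(sprintf("<p300_decoder> %d ch x %d samples, %d parameters, %s\n",
              x$config$n_channels, x$config$n_samples, n_params(x),
              if (is.null(x$manifest)) "untrained" else
                paste0("trained on ",
                       paste(x$manifest$experiments, collapse = "+"))))
  invisible(x)
}

#' Class- and experiment-balancing sample weights
#'
#' Within each experiment, a class's weight is the count of that
#' experiment's largest class divided by the count of this class (so the
#' majority class is anchored at 1); each experiment's weight is the largest
#' experiment's trial count divided by this experiment's trial count. The
#' final per-trial weight is the product, which makes the summed weight
#' identical across every (class, experiment) cell - the operational meaning
#' of each class and experiment contributing equally to training.
#'
#' @param labels Per-trial class labels (any atomic type).
#' @param experiment_ids Per-trial experiment identifiers.
#' @return Numeric weight per trial (class `sample_weights`).
#' @export
compute_sample_weights <- function(labels,
                                   experiment_ids = rep("EXP1",
                                                        length(labels))) {
  stopifnot(length(labels) == length(experiment_ids), length(labels) > 0)
  labels <- as.character(labels)
  experiment_ids <- as.character(experiment_ids)
  classes <- sort(unique(labels))
  exps <- sort(unique(experiment_ids))
  exp_n <- vapply(exps, function(e) sum(experiment_ids == e), numeric(1))
  exp_w <- max(exp_n) / exp_n
  w <- numeric(length(labels))
  for (e in exps) {
    in_e <- experiment_ids == e
    cls_n <- vapply(classes, function(cl) sum(labels[in_e] == cl),
                    numeric(1))
    if (any(cls_n == 0))
      stop(sprintf("empty (class, experiment) cell: class '%s' in '%s'",
                   classes[which(cls_n == 0)[1]], e))
    cls_w <- max(cls_n) / cls_n
    w[in_e] <- cls_w[match(labels[in_e], classes)] * exp_w[[e]]
  }
  class(w) <- c("sample_weights", "numeric")
  w
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

renorm_rows <- function(w, max_norm) {
  r <- sqrt(rowSums(w^2))
  s <- pmin(1, max_norm / pmax(r, 1e-12))
  w * s
}

#' Train the decoder
#'
#' Minibatch training with the Adam optimizer (default settings) on a
#' weighted categorical cross-entropy loss. One iteration is one full pass
#' over the training pool. Max-norm constraints are applied after every
#' update: 1.0 on each spatial filter, 0.25 on each dense row. A fixed seed
#' reproduces the loss trajectory exactly.
#'
#' @param decoder An untrained (or previously trained) `p300_decoder`.
#' @param epochs An `epoch_set` training pool.
#' @param weights Per-trial sample weights; default
#'   [compute_sample_weights()] on the pool's labels and experiments.
#' @param n_iterations Number of passes over the pool.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed controlling shuffling and dropout.
#' @return The trained `p300_decoder`, with a `manifest` recording the
#'   training experiments, iteration count, seed and loss trajectory.
#' @export
train_decoder <- function(decoder, epochs, weights = NULL,
                          n_iterations = 100, batch_size = 64, lr = 1e-3,
                          seed = 1) {
  stopifnot(inherits(decoder, "p300_decoder"),
            inherits(epochs, "epoch_set"))
  y <- as.integer(epochs$labels)
  if (length(unique(y)) < 2)
    stop("training pool contains a single class")
  n <- length(y)
  if (is.null(weights)) {
    exps <- if (!is.null(epochs$meta$experiment)) epochs$meta$experiment
            else rep("EXP1", n)
    weights <- compute_sample_weights(y, exps)
  }
  stopifnot(length(weights) == n, all(weights > 0))
  X <- aperm(epochs$data, c(2, 3, 1))  # C x T x N
  cfg <- decoder$config
  stopifnot(dim(X)[1] == cfg$n_channels, dim(X)[2] == cfg$n_samples)
  params <- decoder$params
  state <- decoder$state
  opt <- adam_init(params)
  set.seed(seed)
  losses <- numeric(0)
  if (n_iterations > 0) {
    for (it in seq_len(n_iterations)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        drop_seed <- sample.int(.Machine$integer.max, 1)
        res <- eegnet_pass(X[, , idx, drop = FALSE], y[idx], weights[idx],
                           params, state, unclass(cfg),
                           TRUE, TRUE, cfg$dropout_p, 0.99, drop_seed)
        state <- res$state
        upd <- adam_step(params, res$grads, opt, lr = lr)
        params <- upd$params; opt <- upd$opt
        params$W2 <- renorm_rows(params$W2, 1.0)
        params$W5 <- renorm_rows(params$W5, 0.25)
        batch_losses <- c(batch_losses, res$loss)
      }
      losses <- c(losses, mean(batch_losses))
    }
  }
  decoder$params <- params
  decoder$state <- state
  decoder$manifest <- list(
    experiments = sort(unique(as.character(
      if (!is.null(epochs$meta$experiment)) epochs$meta$experiment
      else "EXP1"))),
    n_trials = n, n_iterations = n_iterations, batch_size = batch_size,
    seed = seed, loss_trajectory = losses,
    final_loss = if (length(losses)) losses[length(losses)] else NA_real_)
  decoder
}

#' Decoder probabilities for a set of epochs
#'
#' Evaluation-mode forward pass (batchnorm running statistics, no dropout).
#'
#' @param decoder A `p300_decoder`.
#' @param epochs An `epoch_set`, or a trials x channels x samples array.
#' @param batch_size Evaluation batch size.
#' @return Numeric vector: probability of the P300 class per trial.
#' @export
predict_decoder <- function(decoder, epochs, batch_size = 256) {
  dat <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  stopifnot(length(dim(dat)) == 3)
  X <- aperm(dat, c(2, 3, 1))
  n <- dim(X)[3]
  out <- numeric(n)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    res <- eegnet_pass(X[, , idx, drop = FALSE], integer(0), numeric(0),
                       decoder$params, decoder$state,
                       unclass(decoder$config), FALSE, FALSE, 0, 0.99, 1L)
    out[idx] <- res$probs[2, ]
  }
  out
}

#' Leave-one-experiment-out training
#'
#' Pools the conditioned epochs of every experiment except the held-out one,
#' computes sample weights on that training pool only, and trains. The
#' held-out experiment contributes zero trials; the manifest lists exactly
#' the training experiments.
#'
#' @param databases List of `simulated_database` (one per experiment).
#' @param heldout_experiment_id Experiment to exclude.
#' @param config A [model_config()].
#' @param window Epoch window passed to [prepare_epochs()].
#' @param n_iterations,batch_size,lr,seed Training parameters.
#' @return A trained `p300_decoder`.
#' @export
train_leave_one_experiment_out <- function(databases, heldout_experiment_id,
                                           config = model_config(),
                                           window = c(0.0, 1.0),
                                           n_iterations = 100,
                                           batch_size = 64, lr = 1e-3,
                                           seed = 1) {
  ids <- vapply(databases, function(d) d$spec$experiment_id, character(1))
  if (!heldout_experiment_id %in% ids)
    stop("held-out experiment not in database list: ",
         heldout_experiment_id)
  if (length(ids) < 2)
    stop("leave-one-experiment-out needs at least 2 experiments")
  train_dbs <- databases[ids != heldout_experiment_id]
  pool <- combine_epochs(lapply(train_dbs, prepare_epochs, window = window))
  dec <- build_model(config, seed = seed)
  dec <- train_decoder(dec, pool, n_iterations = n_iterations,
                       batch_size = batch_size, lr = lr, seed = seed)
  dec$manifest$heldout <- heldout_experiment_id
  dec
}
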