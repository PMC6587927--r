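# Amplitude measurement and hypothesis testing.

mk_epochs <- function(data, meta, labels, window = c(0, 1), fs = 128) {
  structure(list(data = data, labels = labels, window = window,
                 sample_rate_hz = fs,
                 channel_names = standard_montage_64()$channel,
                 meta = meta), class = "epoch_set")
}

test_that("roi_average: identical channels, Pz-only signal, missing channel", {
  ch <- standard_montage_64()$channel
  n <- 3; L <- 16
  dat <- array(rep(1:L, each = n * 64), dim = c(n, 64, L))
  ep <- mk_epochs(dat, data.frame(subject = rep("s01", n)), rep(1L, n),
                  fs = 16)
  tr <- roi_average(ep)
  expect_equal(tr$values[1, ], as.numeric(1:L))

  dat2 <- array(0, dim = c(1, 64, L))
  dat2[1, match("Pz", ch), ] <- 6
  ep2 <- mk_epochs(dat2, data.frame(subject = "s01"), 1L, fs = 16)
  expect_true(all(roi_average(ep2)$values == 1))

  ep3 <- ep
  ep3$channel_names[match("CPz", ch)] <- "XX"
  expect_error(roi_average(ep3), "CPz")
})

test_that("window_mean: constant, linear ramp, zero, out-of-grid window", {
  tr <- list(times_s = (0:127) / 128,
             values = rbind(rep(3.5, 128), (0:127) / 128, rep(0, 128)))
  expect_equal(window_mean(tr), c(3.5, 0.625, 0))
  expect_error(window_mean(tr, c(2, 3)), "outside the trace grid")
})

test_that("contrasts: no-effect p = 0.5, baselining identity and invariance", {
  v <- rep(c(0.2, 0.5, 0.9, 0.4), 10)
  df <- data.frame(value = c(v, v, rep(0.1, 20)),
                   subject = "s01",
                   condition = c(rep("A", 40), rep("B", 40), rep("bg", 20)),
                   label = rep(c(1L, 0L), c(80, 20)))
  res <- p300decode:::pooled_contrast(df, "A", "B")
  expect_equal(res$p, 0.5)
  expect_true(res$p > 0 && res$p <= 1)

  # background-only "targets" are centred at zero after baselining
  df2 <- data.frame(value = rnorm(30, 5), subject = rep(c("s01", "s02"), 15),
                    condition = "A", label = 0L)
  df2t <- df2; df2t$label <- 1L; df2t$condition <- "A"
  both <- rbind(df2, df2t)
  res2 <- p300decode:::pooled_contrast(
    rbind(both, data.frame(value = 1, subject = c("s01", "s02"),
                           condition = "B", label = 1L,
                           row.names = NULL)), "A", "B",
    alternative = "two.sided")
  expect_equal(mean(res2$values_a), 0)

  # adding a per-subject constant to all trials leaves the result unchanged
  set.seed(20)
  df3 <- data.frame(value = rnorm(120),
                    subject = rep(c("s01", "s02"), 60),
                    condition = rep(c("A", "B", "bg"), each = 40),
                    label = rep(c(1L, 1L, 0L), each = 40))
  shifted <- df3
  shifted$value <- shifted$value + ifelse(shifted$subject == "s01", 10, -4)
  r1 <- p300decode:::pooled_contrast(df3, "A", "B")
  r2 <- p300decode:::pooled_contrast(shifted, "A", "B")
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)

  df4 <- df3[df3$subject == "s01" | df3$label == 1, ]
  expect_error(p300decode:::pooled_contrast(
    df4[!(df4$subject == "s02" & df4$label == 0), ], "A", "B"),
    "lacking background")
})

test_that("the one-tailed Welch test detects a 1.0 vs 0.7 amplitude effect", {
  # Monte-Carlo power of the implemented test at n = 200 per condition
  hits <- 0L
  for (s in 1:40) {
    set.seed(1000 + s)
    df <- data.frame(
      value = c(rnorm(200, 1.0, 0.3), rnorm(200, 0.7, 0.3), rnorm(50, 0)),
      subject = "s01",
      condition = rep(c("A", "B", "bg"), c(200, 200, 50)),
      label = rep(c(1L, 0L), c(400, 50)))
    if (p300decode:::pooled_contrast(df, "A", "B")$p < 0.01)
      hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # >= 95% of seeded runs
})

test_that("downselection: determinism, skip warning, power monotonicity", {
  tv <- fix_trial_values()
  a <- downselect_power_curve(tv, "Silent", "2-Back", fractions = 0.5,
                              n_reps = 1, seed = 42)
  b <- downselect_power_curve(tv, "Silent", "2-Back", fractions = 0.5,
                              n_reps = 1, seed = 42)
  expect_identical(a$reps$p, b$reps$p)

  expect_warning(
    downselect_power_curve(tv, "Silent", "2-Back", fractions = 0.01,
                           n_reps = 1, seed = 1), "skipped")

  pc <- fix_power_curve()
  for (m in c("amplitude", "decode")) {
    d <- pc$curve[pc$curve$method == m, ]
    d <- d[order(d$fraction), ]
    # mean p non-increasing in fraction, up to Monte-Carlo noise
    expect_true(all(diff(log10(d$mean_p)) < 0.5))
  }
})

test_that("rt_tertiles: percentile rule, tie handling, balanced sizes", {
  g <- rt_tertiles(1:9)
  expect_equal(g$fast, 1:3)
  expect_equal(g$medium, 4:6)
  expect_equal(g$slow, 7:9)

  expect_warning(g2 <- rt_tertiles(rep(0.5, 10)), "degenerate")
  expect_equal(sort(c(g2$fast, g2$medium, g2$slow)), 1:10)

  set.seed(30)
  r <- rlnorm(3000, -0.6, 0.3)
  g3 <- rt_tertiles(r)
  for (grp in c("fast", "medium", "slow"))
    expect_lt(abs(length(g3[[grp]]) / 1000 - 1), 0.06)
  expect_error(rt_tertiles(c(1, NA, 3)), "non-finite")
})

test_that("lognormal_mode: degenerate limit, parameter recovery, right skew", {
  expect_equal(lognormal_mode(rep(0.5, 10)), 0.5)
  set.seed(8)
  x <- rlnorm(10000, -1.517, 0.4)
  expect_lt(abs(lognormal_mode(x) / exp(-1.517 - 0.16) - 1), 0.05)
  expect_lt(lognormal_mode(x), median(x))
  expect_error(lognormal_mode(c(0.1, -0.2)), "positive")
})

test_that("latency_split: boundary rule and empty-group warning", {
  tt <- slide_times()
  tr <- structure(list(times_s = tt, probs = matrix(runif(3 * 65), 3),
                       meta = data.frame(id = 1:3)), class = "trace_set")
  sp <- latency_split(tr, c(0.1, 0.2194, 0.3), 0.2194)
  expect_equal(unname(sp$sizes), c(1L, 2L))
  expect_equal(sp$short$meta$id, 1L)
  expect_equal(sp$long$meta$id, 2:3)

  expect_warning(latency_split(tr, c(0.5, 0.6, 0.7), 0.1), "short group")
  expect_error(latency_split(tr, c(0.1, NA, 0.2), 0.2), "missing")
})

test_that("fixation-locked latency split: short group peaks nearer onset", {
  spec <- experiment_spec("FX", 1, 360,
    conditions = list(
      condition_spec("fixlock", latency_shift_s = 0,
                     class_ratio = c(1, 0, 1), jitter_sd_s = 0.04,
                     locking = "fixation", isi_s = 1.5,
                     fixation_latency = list(meanlog = -2.2, sdlog = 0.3)),
      condition_spec("stimlock", latency_shift_s = 0.2,
                     class_ratio = c(1, 0, 1), jitter_sd_s = 0.04,
                     locking = "fixation", isi_s = 1.5,
                     fixation_latency = list(meanlog = -1.0, sdlog = 0.3))),
    seed = 606)
  db <- simulate_experiment(spec, fix_template())
  ev <- db$events[db$events$label == "target", ]
  tr <- decode_traces(fix_decoder(), db, ev)
  thr <- lognormal_mode(ev$fixation_latency_s[ev$condition == "fixlock"])
  sp <- latency_split(tr, ev$fixation_latency_s, thr)
  peak_t <- function(ts) {
    a <- average_traces(ts)
    a$time_s[which.max(a$mean)]
  }
  expect_lt(abs(peak_t(sp$short)), abs(peak_t(sp$long)))
})
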