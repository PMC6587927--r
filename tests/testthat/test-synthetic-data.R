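# Synthetic EEG generator: template construction, evoked recovery,
# determinism, class ratios, spectral shape, jitter attenuation.

test_that("montage has 64 unique positions and the parietal ROI", {
  m <- standard_montage_64()
  expect_equal(nrow(m), 64L)
  expect_true(all(roi_channels() %in% m$channel))
  expect_false(anyDuplicated(paste(m$x, m$y)) > 0)
  expect_true(all(m$x^2 + m$y^2 <= 1 + 1e-9))
})

test_that("template: construction, zero case, and parietal-maximal topography", {
  tpl <- make_template(peak_latency_s = 0.5, width_s = 0.3, amplitude = 1)
  tt <- seq(0, 1, by = 1 / 128)
  wf <- template_waveform(tpl, tt)
  expect_equal(tt[which.max(wf)], 0.5)
  expect_equal(max(wf), 1)
  expect_equal(unname(tpl$topography[["Pz"]]), 1)

  z <- make_template(amplitude = 0)
  expect_true(all(template_waveform(z, tt) == 0))

  # independent evaluation of the spatial Gaussian at all 64 positions
  m <- standard_montage_64()
  i <- match("Pz", m$channel)
  d2 <- (m$x - m$x[i])^2 + (m$y - m$y[i])^2
  gain <- exp(-d2 / (2 * 0.35^2))
  gain <- gain / max(gain)
  expect_equal(unname(tpl$topography), unname(gain))
  frontal <- m$channel[m$y > 0]
  expect_true(all(tpl$topography[["Pz"]] >= tpl$topography[frontal]))

  expect_error(make_template(roi_center = "XX9"), "XX9")
})

test_that("noiseless jitterless target average at Pz equals the template", {
  db <- noiseless_db(n_trials = 40, jitter = 0, seed = 3)
  ep <- epoch_events(db$recordings[[1]], db$events)
  pz <- match("Pz", ep$channel_names)
  avg <- colMeans(ep$data[ep$labels == 1, pz, ])
  ref <- template_waveform(fix_template(), (0:127) / 128)
  expect_lt(max(abs(avg - ref)), 1e-3)
})

test_that("same spec and seed give bit-identical databases", {
  spec <- experiment_spec("E1", 1, 30,
                          conditions = list(condition_spec()), seed = 17)
  a <- simulate_experiment(spec, fix_template())
  b <- simulate_experiment(spec, fix_template())
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$events, b$events)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("ROI evoked peak over 500 noisy target trials is within 10% of truth", {
  tpl <- make_template(jitter_sd_s = 0)
  spec <- experiment_spec("E1", 1, 550,
    conditions = list(condition_spec(class_ratio = c(1, 0, 0),
                                     isi_s = 1.5, jitter_sd_s = 0)),
    seed = 31)
  db <- simulate_experiment(spec, tpl)
  ep <- epoch_events(db$recordings[[1]], db$events)
  roi_idx <- match(roi_channels(), ep$channel_names)
  evoked <- colMeans(apply(ep$data[, roi_idx, ], c(1, 3), mean))
  truth <- max(template_waveform(tpl, (0:127) / 128)) *
    mean(tpl$topography[roi_channels()])
  expect_lt(abs(max(evoked) / truth - 1), 0.10)
})

test_that("multi-experiment databases preserve configured class ratios", {
  ratios <- list(c(1, 0, 10), c(1, 0, 22), c(1, 0, 10), c(1, 0, 9))
  specs <- lapply(seq_along(ratios), function(i)
    experiment_spec(paste0("EXP", i), 1, 230,
      conditions = list(condition_spec(class_ratio = ratios[[i]],
                                       isi_s = 0.5)),
      noise = noise_spec(onef_sd = 0, osc_amp = 0, white_sd = 0.05),
      seed = 40 + i))
  dbs <- simulate_database(specs, fix_template())
  for (i in seq_along(ratios)) {
    ev <- dbs[[i]]$events
    emp <- sum(ev$label == "background") / sum(ev$label == "target")
    expect_lt(abs(emp / (ratios[[i]][3] / ratios[[i]][1]) - 1), 0.10)
  }
  expect_identical(simulate_database(list()), list())
  expect_error(simulate_database(specs[c(1, 1)]), "duplicate")
})

test_that("fixation-locked conditions carry fixation latencies", {
  spec <- experiment_spec("E1", 1, 30,
    conditions = list(condition_spec(locking = "fixation")), seed = 8)
  db <- simulate_experiment(spec, fix_template())
  expect_true(all(is.finite(db$events$fixation_latency_s)))
  expect_true(all(db$events$fixation_latency_s > 0))
})

test_that("background PSD has the configured 1/f slope over 1-40 Hz", {
  spec <- experiment_spec("E1", 1, 200,
    conditions = list(condition_spec(class_ratio = c(0, 0, 1))),
    noise = noise_spec(onef_exponent = 1.0, onef_sd = 1, osc_amp = 0,
                       white_sd = 0), seed = 55)
  db <- simulate_experiment(spec, fix_template())
  x <- db$recordings[[1]]$data[1, ]
  n <- length(x)
  pw <- Mod(fft(x))^2 / n
  fr <- (seq_len(n) - 1) * 128 / n
  sel <- fr >= 1 & fr <= 40
  # smooth the periodogram in log-spaced bins before fitting the slope
  bins <- cut(log10(fr[sel]), 24)
  lp <- tapply(log10(pw[sel]), bins, mean)
  lf <- tapply(log10(fr[sel]), bins, mean)
  slope <- unname(coef(lm(lp ~ lf))[2])
  expect_lt(abs(slope - (-1.0)), 0.3)
})

test_that("increasing latency jitter strictly attenuates the evoked peak", {
  peaks <- vapply(c(0, 0.05, 0.12), function(j) {
    db <- noiseless_db(n_trials = 80, jitter = j, seed = 63, isi = 2)
    ep <- epoch_events(db$recordings[[1]], db$events)
    pz <- match("Pz", ep$channel_names)
    max(colMeans(ep$data[ep$labels == 1, pz, ]))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("an infeasible trial schedule reports the required duration", {
  spec <- experiment_spec("E1", 1, 100,
                          conditions = list(condition_spec(isi_s = 2)),
                          seed = 2, duration_s = 10)
  expect_error(simulate_experiment(spec, fix_template()), "needs")
})
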