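# Conditioning pipeline: bandpass response, resampling, MAD scaling,
# epoching arithmetic.

make_rec <- function(x, fs = 128) {
  recording(matrix(x, nrow = 1), fs, "ch1")
}

test_that("bandpass removes DC and matches its analytic response in the passband", {
  fs <- 128
  rec <- make_rec(rep(3.2, fs * 30), fs)
  out <- bandpass_filter(rec)
  expect_lt(max(abs(out$data)), 1e-6)

  tt <- (0:(fs * 30 - 1)) / fs
  s10 <- make_rec(sin(2 * pi * 10 * tt), fs)
  y <- bandpass_filter(s10)$data[1, ]
  mid <- seq(5 * fs, 25 * fs)  # avoid edges
  amp <- 2 * sqrt(mean(y[mid] * sin(2 * pi * 10 * tt[mid]))^2 +
                    mean(y[mid] * cos(2 * pi * 10 * tt[mid]))^2)
  expect_lt(abs(amp - 1), 0.05)
  expect_equal(amp, bandpass_gain(10, 0.3, 50, fs), tolerance = 0.01)

  s60 <- make_rec(sin(2 * pi * 60 * tt), fs)
  y60 <- bandpass_filter(s60)$data[1, mid]
  # >= 20 dB power attenuation of a 60 Hz tone
  expect_lt(10 * log10(mean(y60^2) / 0.5), -20)

  expect_error(bandpass_filter(rec, high_hz = 64), "Nyquist")
  expect_error(bandpass_filter(rec, low_hz = 50, high_hz = 0.3), "below")
})

test_that("resampling preserves duration, identity, and pure tones", {
  n <- 10000
  rec <- recording(matrix(rnorm(2 * n), 2), 256, c("a", "b"))
  out <- resample_recording(rec, 128)
  expect_equal(ncol(out$data), round(n / 2))
  expect_equal(out$sample_rate_hz, 128)

  rec128 <- make_rec(rnorm(500), 128)
  expect_identical(resample_recording(rec128, 128)$data, rec128$data)

  tt <- (0:5119) / 512
  tone <- make_rec(sin(2 * pi * 5 * tt), 512)
  y <- resample_recording(tone, 128)$data[1, ]
  ref <- sin(2 * pi * 5 * (0:(length(y) - 1)) / 128)
  expect_gt(cor(y, ref), 0.999)

  expect_error(resample_recording(rec128, 256), "upsampling")
})

test_that("MAD normalization: fixed point, scale invariance, unit output, idempotence", {
  pat <- make_rec(rep(c(-1, 0, 1), 200))
  expect_equal(mad_normalize(pat)$data, pat$data)

  set.seed(7)
  x <- rnorm(3000)
  a <- mad_normalize(make_rec(x))
  b <- mad_normalize(make_rec(7 * x))
  expect_equal(a$data, b$data)
  expect_equal(median(abs(a$data - median(a$data))), 1)
  expect_equal(mad_normalize(a)$data, a$data)

  flat <- make_rec(rep(2, 100))
  expect_error(mad_normalize(flat), "MAD is zero")
})

test_that("epoching: sample arithmetic, binary labels, skip accounting", {
  fs <- 128
  n <- fs * 40
  onsets <- seq(5, 30, by = 1.5)
  labs <- rep(c("target", "distractor", "background"),
              c(3, 2, length(onsets) - 5))
  ev <- data.frame(onset_s = onsets, label = labs, subject = "s01",
                   experiment = "E1", condition = "c")
  x <- numeric(n)
  x[round(onsets * fs) + 1] <- 1  # impulse at each onset sample
  rec <- make_rec(x, fs)

  ep <- epoch_events(rec, ev, window = c(0, 1))
  expect_equal(dim(ep$data)[3], 128L)
  expect_equal(sum(ep$labels), 5L)
  # onset sample is the first sample of a [0, 1) epoch
  expect_true(all(ep$data[, 1, 1] == c(1, rep(0, 127))[1]))

  ep2 <- epoch_events(rec, ev, window = c(-0.3, 0.7))
  expect_equal(dim(ep2$data)[3], 128L)
  # nearest-sample rounding puts 38 samples before the onset impulse
  impulse_at <- which(ep2$data[1, 1, ] == 1)
  expect_equal(impulse_at, 39L)  # 38 pre-onset samples

  ev_bad <- rbind(ev, data.frame(onset_s = 39.9, label = "background",
                                 subject = "s01", experiment = "E1",
                                 condition = "c"))
  expect_warning(ep3 <- epoch_events(rec, ev_bad), "skipped 1")
  expect_equal(dim(ep3$data)[1] + attr(ep3, "n_skipped"), nrow(ev_bad))

  expect_error(epoch_events(rec, transform(ev, label = "weird")),
               "unknown event label")
})

test_that("preprocess_recording applies filter, then resample, then normalize", {
  set.seed(9)
  rec <- recording(matrix(rnorm(2 * 256 * 20), 2), 256, c("a", "b"))
  direct <- mad_normalize(resample_recording(bandpass_filter(rec), 128))
  piped <- preprocess_recording(rec)
  expect_identical(piped$data, direct$data)
  expect_equal(piped$sample_rate_hz, 128)
})
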