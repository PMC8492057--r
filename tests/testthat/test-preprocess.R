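make_rec <- function(data, srate = 1000, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(sample = c(200L, 500L, 800L), label = "weak")
  }
  new_recording(matrix(data, nrow = 1), srate, ch_names = "A", events = events)
}

test_that("artifact interpolation reproduces smooth signals and removes spikes", {
  n <- 1000
  # constant signal: unchanged everywhere
  rec <- make_rec(rep(2.5, n))
  expect_equal(interpolate_stimulus_artifact(rec)$data, rec$data)
  # linear ramp: cubic Hermite reproduces linear data
  rec <- make_rec(seq_len(n) * 0.1)
  expect_equal(interpolate_stimulus_artifact(rec)$data, rec$data,
               tolerance = 1e-12)
  # delta spike at onset on a flat channel vanishes inside the window
  x <- rep(1, n)
  x[500L] <- 50
  out <- interpolate_stimulus_artifact(make_rec(x))
  expect_equal(out$data[1, 490:510], rep(1, 21), tolerance = 1e-12)
  # samples outside the excision windows are bit-identical
  x <- rnorm(n)
  rec <- make_rec(x)
  out <- interpolate_stimulus_artifact(rec)
  win <- unlist(lapply(c(200L, 500L, 800L), function(s) (s - 2L):(s + 4L)))
  expect_identical(out$data[1, -win], rec$data[1, -win])
  # event at the edge is skipped with a warning
  rec2 <- make_rec(x, events = data.frame(sample = c(2L, 500L), label = "weak"))
  expect_warning(interpolate_stimulus_artifact(rec2), "edge")
})

test_that("zero-phase band-pass meets the passband, stopband and lag contracts", {
  fs <- 5000
  t <- seq(0, 2, by = 1 / fs)
  mid <- (0.5 * fs):(1.5 * fs)
  # mid-passband sinusoid: amplitude within 1%, zero lag
  x <- sin(2 * pi * 100 * t)
  y <- zero_phase_filter(x, fs, 30, 200)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  cc <- ccf(x[mid], y[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 14 Hz attenuated by >= 30 dB
  x14 <- sin(2 * pi * 14 * t)
  y14 <- zero_phase_filter(x14, fs, 30, 200)
  expect_gte(-20 * log10(max(abs(y14[mid]))), 30)
})

test_that("8-13 Hz filtered white noise concentrates its spectrum in 6-15 Hz", {
  set.seed(11)
  fs <- 250
  x <- rnorm(60 * fs)
  y <- zero_phase_filter(x, fs, 8, 13)
  sp <- stats::spec.pgram(ts(y, frequency = fs), taper = 0, plot = FALSE,
                          detrend = FALSE)
  inband <- sp$freq >= 6 & sp$freq <= 15
  expect_lt(sum(sp$spec[!inband]) / sum(sp$spec), 0.05)
})

test_that("filtering is linear and the wide-band cascade stays stable at 5 kHz", {
  fs <- 1000
  set.seed(4)
  x <- rnorm(3000)
  y <- rnorm(3000)
  lin <- zero_phase_filter(2 * x - 3 * y, fs, 30, 200)
  sep <- 2 * zero_phase_filter(x, fs, 30, 200) - 3 * zero_phase_filter(y, fs, 30, 200)
  expect_equal(lin, sep, tolerance = 1e-9)
  # 0.5-45 Hz at 5 kHz: the naive single design explodes; ours must not
  fs5 <- 5000
  t <- seq(0, 2, by = 1 / fs5)
  z <- zero_phase_filter(sin(2 * pi * 20 * t), fs5, 0.5, 45)
  expect_equal(max(abs(z[(0.5 * fs5):(1.5 * fs5)])), 1, tolerance = 0.02)
})

test_that("epoching is pure indexing with correct trial bookkeeping", {
  set.seed(9)
  n <- 6000
  events <- data.frame(sample = seq(500L, 5500L, by = 500L), label = "weak")
  rec <- new_recording(matrix(rnorm(2 * n), nrow = 2), 1000,
                       ch_names = c("A", "B"), events = events)
  ep <- epoch_data(rec, c(-100, 300))
  expect_equal(dim(ep$data)[1L], nrow(events))
  expect_true(0 %in% ep$times)
  # concatenating epoch windows reproduces the recording slices exactly
  for (i in c(1L, 5L)) {
    idx <- (events$sample[i] - 100L):(events$sample[i] + 300L)
    expect_equal(ep$data[i, , ], rec$data[, idx], ignore_attr = TRUE,
                 tolerance = 0)
  }
  # event too close to the end is dropped, count = n - 1
  events2 <- rbind(events, data.frame(sample = n - 50L, label = "weak"))
  rec2 <- new_recording(rec$data, 1000, ch_names = c("A", "B"), events = events2)
  # both the appended event and the last original one lack 600 ms of tail
  expect_message(ep2 <- epoch_data(rec2, c(-100, 600)), "dropped 2")
  expect_equal(dim(ep2$data)[1L], nrow(events2) - 2L)
  expect_error(epoch_data(rec, c(-7000, 7000)), "empty")
})

test_that("averaging jitter-locked epochs cancels an ongoing oscillation", {
  fs <- 1000
  n <- 1.6e6
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 10 * t)
  set.seed(2)
  onsets <- as.integer(cumsum(runif(1000, 1.463, 1.563)) * fs)
  rec <- new_recording(matrix(x, nrow = 1), fs, ch_names = "A",
                       events = data.frame(sample = onsets, label = "weak"))
  ep <- epoch_data(rec, c(-100, 100))
  avg <- colMeans(ep$data[, 1L, ])
  expect_lt(max(abs(avg)), 0.08)   # ~1/sqrt(1000) residual of unit amplitude
})

test_that("average re-referencing zeroes the channel mean, idempotently", {
  set.seed(5)
  rec <- new_recording(matrix(rnorm(5 * 400), nrow = 5), 1000,
                       ch_names = paste0("C", 1:5))
  out <- rereference_average(rec, channels = rec$ch_names)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_equal(rereference_average(out, channels = out$ch_names)$data,
               out$data, tolerance = 1e-12)
  # two antisymmetric channels are already average-referenced
  v <- rnorm(100)
  rec2 <- new_recording(rbind(v, -v), 1000, ch_names = c("P", "N"))
  expect_equal(rereference_average(rec2, channels = c("P", "N"))$data,
               rec2$data, tolerance = 1e-12)
  rec1 <- new_recording(matrix(v, nrow = 1), 1000, ch_names = "X")
  expect_error(rereference_average(rec1, channels = "X"), ">= 2")
  # epochs method: per-sample channel mean is zero, peripherals untouched
  ds <- cached_subject()$dataset
  ep <- epoch_data(ds$recording, c(-50, 50))
  epr <- rereference_average(ep, channels = ds$recording$eeg_channels)
  chi <- match(ds$recording$eeg_channels, ep$ch_names)
  expect_lt(max(abs(apply(epr$data[, chi, ], c(1L, 3L), mean))), 1e-10)
  per <- match("CMAP", ep$ch_names)
  expect_identical(epr$data[, per, ], ep$data[, per, ])
})
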