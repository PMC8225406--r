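sineRecording <- function(freqs, amps, rate = 512, dur = 40, nch = 2,
                          events = data.frame(onset = numeric(),
                                              code = integer())) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  eegRecording(matrix(rep(x, each = nch), nch), rate,
               paste0("ch", seq_len(nch)), events)
}

# amplitude of a known sinusoid in a channel (projection oracle)
sineAmp <- function(rec, f, ch = 1) {
  x <- channelData(rec)[ch, ]
  n <- length(x)
  t <- (seq_len(n) - 1) / samplingRate(rec)
  2 * Mod(sum(x * exp(-2i * pi * f * t))) / n
}

test_that("zero-phase Butterworth band-pass keeps the passband, kills drift and DC", {
  rec <- sineRecording(10, 1)
  out <- bandpassButterworth(rec, 0.1, 100, 4)
  gainDb <- 20 * log10(sineAmp(out, 10))
  expect_lt(abs(gainDb), 1)

  drift <- sineRecording(0.01, 1)
  att <- 20 * log10(sineAmp(bandpassButterworth(drift, 0.1, 100, 4), 0.01))
  expect_lt(att, -20)

  dc <- eegRecording(matrix(1, 2, 512 * 60), 512)
  outDc <- bandpassButterworth(dc, 0.1, 100, 4)
  interior <- (20 * 512):(40 * 512)  # away from filtfilt edge transients
  expect_lt(mean(abs(channelData(outDc)[1, interior])), 0.02)

  expect_error(bandpassButterworth(rec, 100, 0.1), "cutoffs")
  expect_error(bandpassButterworth(rec, 0.1, 300), "cutoffs")
})

test_that("FFT multinotch removes listed lines and nothing else", {
  rec50 <- sineRecording(50, 1)
  out <- fftMultinotch(rec50, c(50, 100, 150), 0.5)
  expect_lt(sineAmp(out, 50), 0.01)

  rec47 <- sineRecording(47, 1)
  out47 <- fftMultinotch(rec47, c(50, 100, 150), 0.5)
  expect_lt(max(abs(channelData(out47) - channelData(rec47))), 1e-6)

  expect_identical(channelData(fftMultinotch(rec47, numeric(0))),
                   channelData(rec47))
})

test_that("integer-factor downsampling preserves in-band amplitude and events", {
  rec <- sineRecording(10, 1, events = data.frame(onset = 2.5, code = 1L))
  out <- downsample(rec, 256)
  expect_equal(samplingRate(out), 256)
  expect_equal(duration(out), duration(rec))
  expect_equal(sineAmp(out, 10), 1, tolerance = 0.01)
  expect_equal(events(out)$onset, 2.5)

  expect_identical(channelData(downsample(rec, 512)), channelData(rec))
  expect_error(downsample(rec, 300), "divide")
})

test_that("epoch segmentation cuts the stated windows and skips out-of-bounds", {
  rate <- 256
  rec <- eegRecording(matrix(rnorm(2 * rate * 80), 2), rate,
                      events = data.frame(onset = c(3, 78), code = 1L))
  eps <- NULL
  expect_message(eps <- segmentEpochs(rec, pre = 2, post = 3,
                                      seqDuration = 64),
                 "skipping")
  expect_length(eps, 1)
  expect_equal(duration(eps[[1]]), 69)
  expect_equal(eps[[1]]@t0, -2)

  eps0 <- segmentEpochs(eegRecording(matrix(rnorm(2 * rate * 20), 2), rate,
                                     events = data.frame(onset = 5, code = 1L)),
                        pre = 0, post = 0, seqDuration = 10)
  expect_equal(duration(eps0[[1]]), 10)
  expect_equal(eps0[[1]]@t0, 0)
})

test_that("bad-channel interpolation averages the nearest good neighbours", {
  layout <- data.frame(
    label = c("a", "b", "c", "d"),
    x = c(0, 1, 0, -1), y = c(1, 0, -1, 0), z = c(0.2, 0.2, 0.2, 0.2))
  mat <- rbind(a = rep(5, 10), b = rep(1, 10), c = rep(2, 10),
               d = rep(3, 10))
  ep <- epoch(mat, 100, c("a", "b", "c", "d"))

  out <- interpolateChannels(ep, "a", layout, k = 3)
  expect_equal(channelData(out)["a", ], rep(2, 10))  # mean of b, c, d
  expect_identical(channelData(out)[-1, ], mat[-1, ])

  # identical neighbours reproduce their shared signal
  mat2 <- rbind(a = rnorm(10), b = rep(7, 10), c = rep(7, 10),
                d = rep(7, 10))
  ep2 <- epoch(mat2, 100, c("a", "b", "c", "d"))
  expect_equal(channelData(interpolateChannels(ep2, "a", layout, 3))["a", ],
               rep(7, 10))

  expect_identical(channelData(interpolateChannels(ep, character(0),
                                                   layout, 3)),
                   channelData(ep))
  expect_error(interpolateChannels(ep, "a", layout, k = 4), "fewer than")
})

test_that("average re-referencing zeroes the channel mean and is idempotent", {
  x <- rnorm(50)
  same <- epoch(rbind(x, x, x), 100, c("a", "b", "c"))
  expect_equal(channelData(rereferenceAverage(same)),
               matrix(0, 3, 50), ignore_attr = TRUE)

  set.seed(21)
  ep <- epoch(matrix(rnorm(4 * 100), 4), 100)
  out <- rereferenceAverage(ep)
  expect_lt(max(abs(colMeans(channelData(out)))), 1e-9)
  # idempotence
  expect_equal(channelData(rereferenceAverage(out)), channelData(out),
               tolerance = 1e-12)
  # commutes with channel permutation
  perm <- c(3, 1, 4, 2)
  epPerm <- epoch(channelData(ep)[perm, ], 100,
                  channelLabels(ep)[perm])
  outPerm <- rereferenceAverage(epPerm)
  expect_equal(channelData(outPerm), channelData(out)[perm, ],
               ignore_attr = TRUE)
})

test_that("integer-cycle resegmentation reproduces the study epoch lengths", {
  # 69-s epoch, skip the 2-s pre plus 2-s fade, cap 60 -> 60 s = 80 cycles
  icd <- integerCycleDuration(65, 4 / 3, maxDuration = 60)
  expect_equal(icd$duration, 60)
  expect_equal(icd$cycles, 80L)

  icd2 <- integerCycleDuration(65, 7.8125 / 3, maxDuration = 60)
  expect_equal(icd2$duration, 59.904)
  expect_equal(icd2$cycles, 156L)

  # already an integer number of cycles: unchanged
  expect_equal(integerCycleDuration(60, 4 / 3)$duration, 60)

  rate <- 256
  ep <- epoch(matrix(rnorm(2 * 69 * rate), 2), rate, t0 = -2)
  out <- resegmentIntegerCycles(ep, 4 / 3, skip = 4, maxDuration = 60)
  expect_equal(duration(out), 60)
  expect_equal(out@t0, 2)
  expect_equal(duration(out) * 4 / 3, round(duration(out) * 4 / 3),
               tolerance = 1e-9)
  expect_error(resegmentIntegerCycles(ep, 4 / 3, skip = 68.9), "too short")
})

test_that("the preprocessing chain passes an in-band sinusoid within 2%", {
  rate <- 512
  rec <- sineRecording(c(10, 50, 0.01), c(1, 1, 2), rate = rate, dur = 69,
                       events = data.frame(onset = 0, code = 1L))
  run <- function(r) {
    r <- bandpassButterworth(r, 0.1, 100, 4)
    r <- fftMultinotch(r, c(50, 100, 150), 0.5)
    r <- downsample(r, 256)
    eps <- segmentEpochs(r, pre = 0, post = 0, seqDuration = 69)
    rereferenceAverage(resegmentIntegerCycles(eps[[1]], 4 / 3,
                                              skip = 4, maxDuration = 60))
  }
  out <- run(rec)
  # re-referencing removes the channel-common part, so test on a recording
  # with one differing channel
  mat <- channelData(rec)
  mat[2, ] <- 0
  rec2 <- eegRecording(mat, rate, events = events(rec))
  out2 <- run(rec2)
  # channel 1 carries +x/2 after average reference of (x, 0)
  t <- (seq_len(ncol(channelData(out2))) - 1) / 256 # relative time
  amp10 <- 2 * Mod(sum(channelData(out2)[1, ] * exp(-2i * pi * 10 * t))) /
    length(t)
  expect_equal(amp10, 0.5, tolerance = 0.02)
  # determinism
  expect_identical(channelData(run(rec2)), channelData(out2))
})
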