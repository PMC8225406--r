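test_that("rmsEqualize scales to the requested RMS", {
  rate <- 8000
  const <- audioClip(rep(0.5, 800), rate)
  expect_equal(samples(rmsEqualize(const, 0.1)), rep(0.1, 800))

  sine <- toneClip(440, rate)
  out <- rmsEqualize(sine, 1 / sqrt(2))
  expect_equal(samples(out), samples(sine), tolerance = 1e-9)

  set.seed(3)
  rnd <- audioClip(rnorm(1000), rate)
  expect_equal(rms(rmsEqualize(rnd, 0.37)), 0.37, tolerance = 1e-9)
  # scalar multiple of the input
  ratio <- samples(rmsEqualize(rnd, 0.37)) / samples(rnd)
  expect_lt(diff(range(ratio)), 1e-12)

  expect_error(rmsEqualize(audioClip(rep(0, 100), rate), 0.1), "all-zero")
})

test_that("applyRamps fades edges linearly and leaves the interior intact", {
  set.seed(4)
  clip <- audioClip(rnorm(4000) + 1, 16000)
  expect_identical(samples(applyRamps(clip, 0)), samples(clip))

  out <- applyRamps(clip, 0.010)
  expect_equal(samples(out)[1], 0)
  expect_equal(samples(out)[4000], 0)
  nr <- round(0.010 * 16000)
  interior <- (nr + 1):(4000 - nr)
  expect_identical(samples(out)[interior], samples(clip)[interior])
  # monotone 0 -> 1 over the onset ramp for a positive waveform
  env <- samples(out)[1:nr] / samples(clip)[1:nr]
  expect_true(all(diff(env) > 0))

  expect_error(applyRamps(audioClip(rnorm(100), 16000), 0.01),
               "ramps longer")
})

test_that("extractEnvelope tracks a known AM modulator", {
  rate <- 16000
  t <- seq(0, 0.5 - 1 / rate, by = 1 / rate)
  modulator <- 1 + 0.5 * sin(2 * pi * 7 * t)
  am <- audioClip(modulator * sin(2 * pi * 1000 * t), rate)
  env <- extractEnvelope(am, cutoff = 50)
  inner <- t > 0.05 & t < 0.45
  expect_lt(max(abs(env[inner] - modulator[inner]) / modulator[inner]), 0.05)

  const <- extractEnvelope(toneClip(1000, rate, dur = 0.5), cutoff = 50)
  expect_lt(diff(range(const[inner])), 0.05)

  expect_equal(extractEnvelope(audioClip(rep(0, 1000), rate), 50),
               rep(0, 1000))
  expect_true(all(env >= 0))
})

test_that("frequency-bin scrambling preserves per-bin power and is seeded", {
  rate <- 16000
  sine <- toneClip(1000, rate)
  scr <- scrambleFrequencyBins(sine, 200, seed = 11, applyEnvelope = FALSE)
  p <- binPower(samples(scr), rate)
  lo <- seq(0, rate / 2 - 200, by = 200)
  inBand <- which(lo <= 1000 & lo + 200 > 1000)
  expect_gt(p[inBand] / sum(p), 0.999)

  # determinism per seed
  s1 <- scrambleFrequencyBins(sine, 200, seed = 5)
  s2 <- scrambleFrequencyBins(sine, 200, seed = 5)
  expect_identical(samples(s1), samples(s2))
  s3 <- scrambleFrequencyBins(sine, 200, seed = 6)
  expect_false(identical(samples(s1), samples(s3)))

  # white noise: per-bin power identical to the input before the envelope
  set.seed(9)
  wn <- audioClip(rnorm(4000), rate)
  ws <- scrambleFrequencyBins(wn, 200, seed = 2, applyEnvelope = FALSE)
  expect_lt(max(abs(binPower(samples(ws), rate) - binPower(samples(wn), rate)) /
                binPower(samples(wn), rate)), 1e-6)

  # idempotent in power: scrambling a scrambled clip keeps the original
  # per-bin power
  ws2 <- scrambleFrequencyBins(ws, 200, seed = 3, applyEnvelope = FALSE)
  expect_lt(max(abs(binPower(samples(ws2), rate) - binPower(samples(wn), rate)) /
                binPower(samples(wn), rate)), 1e-6)

  expect_error(scrambleFrequencyBins(wn, rate), "Nyquist")
})

test_that("attenuateTarget divides RMS by the requested factor", {
  set.seed(6)
  clip <- rmsEqualize(audioClip(rnorm(2000), 8000), 0.1)
  out <- attenuateTarget(clip, 12.5)
  expect_equal(rms(out), 0.008, tolerance = 1e-9)
  expect_identical(samples(attenuateTarget(clip, 1)), samples(clip))

  rnd <- audioClip(rnorm(500), 8000)
  expect_equal(rms(attenuateTarget(rnd, 7)) / rms(rnd), 1 / 7,
               tolerance = 1e-9)

  # equalize-then-attenuate lands at target/factor exactly
  out2 <- attenuateTarget(rmsEqualize(rnd, 0.2), 4)
  expect_equal(rms(out2), 0.05, tolerance = 1e-12)
})

test_that("buildSequence enforces the periodic oddball design", {
  pool <- clipPool(4, 8, rate = 8000, soa = 0.25)
  sq <- buildSequence(pool$vocal, pool$nonvocal,
                      sequenceSpec(totalDuration = 64, seed = 7))
  expect_equal(baseFreq(sq), 4)
  expect_equal(targetFreq(sq), 4 / 3, tolerance = 1e-12)

  ev <- events(sq)
  expect_equal(nrow(ev), 256)
  idx0 <- seq_len(nrow(ev)) - 1
  expect_true(all(ev$category[idx0 %% 3 == 2] == "vocal"))
  expect_true(all(ev$category[idx0 %% 3 != 2] == "nonvocal"))
  expect_equal(diff(ev$onset), rep(0.25, 255))

  # attentional targets: six, outside the fades, spaced >= 2 s
  tg <- ev$onset[ev$is_target]
  expect_length(tg, 6)
  expect_true(all(tg >= 2 & tg + 0.25 <= 62))
  expect_true(all(diff(sort(tg)) >= 2))

  # fade windows: linear gain ramp on the summed waveform
  w <- samples(sq)
  expect_equal(w[1], 0)
  expect_lt(mean(abs(w[1:4000])), mean(abs(w[20001:24000])))

  # reproducible per seed, fresh order otherwise
  sq2 <- buildSequence(pool$vocal, pool$nonvocal,
                       sequenceSpec(totalDuration = 64, seed = 7))
  expect_identical(samples(sq2), samples(sq))
  expect_identical(events(sq2)$id, events(sq)$id)
  sq3 <- buildSequence(pool$vocal, pool$nonvocal,
                       sequenceSpec(totalDuration = 64, seed = 8))
  expect_false(identical(events(sq3)$id, events(sq)$id))

  # non-vocal exemplars never repeat back-to-back
  nv <- ev$id[ev$category == "nonvocal"]
  expect_true(all(nv[-1] != nv[-length(nv)]))
})

test_that("the short-SOA design gives the 7.81/2.60 Hz rates", {
  pool <- clipPool(3, 6, rate = 16000, soa = 0.128)
  sq <- buildSequence(pool$vocal, pool$nonvocal,
                      sequenceSpec(soa = 0.128, totalDuration = 16.384,
                                   fadeDuration = 2, nAttentionalTargets = 2,
                                   seed = 1))
  expect_equal(baseFreq(sq), 7.8125)
  expect_equal(targetFreq(sq), 2.604167, tolerance = 1e-6)
  expect_error(buildSequence(pool$vocal, pool$nonvocal,
                             sequenceSpec(soa = 0.25, totalDuration = 16)),
               "does not equal soa")
})

test_that("pitch estimation recovers synthesis f0 and flags noise", {
  expect_equal(pitchEstimate(harmonicClip(220, noiseSd = 0.5))$f0, 220,
               tolerance = 2 / 220)
  expect_equal(pitchEstimate(toneClip(440))$f0, 440, tolerance = 2 / 440)
  set.seed(12)
  wn <- audioClip(rnorm(4000), 16000)
  p <- pitchEstimate(wn)
  expect_false(p$voiced)
  expect_true(is.na(p$f0))
  expect_error(pitchEstimate(audioClip(rnorm(100), 16000)), "too short")
})

test_that("HNR reflects the harmonic-to-noise power ratio", {
  expect_gt(hnrEstimate(harmonicClip(220, noiseSd = 0)), 40)
  # construction: noise power = signal power / rho
  set.seed(13)
  for (rho_db in c(10, 20)) {
    clean <- harmonicClip(223.7, noiseSd = 0, seed = rho_db)
    sigP <- mean(samples(clean)^2)
    noisy <- audioClip(samples(clean) +
                       rnorm(length(samples(clean)),
                             sd = sqrt(sigP / 10^(rho_db / 10))), 16000)
    expect_lt(abs(hnrEstimate(noisy) - rho_db), 2)
  }
  set.seed(14)
  expect_lt(hnrEstimate(audioClip(rnorm(4000), 16000)), 0)
})

test_that("spectral centroid matches a direct weighted mean", {
  rate <- 16000
  expect_equal(spectralCentroid(toneClip(1000, rate)), 1000,
               tolerance = 4 / 1000)
  t <- seq(0, 0.25 - 1 / rate, by = 1 / rate)
  two <- audioClip(sin(2 * pi * 500 * t) + sin(2 * pi * 1500 * t), rate)
  expect_equal(spectralCentroid(two), 1000, tolerance = 0.01)

  set.seed(15)
  rnd <- audioClip(rnorm(2000), rate)
  # brute-force oracle over FFT magnitudes
  A <- Mod(stats::fft(samples(rnd)))[1:1001]
  f <- (0:1000) * rate / 2000
  expect_equal(spectralCentroid(rnd), sum(f * A) / sum(A), tolerance = 1e-12)

  expect_error(spectralCentroid(audioClip(rep(0, 100), rate)), "silence")
})
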