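# naive baseline oracle used against the vectorized implementation
naiveBaseline <- function(A, bin, cfg) {
  extra <- if (cfg@dropExtremes == "minmax") 2L else 0L
  off <- cfg@skipAdjacent + seq_len(cfg@nSide + extra)
  side <- function(sign) {
    v <- A[bin + sign * off]
    if (cfg@dropExtremes == "minmax") sort(v)[2:(length(v) - 1L)] else v
  }
  b <- c(side(-1L), side(1L))
  list(mean = mean(b), sd = stats::sd(b))
}

test_that("time-domain averaging keeps phase-locked signal, divides noise power", {
  set.seed(31)
  e1 <- epoch(matrix(rnorm(3 * 50), 3), 100, paste0("c", 1:3))
  expect_identical(channelData(averageEpochs(list(e1))), channelData(e1))

  e2 <- epoch(-channelData(e1), 100, paste0("c", 1:3))
  expect_equal(channelData(averageEpochs(list(e1, e2))),
               matrix(0, 3, 50), ignore_attr = TRUE)

  # phase-locked sinusoid + independent noise across N epochs
  rate <- 100; N <- 32
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  sig <- sin(2 * pi * 5 * t)
  eps <- lapply(seq_len(N), function(i)
    epoch(rbind(sig + rnorm(length(t))), rate, "c1"))
  avg <- averageEpochs(eps)
  resid <- channelData(avg)[1, ] - sig
  expect_equal(mean(resid^2), 1 / N, tolerance = 0.35)
  expect_error(averageEpochs(list(e1, epoch(matrix(0, 3, 10), 100))),
               "share")
})

test_that("amplitude spectra use single-sided scaling at 1/duration resolution", {
  rate <- 64
  ep <- epoch(rbind(2 * sin(2 * pi * (4 / 3) * seq(0, 60 - 1 / rate,
                                                   by = 1 / rate))),
              rate, "c1")
  sp <- amplitudeSpectrum(ep)
  expect_equal(frequencyResolution(sp), 1 / 60)
  bin <- round((4 / 3) / frequencyResolution(sp)) + 1
  expect_equal(unname(spectralValues(sp)[1, bin]), 2, tolerance = 1e-9)
  expect_lt(max(spectralValues(sp)[1, -bin]), 1e-9)

  spz <- amplitudeSpectrum(epoch(matrix(0, 2, 640), rate))
  expect_true(all(spectralValues(spz) == 0))
})

test_that("local baselines follow the configured bin bookkeeping", {
  flat <- specFromMatrix(matrix(3, 1, 60))
  bl <- localBaseline(flat, bin = 30)
  expect_equal(unname(bl$mean), 3)
  expect_equal(unname(bl$sd), 0)

  # a spike at the scored bin does not contaminate its own baseline
  A <- matrix(1, 1, 60); A[1, 30] <- 100
  bl2 <- localBaseline(specFromMatrix(A), bin = 30)
  expect_equal(unname(bl2$mean), 1)

  # hand-built vector: both conventions against the naive oracle
  set.seed(33)
  v <- matrix(abs(rnorm(60)), 1, 60)
  sp <- specFromMatrix(v)
  for (mode in c("none", "minmax")) {
    cfg <- baselineConfig(dropExtremes = mode)
    got <- localBaseline(sp, bin = 30, cfg)
    want <- naiveBaseline(v[1, ], 30, cfg)
    expect_equal(unname(got$mean), want$mean)
    expect_equal(unname(got$sd), want$sd)
    # exactly 20 baseline bins in both modes: check via a constructed case
  }
  expect_error(localBaseline(sp, bin = 2), "edge")
})

test_that("z-scores measure departure from the local baseline", {
  set.seed(34)
  A <- matrix(abs(rnorm(1 * 80)) + 5, 1, 80)
  sp <- specFromMatrix(A)
  cfg <- baselineConfig()
  bl <- localBaseline(sp, bin = 40, cfg)
  # plant the bin at baseline mean -> z = 0; at mean + 3 SD -> z = 3
  A[1, 40] <- bl$mean
  expect_equal(unname(zscoreAt(specFromMatrix(A), freqs(sp)[40], cfg)), 0)
  A[1, 40] <- bl$mean + 3 * bl$sd
  expect_equal(unname(zscoreAt(specFromMatrix(A), freqs(sp)[40], cfg)), 3,
               tolerance = 1e-9)

  expect_warning(zscoreAt(specFromMatrix(matrix(2, 1, 80)), 4, cfg),
                 "zero baseline")
  expect_error(zscoreAt(sp, 100, cfg), "not on the bin grid")

  # zscoreSpectrum agrees with bin-wise zscoreAt
  zAll <- zscoreSpectrum(sp, cfg)
  expect_equal(zAll[1, 40],
               unname(zscoreAt(sp, freqs(sp)[40], cfg)))
})

test_that("harmonic selection skips base-rate multiples and stops at noise level", {
  # grid 1/60 Hz; fundamental 4/3 Hz, base 4 Hz excluded
  res <- 1 / 60
  nb <- 800
  A <- matrix(1, 1, nb)
  set.seed(35)
  A[1, ] <- abs(rnorm(nb, 1, 0.05))
  putz <- function(freq, z) {
    bin <- round(freq / res) + 1
    cfg <- baselineConfig(dropExtremes = "minmax")
    bl <- naiveBaseline(A[1, ], bin, cfg)
    A[1, bin] <<- bl$mean + z * bl$sd
  }
  # retained harmonics 1.333, 2.667, 5.333, 6.667 significant; 9.333 not
  for (f in (4 / 3) * c(1, 2, 4, 5)) putz(f, 12)
  putz(4, 50); putz(8, 50)           # base-rate lines, must be skipped
  putz((4 / 3) * 7, 0.5)             # first retained non-significant
  sp <- specFromMatrix(A, resolution = res)
  hr <- significantHarmonics(sp, 4 / 3, exclude = 4)
  expect_equal(harmonics(hr)[hr@significant], (4 / 3) * c(1, 2, 4, 5),
               tolerance = 1e-9)
  expect_equal(nSignificant(hr), 4)
  # the walk stopped at the first retained non-significant harmonic
  expect_false(hr@significant[length(hr@harmonics)])
  expect_equal(max(harmonics(hr)), (4 / 3) * 7, tolerance = 1e-9)

  # all-noise spectrum: no significant harmonics
  set.seed(36)
  spn <- specFromMatrix(matrix(abs(rnorm(nb, 1, 0.05)), 1, nb),
                        resolution = res)
  expect_equal(nSignificant(significantHarmonics(spn, 4 / 3, exclude = 4)), 0)
})

test_that("baseline subtraction recovers injected amplitude over a flat floor", {
  flat <- specFromMatrix(matrix(2, 2, 60))
  out <- baselineSubtract(flat)
  inner <- 14:47
  expect_true(all(abs(spectralValues(out)[, inner]) < 1e-12))

  A <- matrix(2, 1, 60); A[1, 30] <- 2 + 0.7   # peak A over floor c
  corr <- baselineSubtract(specFromMatrix(A))
  expect_equal(spectralValues(corr)[1, 30], 0.7, tolerance = 1e-12)

  # noise-only: corrected values average to ~0
  set.seed(37)
  big <- specFromMatrix(matrix(abs(rnorm(4 * 2000)), 4, 2000))
  cvals <- spectralValues(baselineSubtract(big))
  expect_lt(abs(mean(cvals, na.rm = TRUE)), 0.01)
})

test_that("harmonic sums are additive and match the slow path", {
  set.seed(38)
  A <- matrix(abs(rnorm(3 * 200)) + 1, 3, 200)
  sp <- specFromMatrix(A)
  corr <- baselineSubtract(sp)
  h1 <- freqs(sp)[c(30, 50)]
  h2 <- freqs(sp)[c(80, 120)]
  expect_equal(sumHarmonics(corr, numeric(0)),
               setNames(numeric(3), channelLabels(sp)))
  expect_equal(sumHarmonics(corr, c(h1, h2)),
               sumHarmonics(corr, h1) + sumHarmonics(corr, h2))
  # sparse path equals subtract-then-sum
  expect_equal(harmonicTopography(sp, c(h1, h2)),
               sumHarmonics(corr, c(h1, h2)))
})

test_that("summed harmonics recover injected amplitudes at high SNR", {
  # four target harmonics, amplitudes 0.4/0.3/0.2/0.1 uV over low noise
  gt <- testGroundTruth(targetAmps = c(0.4, 0.3, 0.2, 0.1),
                        noiseScale = 0.004, alphaAmp = 0)
  ep <- simulateEpoch(gt, duration = 60, rate = 64, epochSeed = 44)
  sp <- amplitudeSpectrum(ep)
  topo <- harmonicTopography(sp, (4 / 3) * c(1, 2, 4, 5))
  expect_equal(unname(topo["TP8h"]), 1.0, tolerance = 0.05)
  # a harmonic carrying no signal adds ~nothing
  topo5 <- harmonicTopography(sp, (4 / 3) * c(1, 2, 4, 5, 7))
  expect_equal(unname(topo5["TP8h"]), unname(topo["TP8h"]),
               tolerance = 0.02)
})

test_that("SNR spectra normalize by the local noise floor", {
  flat <- specFromMatrix(matrix(2, 1, 60))
  s <- snrSpectrum(flat)
  inner <- 14:47
  expect_true(all(abs(spectralValues(s)[1, inner] - 1) < 1e-12))

  A <- matrix(1, 1, 60); A[1, 30] <- 7
  s2 <- snrSpectrum(specFromMatrix(A))
  expect_equal(spectralValues(s2)[1, 30], 7, tolerance = 1e-12)

  # Rayleigh-distributed bins (amplitude spectrum of Gaussian noise): the
  # mean SNR is ~1 by construction; the median sits at the Rayleigh
  # median/mean ratio sqrt(log 4)/sqrt(pi/2) = 0.939
  set.seed(39)
  ray <- sqrt(rnorm(2 * 3000)^2 + rnorm(2 * 3000)^2)
  noise <- specFromMatrix(matrix(ray, 2, 3000))
  snrv <- spectralValues(snrSpectrum(noise))
  expect_equal(mean(snrv, na.rm = TRUE), 1, tolerance = 0.02)
  expect_equal(median(snrv, na.rm = TRUE), sqrt(log(4)) / sqrt(pi / 2),
               tolerance = 0.03)
})

test_that("the chunked individual-subject test scores summed windows", {
  # flat windows -> z = 0
  flat <- specFromMatrix(matrix(5, 1, 400), resolution = 1 / 60)
  r <- individualSignificance(flat, harmonics = freqs(flat)[c(100, 200)])
  expect_equal(r$z, 0)
  expect_false(r$significant)

  # hand-built two-window toy: compute the expected z directly
  set.seed(40)
  A <- matrix(abs(rnorm(400, 10, 1)), 1, 400)
  sp <- specFromMatrix(A, resolution = 1 / 60)
  bins <- c(100, 200)
  acc <- A[1, (bins[1] - 11):(bins[1] + 11)] +
    A[1, (bins[2] - 11):(bins[2] + 11)]
  base <- acc[setdiff(1:23, 11:13)]
  zExp <- (acc[12] - mean(base)) / sd(base)
  got <- individualSignificance(sp, freqs(sp)[bins])
  expect_equal(got$z, zExp)

  # signal in every window: z grows with the number of summed windows
  mkSpec <- function(nH) {
    set.seed(41)
    A <- matrix(abs(rnorm(2000, 1, 0.2)), 1, 2000)
    bins <- 100 * seq_len(nH)
    A[1, bins] <- A[1, bins] + 1.2
    list(sp = specFromMatrix(A, resolution = 1 / 60), bins = bins)
  }
  one <- mkSpec(1); four <- mkSpec(4)
  z1 <- individualSignificance(one$sp, freqs(one$sp)[one$bins])$z
  z4 <- individualSignificance(four$sp, freqs(four$sp)[four$bins])$z
  expect_gt(z4, z1)

  expect_error(individualSignificance(flat, harmonics = freqs(flat)[5]),
               "margin")
})
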