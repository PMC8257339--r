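test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  tm <- seq(0, 10, by = 0.01)
  const <- Chromatogram(tm, rep(3.5, length(tm)))
  expect_equal(intensity(smoothChromatogram(const)), const@intensity)
  cubic <- Chromatogram(tm, 0.3 * (tm - 5)^3 - 2 * tm + 1)
  expect_equal(intensity(smoothChromatogram(cubic, 9, 3)),
               cubic@intensity, tolerance = 1e-9)
  set.seed(42)
  noisy <- Chromatogram(tm, rnorm(length(tm)))
  expect_lt(var(intensity(smoothChromatogram(noisy))),
            var(noisy@intensity))
  expect_error(smoothChromatogram(const, windowPoints = 8), "odd")
  expect_error(smoothChromatogram(const, windowPoints = 3, polyOrder = 4),
               "exceed")
})

test_that("baseline estimation recovers flat levels and linear drift", {
  ## flat baseline under one Gaussian peak, noiseless
  chr <- gaussChrom(offset = 2)
  bl <- estimateBaseline(chr)
  expect_lt(max(abs(intensity(bl) - 2)), 1e-6)
  ## same, with noise: max error below the noise sd
  chrN <- gaussChrom(offset = 2, noiseSd = 0.5, seed = 1)
  blN <- estimateBaseline(chrN)
  expect_lt(max(abs(intensity(blN) - 2)), 0.5)
  ## zero trace -> zero baseline
  tm <- seq(0, 10, by = 0.01)
  expect_lt(max(abs(intensity(estimateBaseline(Chromatogram(tm, 0 * tm))))),
            1e-12)
  ## drift-only trace: recovered slope within 1%
  drift <- Chromatogram(tm, 0.8 * tm + 1)
  blD <- estimateBaseline(drift)
  slope <- coef(lm(intensity(blD) ~ tm))[2]
  expect_equal(unname(slope), 0.8, tolerance = 0.01)
})

test_that("peak detection recovers the five-analyte fixture areas", {
  run <- simulateRun(fastConfig(seed = 21), concStd)
  gt <- groundTruth(run)
  ## all five analytes absorb near 307 nm: exactly 5 peaks there,
  ## the marker being spectrally remote
  pk307 <- detectPeaks(extractTrace(run, 307))
  expect_identical(nrow(pk307), 5L)
  ## the dead-time marker is found at its own wavelength
  m <- measureRun(run)
  expect_false(anyNA(m$area))
  relErr <- abs(m$area - gt$simulatedArea[match(m$analyte, gt$analyte)]) /
    gt$simulatedArea[match(m$analyte, gt$analyte)]
  expect_lt(max(relErr), 0.005)
  ## apex times match ground truth closely
  expect_equal(m$apexTime, gt$apexTime[match(m$analyte, gt$analyte)],
               tolerance = 1e-3)
})

test_that("pure-noise traces yield no peaks at minSnr 5", {
  tm <- seq(0, 10, by = 1 / 120)
  empty <- 0L
  for (s in 1:100) {
    set.seed(s)
    chr <- Chromatogram(tm, rnorm(length(tm), 0, 0.5))
    if (nrow(detectPeaks(chr, minSnr = 5)) == 0L) empty <- empty + 1L
  }
  expect_gte(empty, 99L)
})

test_that("reported S/N matches height over twice the blank sd", {
  ## Gaussian of known height on known noise
  h <- 50; s <- 1
  chr <- gaussChrom(area = h * 0.1 * sqrt(2 * pi), sigma = 0.1,
                    noiseSd = s, seed = 7, n = 2400)
  pk <- detectPeaks(chr, minSnr = 5)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$snr[1], h / (2 * s), tolerance = 0.2)
  ## explicit blank-window S/N agrees with the definition
  snr <- signalToNoise(pk[1, ], chr, c(7, 9.5))
  expect_equal(snr, h / (2 * s), tolerance = 0.2)
  ## noiseless trace reports an infinite S/N
  clean <- gaussChrom(area = 5)
  pkc <- detectPeaks(clean)
  expect_identical(signalToNoise(pkc[1, ], clean, c(7, 9.5)), Inf)
  ## blank window over the peak is rejected
  expect_error(signalToNoise(pk[1, ], chr, c(4.8, 5.2)), "overlaps")
})

test_that("doubling the noise halves the signal-to-noise ratio", {
  snrAt <- function(noise, seed) {
    chr <- gaussChrom(area = 30, sigma = 0.1, noiseSd = noise,
                      seed = seed, n = 2400)
    pk <- detectPeaks(chr, minSnr = 5)
    signalToNoise(pk[which.max(pk$height), ], chr, c(7, 9.5))
  }
  ratios <- vapply(1:50, function(s) snrAt(0.5, s) / snrAt(1, s + 500),
                   numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("resolution follows the half-height closed form", {
  ## two identical Gaussians sigma apart: Rs = 1.18 * dt / (2 * 2.355 * sigma)
  sigma <- 0.1; dt <- 1.5
  tm <- seq(0, 12, by = 1 / 200)
  y <- 20 * dnorm(tm, 5, sigma) + 20 * dnorm(tm, 5 + dt, sigma)
  chr <- Chromatogram(tm, y)
  pk <- detectPeaks(chr)
  expect_identical(nrow(pk), 2L)
  rs <- peakResolution(pk[1, ], pk[2, ], chr)
  expect_equal(rs, 1.18 * dt / (2 * 2.355 * sigma), tolerance = 0.02)
  ## coincident apexes give zero
  expect_identical(peakResolution(pk[1, ], pk[1, ], chr), 0)
  expect_error(peakResolution(pk[2, ], pk[1, ], chr), "before")
})

test_that("the default assay fixture is baseline resolved (Rs > 1.5)", {
  run <- simulateRun(fastConfig(seed = 22), concStd)
  chr <- extractTrace(run, 307)
  pk <- detectPeaks(chr)
  for (i in seq_len(nrow(pk) - 1))
    expect_gt(peakResolution(pk[i, ], pk[i + 1, ], chr), 1.5)
})

test_that("areas are offset-invariant and detection is idempotent", {
  chr <- gaussChrom(area = 25)
  pk <- detectPeaks(chr)
  shifted <- Chromatogram(rtime(chr), intensity(chr) + 5,
                          wavelength = wavelength(chr))
  pkS <- detectPeaks(shifted)
  expect_equal(pkS$area, pk$area, tolerance = 1e-3)
  ## re-detecting on the baseline-corrected trace changes nothing
  pkI <- detectPeaks(baselineCorrect(chr))
  expect_equal(pkI$apexTime, pk$apexTime, tolerance = 1e-6)
  expect_equal(pkI$area, pk$area, tolerance = 1e-3)
})

test_that("trapezoidal integration of a dense Gaussian is exact to 0.1%", {
  ## >= 20 points per sigma
  sigma <- 0.1
  tm <- seq(0, 10, by = sigma / 25)
  amp <- 40
  y <- amp * dnorm(tm, 5, sigma)
  expect_equal(pracma::trapz(tm, y), amp, tolerance = 1e-3)
})

test_that("non-uniform grids are rejected by grid-sensitive operations", {
  tm <- c(seq(0, 5, by = 0.01), seq(5.02, 10, by = 0.02))
  chr <- Chromatogram(tm, rep(1, length(tm)))
  expect_error(detectPeaks(chr), "uniform")
  expect_error(smoothChromatogram(chr), "uniform")
})
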