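test_that("noiseless simulated areas follow the configured response lines", {
  cfg <- fastConfig(seed = 11)
  run <- simulateRun(cfg, concStd)
  gt <- groundTruth(run)
  ## ondansetron at 20 ug/mL on its printed line
  expect_equal(gt$nominalArea[gt$analyte == "ondansetron"], 42.4614,
               tolerance = 1e-12)
  ## every analyte, several concentrations across the range: the
  ## trapezoidal integral of the extracted trace matches slope*C + b
  for (C in c(5, 20, 100)) {
    conc <- concStd; conc[] <- 0
    for (a in names(conc)) {
      conc0 <- conc; conc0[a] <- C
      run1 <- simulateRun(cfg, conc0)
      i <- match(a, table1$analyte)
      spec <- cfg@analytes[[a]]
      chr <- extractTrace(run1, spec@detectionWavelength)
      sel <- rtime(chr) >= spec@retentionTime - 6 * spec@sigma &
             rtime(chr) <= spec@retentionTime + 6 * spec@sigma
      got <- pracma::trapz(rtime(chr)[sel], intensity(chr)[sel])
      want <- table1$slope[i] * C + table1$intercept[i]
      expect_equal(got, want, tolerance = 1e-3)
    }
  }
})

test_that("zero concentration contributes no peak", {
  cfg <- fastConfig(seed = 3)
  conc <- concStd; conc[] <- 0
  run <- simulateRun(cfg, conc)
  gt <- groundTruth(run)
  expect_true(all(gt$nominalArea[gt$analyte != "marker"] == 0))
  ## at 307 nm only the (spectrally remote) marker could leak through
  expect_lt(max(abs(intensity(extractTrace(run, 307)))), 1e-3)
})

test_that("runs are bit-identical for a fixed seed and differ across seeds", {
  cfg <- fastConfig(seed = 7, noiseSd = 0.05, responseRsdPct = 1)
  r1 <- simulateRun(cfg, concStd)
  r2 <- simulateRun(cfg, concStd)
  expect_identical(r1@absorbance, r2@absorbance)
  r3 <- simulateRun(initialize(cfg, seed = 8L), concStd)
  expect_false(identical(r1@absorbance, r3@absorbance))
})

test_that("noiseless runs superpose: two analytes equal the sum of singles", {
  cfg <- fastConfig(seed = 5)
  cfg@markerConcentration <- 0   # marker would otherwise appear in both
  z <- concStd; z[] <- 0
  a <- z; a["azasetron"] <- 30
  b <- z; b["ondansetron"] <- 15
  ab <- z; ab["azasetron"] <- 30; ab["ondansetron"] <- 15
  expect_equal(simulateRun(cfg, ab)@absorbance,
               simulateRun(cfg, a)@absorbance +
                 simulateRun(cfg, b)@absorbance,
               tolerance = 1e-12)
})

test_that("trace extraction snaps to the grid and rejects out-of-range", {
  run <- simulateRun(defaultRunConfig(seed = 2), concStd)
  chr <- extractTrace(run, 306.4)  # 1 nm grid -> snaps to 306
  expect_equal(wavelength(chr), 306)
  expect_true(chr@metadata$snapped)
  exact <- extractTrace(run, 302)
  expect_identical(intensity(exact),
                   run@absorbance[, match(302, wavelength(run))])
  expect_false(exact@metadata$snapped)
  expect_error(extractTrace(run, 450), "outside")
})

test_that("apex spectra are proportional to the UV band profile", {
  cfg <- defaultRunConfig(seed = 4)
  cfg@analytes <- lapply(cfg@analytes, function(a)
    initialize(a, intercept = 0))
  names(cfg@analytes) <- vapply(cfg@analytes, analyteName, character(1))
  z <- concStd; z[] <- 0
  c1 <- z; c1["tropisetron"] <- 20
  c2 <- z; c2["tropisetron"] <- 40
  r1 <- simulateRun(cfg, c1)
  r2 <- simulateRun(cfg, c2)
  tr <- cfg@analytes[["tropisetron"]]
  s1 <- extractApexSpectrum(r1, tr@retentionTime)
  s2 <- extractApexSpectrum(r2, tr@retentionTime)
  ## scale invariance of the cosine measure: C and 2C give similarity 1
  expect_equal(cosineSimilarity(s1, s2), 1, tolerance = 1e-9)
  ## doubling the concentration doubles the spectrum (proportional model)
  expect_equal(absorbance(s2), 2 * absorbance(s1), tolerance = 1e-6)
  ## and the shape is the analyte's band profile
  prof <- qamsHPLC:::.bandProfile(tr@uvBands, wavelength(run <- r1))
  expect_equal(cosineSimilarity(s1, SpectrumUV(wavelength(r1), prof)), 1,
               tolerance = 1e-9)
})

test_that("apex spectrum in a signal-free region is flagged near zero", {
  run <- simulateRun(defaultRunConfig(seed = 6), concStd)
  expect_warning(sp <- extractApexSpectrum(run, 13.5), "near zero")
  expect_true(attr(sp, "nearZero"))
})

test_that("insufficient peak spacing is flagged and bad input rejected", {
  analytes <- setronAnalytes()
  analytes[["granisetron"]]@retentionTime <-
    analytes[["azasetron"]]@retentionTime + 0.15
  cfg <- runConfig(analytes, deadTimeMarker(),
                   wavelengthGrid = c(285, 302, 307), seed = 1)
  expect_warning(run <- simulateRun(cfg, concStd), "resolution")
  expect_true(length(run@flags) > 0)
  bad <- concStd; bad["ramosetron"] <- -1
  expect_error(suppressWarnings(simulateRun(cfg, bad)), "negative")
  expect_error(simulateRun(fastConfig(seed = 1), concStd[-1]),
               "cover every configured analyte")
})

test_that("exponentially tailed peaks keep their calibrated area", {
  cfg <- fastConfig(seed = 9, tau = 0.05)
  z <- concStd; z[] <- 0; z["ondansetron"] <- 20
  run <- simulateRun(cfg, z)
  chr <- extractTrace(run, 307)
  area <- pracma::trapz(rtime(chr), intensity(chr))
  expect_equal(area, 42.4614, tolerance = 5e-3)
  ## tailing shifts the apex later than the Gaussian location
  gt <- groundTruth(run)
  expect_gt(gt$apexTime[gt$analyte == "ondansetron"], 0)
})

test_that("run configuration invariants are enforced", {
  expect_error(runConfig(setronAnalytes(), deadTimeMarker(), seed = 1,
                         runLength = 9), "runLength")
  expect_error(runConfig(setronAnalytes(), deadTimeMarker(), seed = 1,
                         samplingRate = 5), "samplingRate")
  expect_error(runConfig(setronAnalytes(), deadTimeMarker(),
                         noiseSd = -1, seed = 1), "noiseSd")
  expect_error(runConfig(setronAnalytes(), deadTimeMarker()), "seed")
})
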