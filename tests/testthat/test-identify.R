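test_that("cosine similarity matches the hand-computed angle formula", {
  a <- SpectrumUV(1:3, c(1, 2, 3))
  b <- SpectrumUV(1:3, c(2, 3, 4))
  ## hand oracle: sum(x*y) / sqrt(sum(x^2) * sum(y^2)) = 20 / sqrt(406)
  expect_equal(cosineSimilarity(a, b), 20 / sqrt(14 * 29),
               tolerance = 1e-12)
  expect_equal(round(cosineSimilarity(a, b), 4), 0.9926)
  ## symmetry and scale invariance
  expect_identical(cosineSimilarity(a, b), cosineSimilarity(b, a))
  expect_equal(cosineSimilarity(a, SpectrumUV(1:3, 3 * c(1, 2, 3))), 1,
               tolerance = 1e-12)
  ## disjoint bands are orthogonal
  wl <- seq(220, 400, by = 1)
  s1 <- SpectrumUV(wl, ifelse(wl < 300, 1, 0))
  s2 <- SpectrumUV(wl, ifelse(wl >= 300, 1, 0))
  expect_equal(cosineSimilarity(s1, s2), 0, tolerance = 1e-12)
  expect_error(cosineSimilarity(s1, SpectrumUV(wl, 0 * wl)), "all-zero")
})

test_that("similarity resamples mismatched grids and enforces overlap", {
  f <- function(w) exp(-(w - 280)^2 / 200)
  w1 <- seq(220, 400, by = 1)
  w2 <- seq(221, 399, by = 2)
  expect_equal(cosineSimilarity(SpectrumUV(w1, f(w1)),
                                SpectrumUV(w2, f(w2))), 1,
               tolerance = 1e-4)
  w3 <- seq(350, 400, by = 1)
  expect_error(cosineSimilarity(SpectrumUV(w1, f(w1)),
                                SpectrumUV(w3, f(w3))), "overlap")
})

test_that("the first derivative is exact on constants, ramps and Gaussians", {
  wl <- seq(220, 400, by = 2)
  expect_lt(max(abs(absorbance(firstDerivative(
    SpectrumUV(wl, rep(4, length(wl))))))), 1e-12)
  ramp <- firstDerivative(SpectrumUV(wl, 0.25 * wl))
  expect_equal(absorbance(ramp), rep(0.25, length(wl)), tolerance = 1e-9)
  ## Gaussian band: derivative crosses zero at the band centre
  g <- firstDerivative(SpectrumUV(wl, exp(-(wl - 307)^2 / (2 * 15^2))))
  d <- absorbance(g)
  cross <- wl[which(d[-length(d)] > 0 & d[-1] <= 0)][1]
  expect_lte(abs(cross - 307), 2)
  ## short spectra fall back to central differences, flagged
  short <- firstDerivative(SpectrumUV(1:5, (1:5)^2))
  expect_true(attr(short, "fallback"))
  expect_equal(absorbance(short)[2:4], c(4, 6, 8), tolerance = 1e-12)
})

test_that("relative retention time follows the dead-time-corrected ratio", {
  expect_identical(relativeRetentionTime(9, 9, 1.2), 1)
  expect_identical(relativeRetentionTime(1.2, 9, 1.2), 0)
  ## the azasetron fixture placement: (4.5618 - 1.2) / (9 - 1.2)
  expect_equal(round(relativeRetentionTime(4.5618, 9, 1.2), 3), 0.431)
  expect_error(relativeRetentionTime(5, 1.0, 1.2), "exceed")
  expect_error(relativeRetentionTime(0.5, 9, 1.2), "precede")
})

test_that("RRT is invariant under affine transforms of the time axis", {
  set.seed(99)
  for (k in 1:25) {
    a <- runif(1, 0.2, 5); b <- runif(1, -2, 10)
    t0 <- runif(1, 0.5, 2)
    ti <- t0 + runif(1, 3, 10)
    tx <- t0 + runif(1, 0.1, 12)
    expect_equal(relativeRetentionTime(a * tx + b, a * ti + b, a * t0 + b),
                 relativeRetentionTime(tx, ti, t0), tolerance = 1e-12)
  }
})

test_that("fixture spectral matrices respect the assay's rank order", {
  lib <- buildReferenceLibrary(defaultRunConfig(seed = 41))
  sm <- similarityMatrix(lib)
  for (m in sm) {
    expect_equal(unname(diag(m)), rep(1, 5), tolerance = 1e-12)
    expect_equal(m, t(m), tolerance = 1e-12)
  }
  ## derivative similarity magnifies differences on these fixtures
  expect_true(all(sm$deriv <= sm$raw + 1e-9))
  ## ondansetron/ramosetron are the most alike pair in both views
  offdiag <- function(m) { diag(m) <- NA; m }
  expect_identical(
    which(offdiag(sm$raw) == max(offdiag(sm$raw), na.rm = TRUE),
          arr.ind = TRUE)[1, ] |> sort() |> unname(),
    sort(match(c("ondansetron", "ramosetron"), rownames(sm$raw))))
  ## every cross-pair sits below the identification thresholds
  expect_lt(max(offdiag(sm$raw), na.rm = TRUE), 0.99)
  expect_lt(max(offdiag(sm$deriv), na.rm = TRUE), 0.90)
})

test_that("simulated peaks are identified as the right analyte", {
  cfg <- defaultRunConfig(seed = 42)
  lib <- buildReferenceLibrary(cfg)
  run <- simulateRun(cfg, concStd)
  m <- measureRun(run)
  t0 <- m$apexTime[m$analyte == "marker"]
  ti <- m$apexTime[m$analyte == "ondansetron"]
  for (a in names(concStd)) {
    row <- m[m$analyte == a, ]
    sp <- extractApexSpectrum(run, row$apexTime)
    id <- identifyPeak(row, sp, lib, ti = ti, t0 = t0)
    expect_identical(id@candidate, a)
    expect_true(id@identified)
    expect_false(id@ambiguous)
  }
})

test_that("a wrong reference spectrum fails the derivative indicator", {
  cfg <- defaultRunConfig(seed = 43)
  lib <- buildReferenceLibrary(cfg)
  run <- simulateRun(cfg, concStd)
  m <- measureRun(run)
  t0 <- m$apexTime[m$analyte == "marker"]
  ti <- m$apexTime[m$analyte == "ondansetron"]
  ## azasetron's spectrum tested against a ramosetron reference whose
  ## library RRT is forged to match: RRT passes, the spectrum must not
  row <- m[m$analyte == "azasetron", ]
  sp <- extractApexSpectrum(run, row$apexTime)
  forged <- list(ramosetron = list(
    analyte = "ramosetron",
    rrt = relativeRetentionTime(row$apexTime, ti, t0),
    spectrum = lib[["ramosetron"]]$spectrum))
  id <- identifyPeak(row, sp, forged, ti = ti, t0 = t0,
                     derivSimMin = 0.8)
  expect_true(id@rrtPass)
  expect_false(id@spectrumPass)
  expect_false(id@identified)
})

test_that("candidates inside the same RRT window are flagged ambiguous", {
  cfg <- defaultRunConfig(seed = 44)
  lib <- buildReferenceLibrary(cfg)
  run <- simulateRun(cfg, concStd)
  m <- measureRun(run)
  t0 <- m$apexTime[m$analyte == "marker"]
  ti <- m$apexTime[m$analyte == "ondansetron"]
  row <- m[m$analyte == "granisetron", ]
  sp <- extractApexSpectrum(run, row$apexTime)
  ## clone the granisetron entry under another name at a nearby RRT
  lib2 <- lib
  lib2[["clone"]] <- list(analyte = "clone",
                          rrt = lib[["granisetron"]]$rrt * 1.01,
                          spectrum = lib[["granisetron"]]$spectrum)
  id <- identifyPeak(row, sp, lib2, ti = ti, t0 = t0)
  expect_true(id@ambiguous)
  ## the tie-breaker still lands on a granisetron spectrum
  expect_match(id@candidate, "granisetron|clone")
})
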