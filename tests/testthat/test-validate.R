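lvls <- function(x, r) c(azasetron = x, granisetron = x, tropisetron = x,
                         ondansetron = x, ramosetron = r)

test_that("a noiseless campaign has zero precision RSDs", {
  cfg <- fastConfig(seed = 61)
  prec <- precisionStudy(cfg, list(mid = lvls(20, 3)), nIntraday = 3,
                         nDays = 2, dayRsdPct = 0)
  expect_true(all(prec$intradayRsdPct < 1e-6))
  expect_true(all(prec$interdayRsdPct < 1e-6))
  expect_error(precisionStudy(cfg, list(lvls(20, 3)), nIntraday = 2),
               "nIntraday")
})

test_that("1% injection noise gives sub-2.5% intraday RSDs", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    cfg <- fastConfig(seed = 6000 + s, responseRsdPct = 1)
    prec <- precisionStudy(cfg, list(mid = lvls(20, 3)), nIntraday = 3,
                           nDays = 3, dayRsdPct = 1)
    hits <- hits + sum(prec$intradayRsdPct > 0.2 &
                       prec$intradayRsdPct < 2.5)
    total <- total + nrow(prec)
  }
  expect_gte(hits / total, 0.9)
})

test_that("a day effect makes interday exceed intraday precision", {
  cfg <- fastConfig(seed = 62, responseRsdPct = 0.5)
  prec <- precisionStudy(cfg, list(mid = lvls(20, 3)), nIntraday = 3,
                         nDays = 3, dayRsdPct = 3)
  expect_gt(mean(prec$interdayRsdPct), mean(prec$intradayRsdPct))
})

test_that("precision RSDs scale with the injected noise", {
  rsdAt <- function(pct) {
    cfg <- fastConfig(seed = 63, responseRsdPct = pct)
    mean(precisionStudy(cfg, list(mid = lvls(20, 3)), nIntraday = 3,
                        nDays = 2, dayRsdPct = 0)$intradayRsdPct)
  }
  ratio <- rsdAt(2) / rsdAt(0.5)
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("recovery is exact for a noiseless proportional assay", {
  cfg <- zeroInterceptConfig(seed = 64)
  rec <- recoveryStudy(cfg, baseSample = lvls(20, 3),
                       spikeLevels = list(mid = lvls(10, 2)), n = 3)
  expect_equal(rec$recoveryPct, rep(100, nrow(rec)), tolerance = 1e-3)
  expect_error(recoveryStudy(cfg, lvls(20, 3),
                             list(bad = lvls(0, 2))), "positive")
})

test_that("recovery at 1% noise brackets 100% the way a real assay does", {
  pooled <- numeric(); indiv <- numeric()
  for (s in 1:10) {
    cfg <- fastConfig(seed = 6500 + s, responseRsdPct = 1)
    rec <- recoveryStudy(cfg, baseSample = lvls(20, 3),
                         spikeLevels = list(low = lvls(10, 1.5),
                                            mid = lvls(20, 3),
                                            high = lvls(30, 4.5)), n = 3)
    pooled <- c(pooled, mean(rec$recoveryPct))
    indiv <- c(indiv, rec$recoveryPct)
  }
  ## campaign-level mean recoveries sit inside the 98-102% bracket
  expect_gte(mean(pooled >= 98 & pooled <= 102), 0.9)
  ## spike recovery is unbiased
  expect_equal(mean(indiv), 100, tolerance = 0.01)
  ## individual level recoveries stay physically sensible; the scatter
  ## of a single level grows as (base + added) / added, so the small
  ## ramosetron spikes legitimately wander a few percent
  expect_gte(mean(indiv >= 90 & indiv <= 110), 0.99)
})

test_that("stability RSD matches its closed form and flags decay", {
  hours <- c(0, 1, 2, 4, 6, 8)
  const <- data.frame(hours, a = rep(50, 6))
  expect_equal(stabilitySeries(const)$rsdPct, 0, tolerance = 1e-12)
  ## linear decay: RSD has a closed form sd/mean over the series
  decay <- function(totalPct) 100 * (1 - totalPct / 100 * hours / 8)
  for (pct in c(5, 8)) {
    areas <- decay(pct)
    st <- stabilitySeries(data.frame(hours, a = areas))
    expect_equal(st$rsdPct, 100 * sd(areas) / mean(areas),
                 tolerance = 1e-12)
  }
  ## a 5% total decay sits just under the 2% limit, 8% breaches it
  expect_true(stabilitySeries(data.frame(hours, a = decay(5)))$stable)
  expect_false(stabilitySeries(data.frame(hours, a = decay(8)))$stable)
  ## noisy but stable areas: RSD near the injected 1%
  set.seed(65)
  rsds <- vapply(1:50, function(i)
    stabilitySeries(data.frame(hours,
                               a = 100 * (1 + rnorm(6, 0, 0.01))))$rsdPct,
    numeric(1))
  expect_equal(mean(rsds), 1, tolerance = 0.7)
  expect_error(stabilitySeries(const[1:2, ]), "3 time points")
})

test_that("pure time-axis and gain perturbations leave RRT and RCF fixed", {
  cfg <- fastConfig(seed = 66)
  scaleGrid <- list(list(
    name = "timescale", values = c(0.95, 1, 1.05),
    perturb = function(config, value) {
      analytes <- lapply(config@analytes, function(a)
        initialize(a, retentionTime = a@retentionTime * value))
      names(analytes) <- names(config@analytes)
      marker <- initialize(config@marker,
        retentionTime = config@marker@retentionTime * value)
      initialize(config, analytes = analytes, marker = marker)
    }))
  rob <- robustnessCampaign(scaleGrid, cfg, concStd)
  expect_true(all(rob$rrt$timescale < 0.05))
  gainGrid <- list(list(
    name = "gain", values = c(0.8, 1, 1.25),
    perturb = function(config, value) {
      analytes <- lapply(config@analytes, function(a)
        initialize(a, slope = a@slope * value,
                   intercept = a@intercept * value))
      names(analytes) <- names(config@analytes)
      initialize(config, analytes = analytes)
    }))
  robG <- robustnessCampaign(gainGrid, cfg, concStd)
  expect_true(all(robG$rcf$gain < 0.05))
})

test_that("analyte-specific 1% retention shifts give sub-2% RRT scatter", {
  cfg <- fastConfig(seed = 67)
  shiftGrid <- list(list(
    name = "shift", values = c(-0.01, 0, 0.01),
    perturb = function(config, value) {
      analytes <- lapply(config@analytes, function(a) {
        if (a@name == "ondansetron") return(a)
        initialize(a, retentionTime = a@retentionTime * (1 + value))
      })
      names(analytes) <- names(config@analytes)
      initialize(config, analytes = analytes)
    }))
  rob <- robustnessCampaign(shiftGrid, cfg, concStd)
  nonRef <- rob$rrt$shift[rob$rrt$analyte != "ondansetron"]
  expect_true(all(nonRef > 0.3 & nonRef < 2))
})

test_that("the default robustness campaign is structurally sound", {
  cfg <- fastConfig(seed = 68, noiseSd = 0.02)
  rob <- robustnessCampaign(perturbationGrid(), cfg, concStd)
  facs <- c("flow", "temperature", "pH", "acetonitrile")
  for (tab in rob) {
    expect_identical(names(tab)[-1], facs)
    ## the internal reference's rows are identically zero
    refRow <- unlist(tab[tab$analyte == "ondansetron", facs])
    expect_true(all(refRow < 1e-8))
    others <- unlist(tab[tab$analyte != "ondansetron", facs])
    expect_true(all(others >= 0 & others < 20))
  }
  expect_error(
    robustnessCampaign(list(list(name = "broken", values = 1:3)),
                       cfg, concStd), "no perturbation mapping")
})
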