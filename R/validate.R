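## ICH-style validation campaigns on simulated runs: precision,
## recovery, stability and robustness of RRT and RCF under perturbed
## chromatographic conditions. All RSDs are 100 * sd / mean with the
## (n - 1) denominator.

.rsdPct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || mean(x) == 0) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

.withSeed <- function(config, seed) initialize(config, seed = as.integer(seed))

#' Intraday and interday precision study
#'
#' Simulates `nIntraday` replicate injections on each of `nDays` days
#' at each concentration level, measures peak areas through the full
#' detection pipeline, and reports per-analyte RSDs. Day-to-day
#' variability is emulated as a shared multiplicative detector factor
#' per day (sd `dayRsdPct`%). The intraday RSD is the mean of the
#' per-day RSDs; the interday RSD pools all injections across days.
#'
#' @param config A [RunConfig-class]; its `responseRsdPct` provides the
#'   injection-to-injection variability.
#' @param levels Named list of per-analyte concentration vectors, one
#'   entry per level (e.g. `list(low = c(ondansetron = 10, ...), ...)`).
#' @param nIntraday Replicates per day (>= 3).
#' @param nDays Days (>= 2).
#' @param dayRsdPct Between-day detector variability, percent.
#' @return A `data.frame`: `analyte`, `level`, `concentration`,
#'   `intradayRsdPct`, `interdayRsdPct`.
#' @export
precisionStudy <- function(config, levels, nIntraday = 3, nDays = 3,
                           dayRsdPct = 1) {
  stopifnot(is(config, "RunConfig"))
  if (nIntraday < 3) stop("nIntraday must be >= 3")
  if (nDays < 2) stop("nDays must be >= 2")
  if (is.null(names(levels))) names(levels) <- paste0("level", seq_along(levels))
  anames <- vapply(config@analytes, analyteName, character(1))
  out <- list()
  for (li in seq_along(levels)) {
    conc <- levels[[li]]
    set.seed(config@seed + 90000L + li)
    dayFac <- 1 + stats::rnorm(nDays, 0, dayRsdPct / 100)
    areas <- array(NA_real_, dim = c(length(anames), nDays, nIntraday),
                   dimnames = list(anames, NULL, NULL))
    for (d in seq_len(nDays)) for (r in seq_len(nIntraday)) {
      seed <- config@seed + 1000L * li + 100L * d + r
      run <- simulateRun(.withSeed(config, seed), conc)
      m <- measureRun(run)
      areas[, d, r] <- m$area[match(anames, m$analyte)] * dayFac[d]
    }
    for (a in anames) {
      if (is.na(conc[[a]]) || conc[[a]] <= 0) next
      mu <- mean(areas[a, , ], na.rm = TRUE)
      if (is.na(mu) || mu == 0) stop("zero mean area for ", a)
      perDay <- vapply(seq_len(nDays), function(d)
        .rsdPct(areas[a, d, ]), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        analyte = a, level = names(levels)[li],
        concentration = conc[[a]],
        intradayRsdPct = mean(perDay, na.rm = TRUE),
        interdayRsdPct = .rsdPct(as.vector(areas[a, , ])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Spike-recovery (accuracy) study
#'
#' Simulates a base sample and spiked samples at each spike level,
#' quantifies them by the external-standard route through the full
#' pipeline, and reports
#' `recovery% = (measured_spiked - measured_base) / added * 100`
#' per analyte and level with its RSD across `n` replicates. Negative
#' spike differences yield recoveries below 100%, never an error.
#'
#' @param config A [RunConfig-class].
#' @param baseSample Named per-analyte concentrations of the base
#'   sample, ug/mL.
#' @param spikeLevels Named list of per-analyte added amounts, one
#'   entry per spike level; all added amounts must be positive.
#' @param n Replicates per level (>= 3).
#' @param curves Optional named list of [CalibrationCurve-class]; by
#'   default fitted from measured simulated calibration runs
#'   ([measuredCurves()]), so that quantification shares the
#'   integrator's conventions with the sample measurements.
#' @return A `data.frame`: `analyte`, `level`, `added`,
#'   `recoveryPct`, `rsdPct`.
#' @export
recoveryStudy <- function(config, baseSample, spikeLevels, n = 3,
                          curves = NULL) {
  stopifnot(is(config, "RunConfig"))
  if (n < 3) stop("n must be >= 3")
  if (is.null(curves)) curves <- measuredCurves(config)
  if (is.null(names(spikeLevels)))
    names(spikeLevels) <- paste0("level", seq_along(spikeLevels))
  anames <- vapply(config@analytes, analyteName, character(1))

  esmConc <- function(run) {
    m <- measureRun(run)
    vapply(anames, function(a) {
      A <- m$area[m$analyte == a]
      if (is.na(A)) return(NA_real_)
      as.numeric(quantifyESM(A, curves[[a]]))
    }, numeric(1))
  }

  base <- vapply(seq_len(n), function(r) {
    esmConc(simulateRun(.withSeed(config, config@seed + 50000L + r),
                        baseSample))
  }, numeric(length(anames)))
  baseMean <- rowMeans(base, na.rm = TRUE)

  out <- list()
  for (li in seq_along(spikeLevels)) {
    added <- spikeLevels[[li]]
    if (any(added[anames] <= 0, na.rm = TRUE))
      stop("all added amounts must be positive")
    spiked <- baseSample
    spiked[names(added)] <- spiked[names(added)] + added
    meas <- vapply(seq_len(n), function(r) {
      esmConc(simulateRun(.withSeed(config,
                                    config@seed + 60000L + 1000L * li + r),
                          spiked))
    }, numeric(length(anames)))
    for (a in anames) {
      if (!a %in% names(added) || is.na(added[[a]])) next
      rec <- (meas[match(a, anames), ] - baseMean[[a]]) / added[[a]] * 100
      out[[length(out) + 1]] <- data.frame(
        analyte = a, level = names(spikeLevels)[li], added = added[[a]],
        recoveryPct = mean(rec, na.rm = TRUE), rsdPct = .rsdPct(rec),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Solution-stability RSD over a time series
#'
#' RSD% of peak areas across a series of injections of the same
#' solution over time (e.g. at 0, 1, 2, 4, 6 and 8 h). Series with an
#' RSD above `limitPct` are flagged unstable.
#'
#' @param areasOverTime A data.frame whose first column is the time in
#'   hours and remaining columns are per-analyte peak areas (>= 3 time
#'   points).
#' @param limitPct Stability acceptance limit, percent (default 2).
#' @return A `data.frame`: `analyte`, `rsdPct`, `stable`.
#' @export
stabilitySeries <- function(areasOverTime, limitPct = 2) {
  df <- as.data.frame(areasOverTime)
  if (nrow(df) < 3) stop("at least 3 time points are required")
  analytes <- names(df)[-1]
  data.frame(
    analyte = analytes,
    rsdPct = vapply(analytes, function(a) .rsdPct(df[[a]]), numeric(1)),
    stable = vapply(analytes, function(a)
      .rsdPct(df[[a]]) <= limitPct, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Default chromatographic perturbation grid
#'
#' The four robustness factors — flow rate (+/- 0.02 mL/min), column
#' temperature (+/- 1 C), mobile-phase pH (+/- 0.2) and acetonitrile
#' fraction (+/- 2%) — each with a nominal and two perturbed levels,
#' together with their declared mappings onto the simulator. The
#' mappings are structural stand-ins (no physical retention model is
#' attempted): flow rescales the whole time axis and inversely scales
#' areas, with a small analyte-specific secondary term; temperature,
#' pH and acetonitrile apply small analyte-specific retention and
#' response multipliers. The unretained marker only follows the global
#' time-axis scale.
#'
#' @return A list of factor entries, each with `name`, `values` and a
#'   `perturb(config, value)` function returning a perturbed
#'   [RunConfig-class].
#' @export
perturbationGrid <- function() {
  ## analyte-specific sensitivity coefficients (recycled to the roster
  ## length for non-default rosters)
  kFlow <- c(0.30, 0.50, 0.20, 0.40, 0.60)
  kTemp <- c(0.008, 0.010, 0.012, 0.009, 0.011)
  kTempResp <- c(0.002, 0.003, 0.001, 0.002, 0.004)
  kPh <- c(0.10, 0.08, 0.12, 0.09, 0.07)
  kPhResp <- c(0.05, 0.03, 0.06, 0.04, 0.05)
  kAcn <- c(0.060, 0.070, 0.080, 0.075, 0.085)
  kAcnResp <- c(0.004, 0.003, 0.005, 0.004, 0.006)

  scaleAnalytes <- function(config, rtMult, respMult,
                            markerTimeMult = 1) {
    nA <- length(config@analytes)
    rtMult <- rep_len(rtMult, nA)
    respMult <- rep_len(respMult, nA)
    analytes <- lapply(seq_len(nA), function(i) {
      a <- config@analytes[[i]]
      initialize(a, retentionTime = a@retentionTime * rtMult[i],
                 slope = a@slope * respMult[i],
                 intercept = a@intercept * respMult[i])
    })
    names(analytes) <- names(config@analytes)
    marker <- initialize(config@marker,
      retentionTime = config@marker@retentionTime * markerTimeMult)
    initialize(config, analytes = analytes, marker = marker)
  }

  list(
    list(name = "flow", values = c(0.98, 1.00, 1.02),
         perturb = function(config, value) {
           ts <- 1 / value
           nA <- length(config@analytes)
           scaleAnalytes(config,
             rtMult = ts * (1 + rep_len(kFlow, nA) * (value - 1)),
             respMult = ts, markerTimeMult = ts)
         }),
    list(name = "temperature", values = c(29, 30, 31),
         perturb = function(config, value) {
           dT <- value - 30
           nA <- length(config@analytes)
           scaleAnalytes(config,
             rtMult = 1 - rep_len(kTemp, nA) * dT,
             respMult = 1 + rep_len(kTempResp, nA) * dT)
         }),
    list(name = "pH", values = c(3.8, 4.0, 4.2),
         perturb = function(config, value) {
           dp <- value - 4.0
           nA <- length(config@analytes)
           scaleAnalytes(config,
             rtMult = 1 + rep_len(kPh, nA) * dp,
             respMult = 1 + rep_len(kPhResp, nA) * dp)
         }),
    list(name = "acetonitrile", values = c(23, 25, 27),
         perturb = function(config, value) {
           dx <- value - 25
           nA <- length(config@analytes)
           scaleAnalytes(config,
             rtMult = exp(-rep_len(kAcn, nA) * dx),
             respMult = 1 + rep_len(kAcnResp, nA) * dx)
         })
  )
}

#' Robustness campaign for RRT and RCF
#'
#' For every perturbation factor, runs the simulator at the nominal
#' and the two perturbed levels, re-detects all peaks, and recomputes
#' each analyte's relative retention time (against the dead-time
#' marker and the internal reference) and per-level relative
#' correction factor `(A_x/C_x)/(A_i/C_i)`. The RSD% across the three
#' conditions is reported per factor and analyte. The internal
#' reference's rows are identically zero by construction (its RRT and
#' RCF are both 1 in every condition).
#'
#' @param grid A perturbation grid as from [perturbationGrid()].
#' @param config A [RunConfig-class].
#' @param concentrations Named per-analyte concentrations, ug/mL,
#'   injected in every condition.
#' @param reference Internal reference analyte.
#' @return A list of two data.frames, `rrt` and `rcf`, each with one
#'   row per analyte and one RSD% column per factor.
#' @export
robustnessCampaign <- function(grid, config, concentrations,
                               reference = "ondansetron") {
  stopifnot(is(config, "RunConfig"))
  anames <- vapply(config@analytes, analyteName, character(1))
  if (!reference %in% anames)
    stop("reference analyte '", reference, "' is not configured")
  rrtRsd <- rcfRsd <- matrix(NA_real_, nrow = length(anames),
                             ncol = length(grid),
                             dimnames = list(anames,
                               vapply(grid, `[[`, character(1), "name")))
  for (g in seq_along(grid)) {
    fac <- grid[[g]]
    if (!is.function(fac$perturb))
      stop("factor '", fac$name, "' has no perturbation mapping")
    rrts <- rcfs <- matrix(NA_real_, nrow = length(anames),
                           ncol = length(fac$values))
    for (v in seq_along(fac$values)) {
      pc <- fac$perturb(config, fac$values[v])
      pc <- .withSeed(pc, config@seed + 70000L + 100L * g + v)
      run <- simulateRun(pc, concentrations)
      m <- measureRun(run)
      t0 <- m$apexTime[m$analyte == "marker"]
      ti <- m$apexTime[m$analyte == reference]
      Ai <- m$area[m$analyte == reference]
      Ci <- concentrations[[reference]]
      for (i in seq_along(anames)) {
        tx <- m$apexTime[m$analyte == anames[i]]
        Ax <- m$area[m$analyte == anames[i]]
        Cx <- concentrations[[anames[i]]]
        if (!is.na(tx)) rrts[i, v] <- relativeRetentionTime(tx, ti, t0)
        if (!is.na(Ax) && Cx > 0)
          rcfs[i, v] <- (Ax / Cx) / (Ai / Ci)
      }
    }
    rrtRsd[, g] <- apply(rrts, 1, .rsdPct)
    rcfRsd[, g] <- apply(rcfs, 1, .rsdPct)
  }
  asDf <- function(m) data.frame(analyte = rownames(m), m,
                                 row.names = NULL,
                                 stringsAsFactors = FALSE)
  list(rrt = asDf(rrtRsd), rcf = asDf(rcfRsd))
}
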