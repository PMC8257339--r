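## Run-level pipeline: measure per-analyte peak areas from a DAD run
## and quantify them by the single-marker and external-standard routes.

#' Measure per-analyte peak areas in a DAD run
#'
#' Extracts the trace at each compound's detection wavelength, detects
#' peaks, and assigns to each configured compound (analytes and the
#' dead-time marker) the detected peak nearest its expected retention
#' time (within `5 * sigma + 0.1` min). Compounds without a matching
#' peak get NA rows.
#'
#' @param run A [DADRun-class].
#' @param minSnr Detection threshold passed to [detectPeaks()].
#' @return A `data.frame`: `analyte`, `apexTime`, `area`, `height`,
#'   `snr`, one row per configured compound (marker last).
#' @export
measureRun <- function(run, minSnr = 10) {
  stopifnot(is(run, "DADRun"))
  cfg <- run@config
  compounds <- c(cfg@analytes, list(cfg@marker))
  wls <- vapply(compounds, function(a) a@detectionWavelength, numeric(1))
  peakCache <- list()
  rows <- lapply(seq_along(compounds), function(k) {
    a <- compounds[[k]]
    key <- as.character(wls[k])
    if (is.null(peakCache[[key]])) {
      peakCache[[key]] <<- detectPeaks(extractTrace(run, wls[k]),
                                       minSnr = minSnr)
    }
    pk <- peakCache[[key]]
    out <- data.frame(analyte = a@name, apexTime = NA_real_,
                      area = NA_real_, height = NA_real_, snr = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(pk)) {
      d <- abs(pk$apexTime - a@retentionTime)
      i <- which.min(d)
      if (d[i] <= 5 * a@sigma + 0.1) {
        out$apexTime <- pk$apexTime[i]
        out$area <- pk$area[i]
        out$height <- pk$height[i]
        out$snr <- pk$snr[i]
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Quantify a measured run by QAMS and ESM
#'
#' Single-marker route: the internal reference's concentration is read
#' off its own calibration curve, and every other analyte follows from
#' `C_x = C_i / RCF_x * A_x / A_i`. External-standard route: each
#' analyte against its own curve. Analytes whose peak was not found are
#' reported with NA and do not affect the others.
#'
#' @param measured Output of [measureRun()] (or a compatible
#'   data.frame with `analyte` and `area`).
#' @param curves Named list of [CalibrationCurve-class] objects; for
#'   the QAMS route only the reference's curve is required.
#' @param rcf A data.frame from [rcfTable()] (columns `analyte`,
#'   `rcf`).
#' @param reference Internal reference analyte name.
#' @return A `data.frame`: `analyte`, `area`, `cQams`, `cEsm`.
#' @export
quantifyRun <- function(measured, curves, rcf,
                        reference = "ondansetron") {
  if (!reference %in% measured$analyte)
    stop("reference analyte '", reference, "' not among the measurements")
  Ai <- measured$area[measured$analyte == reference]
  if (is.na(Ai) || Ai <= 0)
    stop("reference peak not identified in this run; cannot quantify")
  if (!reference %in% names(curves))
    stop("a calibration curve for the reference analyte is required")
  Ci <- as.numeric(quantifyESM(Ai, curves[[reference]]))
  keep <- measured$analyte != "marker"
  m <- measured[keep, , drop = FALSE]
  res <- data.frame(analyte = m$analyte, area = m$area,
                    cQams = NA_real_, cEsm = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    a <- res$analyte[i]
    if (is.na(res$area[i])) next
    f <- rcf$rcf[rcf$analyte == a]
    if (length(f) == 1 && !is.na(f))
      res$cQams[i] <- quantifyQAMS(res$area[i], Ai, Ci, f)
    if (a %in% names(curves))
      res$cEsm[i] <- as.numeric(quantifyESM(res$area[i], curves[[a]]))
  }
  res
}

#' Calibration curves from the configured response lines
#'
#' Generates noiseless calibration points on each configured analyte's
#' response line at the given concentration levels and fits them with
#' [fitCalibration()]. This reproduces the configured slopes and
#' intercepts exactly and is the standard way to obtain curves for a
#' simulated assay without re-measuring calibration runs peak by peak.
#'
#' @param config A [RunConfig-class].
#' @param levels Named list of concentration vectors per analyte
#'   (default [calibrationLevels()] where names match, else the
#'   standard 5-100 ug/mL series).
#' @return Named list of [CalibrationCurve-class] objects.
#' @export
curvesFromConfig <- function(config, levels = NULL) {
  stopifnot(is(config, "RunConfig"))
  anames <- vapply(config@analytes, analyteName, character(1))
  if (is.null(levels)) {
    std <- calibrationLevels()
    levels <- lapply(anames, function(a)
      if (a %in% names(std)) std[[a]] else c(5, 10, 20, 50, 75, 100))
    names(levels) <- anames
  }
  curves <- lapply(seq_along(config@analytes), function(i) {
    a <- config@analytes[[i]]
    cc <- levels[[a@name]]
    fitCalibration(cc, a@slope * cc + a@intercept, analyte = a@name)
  })
  names(curves) <- anames
  curves
}

#' Calibration curves from measured simulated calibration runs
#'
#' Simulates one noiseless mixed-standard injection per calibration
#' level, measures the peak areas through the full detection pipeline
#' ([measureRun()]) and fits the curves on the measured areas. Unlike
#' [curvesFromConfig()], which uses the nominal response lines, these
#' curves carry the integrator's conventions (baseline estimation and
#' the 1%-of-height boundary rule), exactly as a laboratory calibration
#' does — so sample quantification against them is free of the small
#' systematic integration bias.
#'
#' @param config A [RunConfig-class]; noise settings are ignored for
#'   the calibration runs.
#' @param levels Named list of per-analyte concentration vectors (all
#'   the same length), default [calibrationLevels()].
#' @return Named list of [CalibrationCurve-class] objects.
#' @export
measuredCurves <- function(config, levels = NULL) {
  stopifnot(is(config, "RunConfig"))
  anames <- vapply(config@analytes, analyteName, character(1))
  if (is.null(levels)) {
    std <- calibrationLevels()
    levels <- lapply(anames, function(a)
      if (a %in% names(std)) std[[a]] else c(5, 10, 20, 50, 75, 100))
    names(levels) <- anames
  }
  nLev <- unique(lengths(levels))
  if (length(nLev) != 1)
    stop("all analytes need the same number of calibration levels")
  clean <- initialize(config, noiseSd = 0, baselineDrift = 0,
                      responseRsdPct = 0)
  areas <- matrix(NA_real_, nrow = nLev, ncol = length(anames),
                  dimnames = list(NULL, anames))
  for (l in seq_len(nLev)) {
    conc <- vapply(levels, `[`, numeric(1), l)[anames]
    run <- simulateRun(.withSeed(clean, clean@seed + 80000L + l), conc)
    m <- measureRun(run)
    areas[l, ] <- m$area[match(anames, m$analyte)]
  }
  curves <- lapply(anames, function(a)
    fitCalibration(levels[[a]], areas[, a], analyte = a))
  names(curves) <- anames
  curves
}
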