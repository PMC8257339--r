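## Built-in specification of the five-setron assay.
##
## Response lines (slope, intercept) and detection wavelengths are the
## published calibration constants of the assay; retention times are
## back-computed from the assay's relative retention times with the
## dead-time marker at 1.20 min and ondansetron at 9.00 min on a 15-min
## run at 1.0 mL/min. Peak widths and UV band shapes are simulator
## choices (instrument spectra are not published): bands are placed so
## that ondansetron/ramosetron are the most spectrally alike pair and
## first-derivative similarity separates the rest, matching the assay's
## observed rank order.

.setronTable <- function() {
  data.frame(
    name      = c("azasetron", "granisetron", "tropisetron",
                  "ondansetron", "ramosetron"),
    rrt       = c(0.431, 0.679, 0.812, 1.000, 1.132),
    sigma     = c(0.060, 0.075, 0.085, 0.095, 0.105),
    slope     = c(0.6321, 0.6957, 1.0634, 1.8585, 2.3167),
    intercept = c(1.3833, 0.5444, 4.8592, 5.2914, 8.6551),
    wl        = c(307, 302, 285, 307, 307),
    stringsAsFactors = FALSE
  )
}

.setronBands <- function() {
  list(
    azasetron = cbind(center = c(214, 237, 307),
                      width  = c(9, 8, 14),
                      height = c(1.00, 0.50, 0.30)),
    granisetron = cbind(center = c(229, 252, 302),
                        width  = c(10, 9, 12),
                        height = c(1.00, 0.32, 0.30)),
    tropisetron = cbind(center = c(219, 263, 285),
                        width  = c(9, 10, 12),
                        height = c(1.00, 0.30, 0.35)),
    ondansetron = cbind(center = c(215, 267, 306),
                        width  = c(11, 13, 15),
                        height = c(1.00, 0.32, 0.55)),
    ramosetron = cbind(center = c(219, 262, 311),
                       width  = c(12, 13, 16),
                       height = c(1.00, 0.30, 0.55))
  )
}

#' Built-in analyte roster of the five-setron assay
#'
#' Returns [AnalyteSpec-class] objects for azasetron, granisetron,
#' tropisetron, ondansetron and ramosetron with the assay's published
#' response lines (peak area in mAU.min versus concentration in ug/mL)
#' and detection wavelengths (307, 302, 285, 307 and 307 nm), and
#' simulator defaults for retention (dead time 1.20 min, ondansetron at
#' 9.00 min, the others placed by their relative retention times) and
#' peak width.
#'
#' @param tau Exponential tailing constant in minutes applied to every
#'   analyte (default 0, pure Gaussian peaks).
#' @return Named list of five [AnalyteSpec-class] objects.
#' @examples
#' setronAnalytes()[["ondansetron"]]
#' @seealso [deadTimeMarker()], [defaultRunConfig()]
#' @export
setronAnalytes <- function(tau = 0) {
  tab <- .setronTable()
  bands <- .setronBands()
  t0 <- 1.20
  ti <- 9.00
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    analyteSpec(
      name = tab$name[i],
      retentionTime = t0 + tab$rrt[i] * (ti - t0),
      sigma = tab$sigma[i],
      tau = tau,
      slope = tab$slope[i],
      intercept = tab$intercept[i],
      uvBands = bands[[tab$name[i]]],
      detectionWavelength = tab$wl[i]
    )
  })
  names(specs) <- tab$name
  specs
}

#' Dead-time marker specification
#'
#' An unretained, spectrally distinct marker compound (a uracil-like
#' pyrimidine) eluting at the column dead time, used to correct
#' retention times for the dead volume when computing relative
#' retention times.
#'
#' @param retentionTime Dead time in minutes (default 1.20).
#' @return An [AnalyteSpec-class] object named `"marker"`.
#' @export
deadTimeMarker <- function(retentionTime = 1.20) {
  analyteSpec(
    name = "marker",
    retentionTime = retentionTime,
    sigma = 0.040,
    tau = 0,
    slope = 0.9,
    intercept = 0,
    uvBands = cbind(center = c(258), width = c(9), height = c(1)),
    detectionWavelength = 260
  )
}

#' Default run configuration of the five-setron assay
#'
#' A 15-minute run sampled at 120 points/min with the five setron
#' analytes of [setronAnalytes()], the dead-time marker at 1.20 min, a
#' 220-400 nm wavelength grid at 1 nm steps (so that every detection
#' wavelength lies exactly on the grid), and no noise or drift
#' unless requested.
#'
#' @param seed Integer seed (mandatory).
#' @param noiseSd Additive detector noise sd, mAU (default 0).
#' @param baselineDrift Linear drift, mAU/min (default 0).
#' @param responseRsdPct Per-injection response variability, percent
#'   (default 0).
#' @param wavelengthGrid Detector wavelength grid, nm.
#' @param tau Peak tailing constant passed to [setronAnalytes()].
#' @return A [RunConfig-class] object.
#' @examples
#' cfg <- defaultRunConfig(seed = 1)
#' cfg
#' @export
defaultRunConfig <- function(seed, noiseSd = 0, baselineDrift = 0,
                             responseRsdPct = 0,
                             wavelengthGrid = seq(220, 400, by = 1),
                             tau = 0) {
  runConfig(
    analytes = setronAnalytes(tau = tau),
    marker = deadTimeMarker(),
    runLength = 15,
    samplingRate = 120,
    wavelengthGrid = wavelengthGrid,
    baselineDrift = baselineDrift,
    noiseSd = noiseSd,
    responseRsdPct = responseRsdPct,
    markerConcentration = 20,
    seed = seed
  )
}

#' Published calibration levels of the assay
#'
#' The concentration series used for the calibration graphs: 5, 10, 20,
#' 50, 75 and 100 ug/mL for azasetron, granisetron, tropisetron and
#' ondansetron, and 0.5, 3, 6, 20, 30 and 50 ug/mL for ramosetron.
#'
#' @return Named list of numeric concentration vectors (ug/mL).
#' @export
calibrationLevels <- function() {
  std <- c(5, 10, 20, 50, 75, 100)
  list(
    azasetron = std, granisetron = std, tropisetron = std,
    ondansetron = std, ramosetron = c(0.5, 3, 6, 20, 30, 50)
  )
}
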