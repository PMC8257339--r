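#' @import methods
NULL

#' Single-wavelength chromatogram
#'
#' An S4 container for a detector trace at one wavelength: a strictly
#' increasing retention-time axis (minutes) and the matching absorbance
#' values (mAU). Smoothing, derivative and peak-detection operations
#' additionally require a uniform time grid (checked where needed, to a
#' tolerance of 1e-6 min).
#'
#' @slot rtime Numeric, retention time in minutes, strictly increasing.
#' @slot intensity Numeric, absorbance in mAU, same length as `rtime`.
#' @slot wavelength Numeric scalar, detection wavelength in nm (`NA` if
#'   unknown or not applicable).
#' @slot metadata List of free-form provenance fields (run id, snap
#'   records, baseline-point masks and the like).
#'
#' @seealso [Chromatogram()] for the user-facing constructor.
#' @export
setClass("Chromatogram",
  slots = c(
    rtime = "numeric",
    intensity = "numeric",
    wavelength = "numeric",
    metadata = "list"
  ),
  prototype = prototype(wavelength = NA_real_, metadata = list())
)

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@rtime) != length(object@intensity))
    msg <- c(msg, "rtime and intensity must have equal length")
  if (length(object@rtime) >= 2 && any(diff(object@rtime) <= 0))
    msg <- c(msg, "rtime must be strictly increasing")
  if (anyNA(object@rtime))
    msg <- c(msg, "rtime must not contain NA")
  if (length(object@wavelength) != 1)
    msg <- c(msg, "wavelength must be a single value")
  if (length(msg)) msg else TRUE
})

#' Construct a Chromatogram
#'
#' @param rtime Retention time in minutes, strictly increasing.
#' @param intensity Absorbance in mAU, same length as `rtime`.
#' @param wavelength Detection wavelength in nm.
#' @param metadata Optional list of provenance fields.
#'
#' @return A [Chromatogram-class] object.
#' @examples
#' tm <- seq(0, 2, by = 0.01)
#' chr <- Chromatogram(tm, exp(-(tm - 1)^2 / (2 * 0.05^2)), wavelength = 307)
#' chr
#' @export
Chromatogram <- function(rtime, intensity, wavelength = NA_real_,
                         metadata = list()) {
  obj <- new("Chromatogram", rtime = as.numeric(rtime),
             intensity = as.numeric(intensity),
             wavelength = as.numeric(wavelength)[1], metadata = metadata)
  if (length(rtime) < 50)
    warning("chromatogram has fewer than 50 points; ",
            "smoothing and peak detection may be unreliable")
  obj
}

#' UV absorbance spectrum
#'
#' A diode-array-detector UV spectrum: absorbance (mAU, baseline
#' subtracted) on a wavelength grid (nm). Similarity computations require
#' a non-degenerate (not all-zero) spectrum.
#'
#' @slot wavelength Numeric, wavelength grid in nm, strictly increasing.
#' @slot absorbance Numeric, absorbance in mAU.
#' @slot analyte Character scalar label (`NA` if unassigned).
#' @seealso [SpectrumUV()], [cosineSimilarity()], [firstDerivative()]
#' @export
setClass("SpectrumUV",
  slots = c(
    wavelength = "numeric",
    absorbance = "numeric",
    analyte = "character"
  ),
  prototype = prototype(analyte = NA_character_)
)

setValidity("SpectrumUV", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@absorbance))
    msg <- c(msg, "wavelength and absorbance must have equal length")
  if (length(object@wavelength) >= 2 && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (length(object@analyte) != 1)
    msg <- c(msg, "analyte must be a single label")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumUV
#'
#' @param wavelength Wavelength grid in nm, strictly increasing.
#' @param absorbance Absorbance in mAU, same length as `wavelength`.
#' @param analyte Optional analyte label.
#' @return A [SpectrumUV-class] object.
#' @export
SpectrumUV <- function(wavelength, absorbance, analyte = NA_character_) {
  new("SpectrumUV", wavelength = as.numeric(wavelength),
      absorbance = as.numeric(absorbance),
      analyte = as.character(analyte)[1])
}

#' Analyte specification for the LC-DAD simulator
#'
#' Everything the simulator needs to place one compound in a run: its
#' chromatographic peak (retention time, Gaussian width, optional
#' exponential tailing), its detector response line (peak area in
#' mAU.min versus concentration in ug/mL), and its UV spectrum as a
#' small set of Gaussian absorption bands.
#'
#' @slot name Character, analyte name.
#' @slot retentionTime Minutes; must exceed the run's dead time.
#' @slot sigma Gaussian peak width (standard deviation) in minutes.
#' @slot tau Exponential tailing time constant in minutes; 0 gives a
#'   pure Gaussian, > 0 an exponentially modified Gaussian.
#' @slot slope Response slope, area (mAU.min) per (ug/mL).
#' @slot intercept Response intercept, area (mAU.min).
#' @slot uvBands Numeric matrix with columns `center` (nm), `width`
#'   (nm, Gaussian sd) and `height` (relative), one row per band.
#' @slot detectionWavelength nm; the wavelength at which the response
#'   line is defined and the analyte is quantified.
#' @seealso [analyteSpec()], [setronAnalytes()]
#' @export
setClass("AnalyteSpec",
  slots = c(
    name = "character",
    retentionTime = "numeric",
    sigma = "numeric",
    tau = "numeric",
    slope = "numeric",
    intercept = "numeric",
    uvBands = "matrix",
    detectionWavelength = "numeric"
  )
)

setValidity("AnalyteSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (object@slope <= 0) msg <- c(msg, "response slope must be > 0")
  if (nrow(object@uvBands) < 1)
    msg <- c(msg, "uvBands must contain at least one band")
  if (ncol(object@uvBands) != 3)
    msg <- c(msg, "uvBands must have columns center, width, height")
  if (nrow(object@uvBands) >= 1 &&
      (any(object@uvBands[, 2] <= 0) || any(object@uvBands[, 3] <= 0)))
    msg <- c(msg, "uvBands widths and heights must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalyteSpec
#'
#' @param name Analyte name.
#' @param retentionTime Apex retention time in minutes.
#' @param sigma Gaussian peak width (sd) in minutes.
#' @param tau Exponential tailing constant in minutes (0 = Gaussian).
#' @param slope,intercept Linear response: area = slope * conc + intercept.
#' @param uvBands Matrix (or 3-column data.frame) of UV bands:
#'   center nm, width nm, relative height.
#' @param detectionWavelength Quantification wavelength in nm.
#' @return An [AnalyteSpec-class] object.
#' @examples
#' analyteSpec("ondansetron", 9.0, 0.095,
#'   slope = 1.8585, intercept = 5.2914,
#'   uvBands = cbind(c(216, 265, 307), c(12, 15, 14), c(1, 0.25, 0.35)),
#'   detectionWavelength = 307)
#' @export
analyteSpec <- function(name, retentionTime, sigma, tau = 0,
                        slope, intercept = 0, uvBands,
                        detectionWavelength) {
  uvBands <- as.matrix(uvBands)
  colnames(uvBands) <- c("center", "width", "height")
  new("AnalyteSpec", name = name, retentionTime = as.numeric(retentionTime),
      sigma = as.numeric(sigma), tau = as.numeric(tau),
      slope = as.numeric(slope), intercept = as.numeric(intercept),
      uvBands = uvBands,
      detectionWavelength = as.numeric(detectionWavelength))
}

#' Run configuration for the LC-DAD simulator
#'
#' @slot analytes List of [AnalyteSpec-class] objects (the quantified
#'   compounds).
#' @slot marker [AnalyteSpec-class] for the unretained dead-time marker.
#' @slot runLength Minutes.
#' @slot samplingRate Points per minute.
#' @slot wavelengthGrid nm values recorded by the detector.
#' @slot baselineDrift mAU per minute, linear.
#' @slot noiseSd Additive i.i.d. Gaussian noise sd, mAU per point.
#' @slot responseRsdPct Per-analyte, per-injection multiplicative
#'   response-factor variability in percent (emulates injection-to-
#'   injection area scatter; 0 = none).
#' @slot markerConcentration ug/mL of the dead-time marker in every run.
#' @slot seed Integer random seed; mandatory for reproducibility.
#' @seealso [runConfig()], [defaultRunConfig()], [simulateRun()]
#' @export
setClass("RunConfig",
  slots = c(
    analytes = "list",
    marker = "AnalyteSpec",
    runLength = "numeric",
    samplingRate = "numeric",
    wavelengthGrid = "numeric",
    baselineDrift = "numeric",
    noiseSd = "numeric",
    responseRsdPct = "numeric",
    markerConcentration = "numeric",
    seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!length(object@analytes))
    msg <- c(msg, "at least one analyte is required")
  if (!all(vapply(object@analytes, is, logical(1), "AnalyteSpec")))
    msg <- c(msg, "analytes must all be AnalyteSpec objects")
  else {
    rts <- vapply(object@analytes, function(a) a@retentionTime, numeric(1))
    sds <- vapply(object@analytes, function(a) a@sigma, numeric(1))
    if (any(rts <= object@marker@retentionTime))
      msg <- c(msg, "every analyte must elute after the dead-time marker")
    if (object@runLength < max(rts + 5 * sds))
      msg <- c(msg, "runLength must cover the last peak plus 5 sigma")
    minSigma <- min(c(sds, object@marker@sigma))
    if (object@samplingRate * 4 * minSigma < 10)
      msg <- c(msg,
        "samplingRate must give at least 10 points across the narrowest peak")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@responseRsdPct < 0) msg <- c(msg, "responseRsdPct must be >= 0")
  if (length(object@wavelengthGrid) < 1 ||
      (length(object@wavelengthGrid) >= 2 &&
       any(diff(object@wavelengthGrid) <= 0)))
    msg <- c(msg, "wavelengthGrid must be non-empty and strictly increasing")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param analytes List of [AnalyteSpec-class] objects.
#' @param marker [AnalyteSpec-class] for the unretained marker.
#' @param runLength Run length, minutes.
#' @param samplingRate Detector sampling, points per minute.
#' @param wavelengthGrid Recorded wavelengths, nm.
#' @param baselineDrift Linear drift, mAU/min.
#' @param noiseSd Additive noise sd, mAU.
#' @param responseRsdPct Per-injection response variability, percent.
#' @param markerConcentration Marker concentration, ug/mL.
#' @param seed Integer seed (mandatory).
#' @return A [RunConfig-class] object.
#' @export
runConfig <- function(analytes, marker, runLength = 15,
                      samplingRate = 120,
                      wavelengthGrid = seq(220, 400, by = 1),
                      baselineDrift = 0, noiseSd = 0,
                      responseRsdPct = 0, markerConcentration = 20,
                      seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("runConfig: 'seed' is mandatory and must be an integer")
  new("RunConfig", analytes = analytes, marker = marker,
      runLength = as.numeric(runLength),
      samplingRate = as.numeric(samplingRate),
      wavelengthGrid = as.numeric(wavelengthGrid),
      baselineDrift = as.numeric(baselineDrift),
      noiseSd = as.numeric(noiseSd),
      responseRsdPct = as.numeric(responseRsdPct),
      markerConcentration = as.numeric(markerConcentration),
      seed = as.integer(seed))
}

#' Simulated LC-DAD run
#'
#' Full diode-array data for one injection: an absorbance matrix over a
#' time x wavelength grid plus the per-analyte ground truth (injected
#' concentration, nominal and realised peak areas, true apex times) and
#' the generating configuration.
#'
#' @slot rtime Minutes, the time grid.
#' @slot wavelength nm, the wavelength grid.
#' @slot absorbance Matrix, time in rows, wavelength in columns, mAU.
#' @slot groundTruth data.frame: analyte, concentration, nominalArea
#'   (slope*C + intercept), simulatedArea (after response noise),
#'   apexTime, detectionWavelength.
#' @slot config The generating [RunConfig-class].
#' @slot flags Character vector of warnings raised during generation
#'   (e.g. insufficient peak spacing).
#' @export
setClass("DADRun",
  slots = c(
    rtime = "numeric",
    wavelength = "numeric",
    absorbance = "matrix",
    groundTruth = "data.frame",
    config = "RunConfig",
    flags = "character"
  )
)

setValidity("DADRun", function(object) {
  msg <- character()
  if (nrow(object@absorbance) != length(object@rtime))
    msg <- c(msg, "absorbance rows must match the time grid")
  if (ncol(object@absorbance) != length(object@wavelength))
    msg <- c(msg, "absorbance columns must match the wavelength grid")
  if (length(msg)) msg else TRUE
})

#' Linear calibration curve for one analyte
#'
#' Ordinary (optionally weighted) least-squares calibration of peak area
#' against concentration, fitted on per-level mean areas, with the
#' Pearson correlation of the level means and signal-to-noise based
#' detection and quantification limits.
#'
#' @slot analyte Character, analyte name.
#' @slot slope Area (mAU.min) per (ug/mL).
#' @slot intercept Area (mAU.min).
#' @slot r Pearson correlation coefficient of the level means.
#' @slot levels data.frame: concentration, meanArea, rsdPct (RSD% across
#'   replicate injections; NA for single injections), n.
#' @slot lod,loq ug/mL (NA until [lodLoq()] is applied).
#' @slot linearRange ug/mL, `c(min, max)` of the calibrated levels.
#' @slot weighting One of "none", "1/x", "1/x2".
#' @seealso [fitCalibration()], [lodLoq()], [quantifyESM()]
#' @export
setClass("CalibrationCurve",
  slots = c(
    analyte = "character",
    slope = "numeric",
    intercept = "numeric",
    r = "numeric",
    levels = "data.frame",
    lod = "numeric",
    loq = "numeric",
    linearRange = "numeric",
    weighting = "character"
  ),
  prototype = prototype(lod = NA_real_, loq = NA_real_, weighting = "none")
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@slope <= 0) msg <- c(msg, "slope must be > 0")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (!is.na(object@lod) && !is.na(object@loq) && object@lod >= object@loq)
    msg <- c(msg, "lod must be below loq")
  if (nrow(object@levels) > 0 &&
      length(unique(object@levels$concentration)) < 5)
    msg <- c(msg, "at least 5 distinct concentration levels are required")
  if (length(msg)) msg else TRUE
})

#' Qualitative identification result
#'
#' The double-indicator verdict for one chromatographic peak: the
#' dead-time-corrected relative retention time (RRT) against the best
#' matching library candidate, and the raw plus first-derivative UV
#' spectral cosine similarities against that candidate's reference
#' spectrum. The peak is identified only if both indicators pass.
#'
#' @slot candidate Character, best-matching library analyte.
#' @slot rrt Observed relative retention time.
#' @slot rrtReference Library RRT of the candidate.
#' @slot rawSimilarity Cosine similarity of the raw spectra, in \[-1, 1\].
#' @slot derivSimilarity Cosine similarity of the first-derivative
#'   spectra, in \[-1, 1\].
#' @slot rrtPass,spectrumPass,identified Logical indicator verdicts;
#'   `identified` is the conjunction of the other two.
#' @slot ambiguous Logical; TRUE when more than one library candidate
#'   fell inside the RRT window (spectrum used as tie-breaker).
#' @seealso [identifyPeak()]
#' @export
setClass("IdentificationResult",
  slots = c(
    candidate = "character",
    rrt = "numeric",
    rrtReference = "numeric",
    rawSimilarity = "numeric",
    derivSimilarity = "numeric",
    rrtPass = "logical",
    spectrumPass = "logical",
    identified = "logical",
    ambiguous = "logical"
  )
)

setValidity("IdentificationResult", function(object) {
  if (!identical(object@identified, object@rrtPass && object@spectrumPass))
    "identified must equal rrtPass AND spectrumPass"
  else TRUE
})
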