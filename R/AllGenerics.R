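#' Retention-time axis of a chromatographic object
#'
#' @param object A [Chromatogram-class] or [DADRun-class].
#' @return Numeric vector of retention times in minutes.
#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))

#' Intensity values of a chromatographic object
#'
#' @param object A [Chromatogram-class].
#' @return Numeric vector of absorbances in mAU.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' Wavelength of a chromatographic object
#'
#' @param object A [Chromatogram-class], [SpectrumUV-class] or
#'   [DADRun-class].
#' @return Numeric: a scalar detection wavelength for a chromatogram, the
#'   full grid for a spectrum or DAD run.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' Absorbance values of a UV spectrum
#'
#' @param object A [SpectrumUV-class].
#' @return Numeric vector of absorbances in mAU.
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' Analyte label
#'
#' @param object A [SpectrumUV-class], [AnalyteSpec-class] or
#'   [CalibrationCurve-class].
#' @return Character scalar.
#' @export
setGeneric("analyteName", function(object) standardGeneric("analyteName"))

#' Calibration slope
#'
#' @param object A [CalibrationCurve-class] or [AnalyteSpec-class].
#' @return Numeric scalar, area (mAU.min) per (ug/mL).
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))

#' Calibration intercept
#'
#' @param object A [CalibrationCurve-class] or [AnalyteSpec-class].
#' @return Numeric scalar, area (mAU.min).
#' @export
setGeneric("calIntercept", function(object) standardGeneric("calIntercept"))

#' Ground truth of a simulated run
#'
#' @param object A [DADRun-class].
#' @return data.frame with one row per simulated compound.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

## ---- methods -------------------------------------------------------------

#' @describeIn rtime time grid of a chromatogram
#' @export
setMethod("rtime", "Chromatogram", function(object) object@rtime)

#' @describeIn rtime time grid of a DAD run
#' @export
setMethod("rtime", "DADRun", function(object) object@rtime)

#' @describeIn intensity absorbance trace of a chromatogram
#' @export
setMethod("intensity", "Chromatogram", function(object) object@intensity)

#' @describeIn wavelength detection wavelength of a chromatogram
#' @export
setMethod("wavelength", "Chromatogram", function(object) object@wavelength)

#' @describeIn wavelength wavelength grid of a spectrum
#' @export
setMethod("wavelength", "SpectrumUV", function(object) object@wavelength)

#' @describeIn wavelength wavelength grid of a DAD run
#' @export
setMethod("wavelength", "DADRun", function(object) object@wavelength)

#' @describeIn absorbance absorbances of a spectrum
#' @export
setMethod("absorbance", "SpectrumUV", function(object) object@absorbance)

#' @describeIn analyteName label of a spectrum
#' @export
setMethod("analyteName", "SpectrumUV", function(object) object@analyte)

#' @describeIn analyteName name of an analyte specification
#' @export
setMethod("analyteName", "AnalyteSpec", function(object) object@name)

#' @describeIn analyteName analyte of a calibration curve
#' @export
setMethod("analyteName", "CalibrationCurve", function(object) object@analyte)

#' @describeIn calSlope fitted slope of a calibration curve
#' @export
setMethod("calSlope", "CalibrationCurve", function(object) object@slope)

#' @describeIn calSlope nominal response slope of an analyte spec
#' @export
setMethod("calSlope", "AnalyteSpec", function(object) object@slope)

#' @describeIn calIntercept fitted intercept of a calibration curve
#' @export
setMethod("calIntercept", "CalibrationCurve", function(object) object@intercept)

#' @describeIn calIntercept nominal response intercept of an analyte spec
#' @export
setMethod("calIntercept", "AnalyteSpec", function(object) object@intercept)

#' @describeIn groundTruth ground-truth table of a simulated run
#' @export
setMethod("groundTruth", "DADRun", function(object) object@groundTruth)

## ---- show methods --------------------------------------------------------

setMethod("show", "Chromatogram", function(object) {
  n <- length(object@rtime)
  cat("Chromatogram @", ifelse(is.na(object@wavelength), "? nm",
      paste0(object@wavelength, " nm")), "\n")
  if (n) {
    cat(sprintf("  %d points, %.3f-%.3f min, max %.2f mAU\n",
                n, object@rtime[1], object@rtime[n],
                max(object@intensity)))
  } else cat("  <empty>\n")
  invisible(NULL)
})

setMethod("show", "SpectrumUV", function(object) {
  cat("SpectrumUV", ifelse(is.na(object@analyte), "",
      paste0("[", object@analyte, "]")), "\n")
  cat(sprintf("  %d points, %.0f-%.0f nm\n", length(object@wavelength),
              min(object@wavelength), max(object@wavelength)))
  invisible(NULL)
})

setMethod("show", "AnalyteSpec", function(object) {
  cat(sprintf("AnalyteSpec '%s': tR %.2f min (sigma %.3f, tau %.3f)\n",
              object@name, object@retentionTime, object@sigma, object@tau))
  cat(sprintf("  response: area = %.4f * C + %.4f @ %g nm; %d UV bands\n",
              object@slope, object@intercept, object@detectionWavelength,
              nrow(object@uvBands)))
  invisible(NULL)
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %d analytes + marker '%s', %.0f min @ %g pts/min\n",
              length(object@analytes), object@marker@name,
              object@runLength, object@samplingRate))
  cat(sprintf("  wavelengths %g-%g nm (%d), drift %g mAU/min, noise %g mAU,\n",
              min(object@wavelengthGrid), max(object@wavelengthGrid),
              length(object@wavelengthGrid), object@baselineDrift,
              object@noiseSd))
  cat(sprintf("  response RSD %g%%, seed %d\n", object@responseRsdPct,
              object@seed))
  invisible(NULL)
})

setMethod("show", "DADRun", function(object) {
  cat(sprintf("DADRun: %d x %d (time x wavelength), %d compounds\n",
              nrow(object@absorbance), ncol(object@absorbance),
              nrow(object@groundTruth)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve [%s]: Y = %.4fX %s %.4f, r = %.4f\n",
              object@analyte, object@slope,
              ifelse(object@intercept < 0, "-", "+"),
              abs(object@intercept), object@r))
  cat(sprintf("  %d levels over %g-%g ug/mL", nrow(object@levels),
              object@linearRange[1], object@linearRange[2]))
  if (!is.na(object@lod))
    cat(sprintf("; LOD %.3g, LOQ %.3g ug/mL", object@lod, object@loq))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "IdentificationResult", function(object) {
  cat(sprintf("IdentificationResult: %s (%s)\n", object@candidate,
              ifelse(object@identified, "identified", "not identified")))
  cat(sprintf("  RRT %.3f vs %.3f (%s); raw sim %.4f, 1st-deriv sim %.4f (%s)%s\n",
              object@rrt, object@rrtReference,
              ifelse(object@rrtPass, "pass", "fail"),
              object@rawSimilarity, object@derivSimilarity,
              ifelse(object@spectrumPass, "pass", "fail"),
              ifelse(object@ambiguous, " [ambiguous RRT window]", "")))
  invisible(NULL)
})

#' Plot a chromatogram
#'
#' @param x A [Chromatogram-class].
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `NULL`; called for its side effect.
#' @importFrom graphics plot
#' @export
setMethod("plot", signature(x = "Chromatogram", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@rtime, x@intensity, type = "l",
                   xlab = "Retention time (min)",
                   ylab = "Absorbance (mAU)",
                   main = ifelse(is.na(x@wavelength), "Chromatogram",
                                 sprintf("Chromatogram @ %g nm",
                                         x@wavelength)), ...)
    invisible(NULL)
  })
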