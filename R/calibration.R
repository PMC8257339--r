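## Per-analyte linear calibration: OLS on level means, Pearson r,
## and S/N-based detection/quantification limits.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area against concentration, fitted on
#' the per-level mean areas (replicate injections at a level are first
#' averaged, the conventional treatment when each level is injected in
#' triplicate). `r` is the Pearson correlation of the level means with
#' concentration. Weighted fits (`1/x`, `1/x^2`) are available but the
#' default is unweighted.
#'
#' @param concentration Numeric, ug/mL, one entry per injection.
#' @param area Numeric, peak areas in mAU.min, same length.
#' @param analyte Analyte name for the curve label.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`.
#' @return A [CalibrationCurve-class]. Slope, intercept and r are
#'   stored at full precision; the show method reports them to 4
#'   decimals.
#' @examples
#' conc <- c(5, 10, 20, 50, 75, 100)
#' fitCalibration(conc, 1.8585 * conc + 5.2914, "ondansetron")
#' @export
fitCalibration <- function(concentration, area, analyte = NA_character_,
                           weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  if (length(concentration) != length(area))
    stop("'concentration' and 'area' must have equal length")
  lv <- sort(unique(concentration))
  if (length(lv) < 5)
    stop("at least 5 distinct concentration levels are required")
  if (stats::var(concentration) == 0)
    stop("concentration levels have zero variance")
  levels <- do.call(rbind, lapply(lv, function(cc) {
    a <- area[concentration == cc]
    data.frame(concentration = cc, meanArea = mean(a),
               rsdPct = if (length(a) > 1 && mean(a) != 0)
                 100 * stats::sd(a) / mean(a) else NA_real_,
               n = length(a))
  }))
  w <- switch(weighting, none = NULL, `1/x` = 1 / levels$concentration,
              `1/x2` = 1 / levels$concentration^2)
  fit <- if (is.null(w)) stats::lm(meanArea ~ concentration, data = levels)
         else stats::lm(meanArea ~ concentration, data = levels, weights = w)
  cf <- stats::coef(fit)
  new("CalibrationCurve",
      analyte = as.character(analyte),
      slope = unname(cf[2]), intercept = unname(cf[1]),
      r = stats::cor(levels$concentration, levels$meanArea),
      levels = levels, linearRange = range(lv), weighting = weighting)
}

#' Detection and quantification limits from blank noise
#'
#' The limit of detection is the concentration whose expected Gaussian
#' peak reaches `S/N = 3`, and the limit of quantification the
#' concentration reaching `S/N = 10`, under the package's S/N
#' convention `S/N = height / (2 * blank sd)` and the Gaussian
#' height-area relation `height = area / (sigma * sqrt(2*pi))`. At
#' these trace levels the response is taken as proportional (area =
#' slope * C). If a replicate RSD at the LOQ is supplied it must not
#' exceed 10%; otherwise the LOQ is raised in proportion to the excess
#' scatter and flagged.
#'
#' @param curve A [CalibrationCurve-class].
#' @param blankNoiseSd Blank noise sd, mAU (> 0).
#' @param sigma Chromatographic peak width (sd) of the analyte,
#'   minutes.
#' @param loqRsdPct Optional measured replicate RSD% at the candidate
#'   LOQ; values above 10 raise the LOQ.
#' @return The input curve with `lod` and `loq` (ug/mL) filled in;
#'   retrieve them with `curve@lod` / `curve@loq`. When the RSD
#'   constraint was active the attribute `"loqRaised"` is `TRUE`.
#' @export
lodLoq <- function(curve, blankNoiseSd, sigma, loqRsdPct = NULL) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (blankNoiseSd <= 0)
    stop("'blankNoiseSd' must be positive")
  if (sigma <= 0)
    stop("'sigma' must be positive")
  ## height(C) = slope * C / (sigma * sqrt(2*pi));  S/N = height / (2*sd)
  concAtSnr <- function(snr)
    snr * 2 * blankNoiseSd * sigma * sqrt(2 * pi) / curve@slope
  lod <- concAtSnr(3)
  loq <- concAtSnr(10)
  raised <- FALSE
  if (!is.null(loqRsdPct) && loqRsdPct > 10) {
    loq <- loq * loqRsdPct / 10
    raised <- TRUE
  }
  out <- initialize(curve, lod = lod, loq = loq)
  attr(out, "loqRaised") <- raised
  out
}

#' Calibration report table
#'
#' Collects fitted curves into the conventional calibration summary:
#' regression equation, correlation coefficient, linear range and
#' detection/quantification limits, one row per analyte.
#'
#' @param curves List of [CalibrationCurve-class] objects.
#' @return A `data.frame` with one row per curve.
#' @export
calibrationReport <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(
      analyte = cv@analyte,
      equation = sprintf("Y = %.4fX %s %.4f", cv@slope,
                         ifelse(cv@intercept < 0, "-", "+"),
                         abs(cv@intercept)),
      slope = round(cv@slope, 4),
      intercept = round(cv@intercept, 4),
      r = round(cv@r, 4),
      rangeLow = cv@linearRange[1], rangeHigh = cv@linearRange[2],
      lod = cv@lod, loq = cv@loq,
      stringsAsFactors = FALSE
    )
  }))
}
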