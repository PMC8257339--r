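## Single-marker quantification (QAMS): relative correction factors of
## each analyte against the internal reference, concentration from the
## reference peak alone, the external-standard comparator, and the
## paired-method agreement test.

#' Relative correction factor from calibration slopes
#'
#' The relative correction factor (RCF) of analyte x against the
#' internal reference i is the ratio of response factors
#' `f_x / f_i = (A_x/C_x) / (A_i/C_i)`; with linear area-concentration
#' responses this is the ratio of the calibration slopes. This is the
#' package's canonical RCF.
#'
#' @param curveX [CalibrationCurve-class] of the analyte.
#' @param curveRef [CalibrationCurve-class] of the internal reference.
#' @param digits Decimals for the reported value (default 3, the
#'   conventional reporting precision). Use `NULL` for full precision.
#' @return The RCF as a single number.
#' @examples
#' conc <- c(5, 10, 20, 50, 75, 100)
#' azt <- fitCalibration(conc, 0.6321 * conc + 1.3833, "azasetron")
#' odt <- fitCalibration(conc, 1.8585 * conc + 5.2914, "ondansetron")
#' rcfFromSlopes(azt, odt)  # 0.340
#' @export
rcfFromSlopes <- function(curveX, curveRef, digits = 3) {
  stopifnot(is(curveX, "CalibrationCurve"), is(curveRef, "CalibrationCurve"))
  if (curveRef@slope <= 0)
    stop("reference slope must be positive")
  rcf <- curveX@slope / curveRef@slope
  if (!is.null(digits)) rcf <- round(rcf, digits)
  rcf
}

#' Relative correction factor from paired measurement levels
#'
#' The literal per-level reading of the response-factor ratio: for each
#' paired measurement of the analyte and the reference,
#' `(A_x/C_x) / (A_i/C_i)` is formed, and the mean and RSD% across
#' levels are returned. With non-zero calibration intercepts the
#' per-level values drift with concentration; the RSD quantifies that
#' proportionality bias.
#'
#' @param measurements A data.frame (or list coercible to one) with
#'   columns `Ax`, `Cx`, `Ai`, `Ci`: at least 3 paired levels, all
#'   positive.
#' @return A list with `rcf` (mean across levels) and `rsdPct`.
#' @export
rcfFromPairedLevels <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!all(c("Ax", "Cx", "Ai", "Ci") %in% names(m)))
    stop("measurements need columns Ax, Cx, Ai, Ci")
  if (nrow(m) < 3)
    stop("at least 3 paired levels are required")
  if (any(m$Cx <= 0) || any(m$Ci <= 0))
    stop("all concentrations must be positive")
  if (any(m$Ax <= 0) || any(m$Ai <= 0))
    stop("all areas must be positive")
  perLevel <- (m$Ax / m$Cx) / (m$Ai / m$Ci)
  mu <- mean(perLevel)
  list(rcf = mu,
       rsdPct = if (mu != 0) 100 * stats::sd(perLevel) / mu else NA_real_)
}

#' Build the RCF table for an analyte roster
#'
#' Computes the slope-ratio RCF of every analyte against the chosen
#' internal reference; the reference row is exactly 1 by construction.
#'
#' @param curves Named list of [CalibrationCurve-class] objects.
#' @param reference Name of the internal reference analyte (default
#'   `"ondansetron"`).
#' @param digits Reporting decimals (default 3).
#' @return A `data.frame` with columns `analyte` and `rcf`.
#' @export
rcfTable <- function(curves, reference = "ondansetron", digits = 3) {
  if (!reference %in% names(curves))
    stop("reference analyte '", reference, "' not among the curves")
  ref <- curves[[reference]]
  data.frame(
    analyte = names(curves),
    rcf = vapply(curves, function(cv)
      rcfFromSlopes(cv, ref, digits = digits), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Quantify an analyte from the single reference marker
#'
#' The single-marker concentration estimate
#' `C_x = C_i / RCF_x * A_x / A_i`: only the reference compound's peak
#' area and known concentration are needed at analysis time, the
#' analyte being tied to the reference by its pre-established relative
#' correction factor. The relation ignores calibration intercepts by
#' construction; the resulting proportionality bias is surfaced by the
#' validation reports rather than silently corrected.
#'
#' @param Ax Peak area of the analyte, mAU.min.
#' @param Ai Peak area of the internal reference (> 0).
#' @param Ci Concentration of the internal reference, ug/mL (> 0).
#' @param rcf Relative correction factor of the analyte (> 0).
#' @return Estimated concentration, ug/mL.
#' @examples
#' quantifyQAMS(Ax = 6.8, Ai = 20, Ci = 20, rcf = 0.340)
#' @export
quantifyQAMS <- function(Ax, Ai, Ci, rcf) {
  if (any(Ai <= 0)) stop("reference peak area must be positive ",
                         "(reference peak missing?)")
  if (any(Ci <= 0)) stop("reference concentration must be positive")
  if (any(rcf <= 0)) stop("rcf must be positive")
  Ci / rcf * Ax / Ai
}

#' Quantify an analyte by the external standard method
#'
#' Inverts the analyte's own calibration line:
#' `C = (A - intercept) / slope`. Areas outside the calibrated area
#' range are extrapolations and flagged; negative estimates are clamped
#' to 0 and flagged.
#'
#' @param Ax Peak area, mAU.min.
#' @param curve The analyte's [CalibrationCurve-class].
#' @return Concentration in ug/mL, with attributes `"extrapolated"`
#'   and `"clamped"` when applicable.
#' @export
quantifyESM <- function(Ax, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  C <- (Ax - curve@intercept) / curve@slope
  lo <- curve@intercept + curve@slope * curve@linearRange[1]
  hi <- curve@intercept + curve@slope * curve@linearRange[2]
  extrapolated <- Ax < lo - 1e-9 | Ax > hi + 1e-9
  clamped <- C < 0
  C[clamped] <- 0
  attr(C, "extrapolated") <- extrapolated
  attr(C, "clamped") <- clamped
  C
}

#' Compare single-marker and external-standard quantification
#'
#' Two-sided paired t-test on matched concentration estimates from the
#' two methods, with the per-method RSD%. Degenerate difference
#' vectors (all differences identical) are handled explicitly: zero
#' mean difference gives `t = 0, p = 1`; a non-zero constant offset
#' gives `p = 0`.
#'
#' @param cQams,cEsm Numeric vectors of paired concentration estimates
#'   (>= 3 pairs).
#' @return A list: `meanDiff`, `tStatistic`, `pValue`, `rsdQamsPct`,
#'   `rsdEsmPct`, `significant` (at alpha = 0.05).
#' @export
compareMethods <- function(cQams, cEsm) {
  if (length(cQams) != length(cEsm))
    stop("paired vectors must have equal length")
  if (length(cQams) < 3)
    stop("at least 3 pairs are required")
  d <- cQams - cEsm
  if (stats::sd(d) == 0) {
    tS <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(cQams, cEsm, paired = TRUE)
    tS <- unname(tt$statistic)
    p <- tt$p.value
  }
  rsd <- function(x) if (mean(x) != 0) 100 * stats::sd(x) / mean(x)
                     else NA_real_
  list(meanDiff = mean(d), tStatistic = tS, pValue = p,
       rsdQamsPct = rsd(cQams), rsdEsmPct = rsd(cEsm),
       significant = p < 0.05)
}
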