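## LC-DAD run simulator: tailed-Gaussian peaks on a linear baseline with
## additive detector noise, scaled so that each compound's integrated
## area at its detection wavelength follows its linear response line.

## Unit-area peak shape: Gaussian (tau = 0) or exponentially modified
## Gaussian. The EMG is evaluated in the numerically stable exp-scaled
## form using erfcx to avoid overflow for small tau.
.unitPeak <- function(t, mu, sigma, tau) {
  if (tau <= 0) return(stats::dnorm(t, mean = mu, sd = sigma))
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  ## three numerically safe regimes: erfcx on the leading flank,
  ## its asymptotic expansion far out on that flank (where pracma's
  ## erfcx breaks down), and the plain form on the tail, where the
  ## exponent is provably <= 0
  erfcxSafe <- function(x) {
    ifelse(x < 20, pracma::erfcx(pmin(x, 20)),
           (1 - 1 / (2 * x^2) + 3 / (4 * x^4)) / (x * sqrt(pi)))
  }
  out <- numeric(length(t))
  pos <- z >= 0
  out[pos] <- 0.5 / tau * exp(-(t[pos] - mu)^2 / (2 * sigma^2)) *
    erfcxSafe(z[pos])
  out[!pos] <- 0.5 / tau *
    exp(sigma^2 / (2 * tau^2) - (t[!pos] - mu) / tau) *
    pracma::erfc(z[!pos])
  out
}

## Evaluate an analyte's UV band profile at arbitrary wavelengths.
.bandProfile <- function(uvBands, wl) {
  out <- numeric(length(wl))
  for (b in seq_len(nrow(uvBands))) {
    out <- out + uvBands[b, "height"] *
      exp(-(wl - uvBands[b, "center"])^2 / (2 * uvBands[b, "width"]^2))
  }
  out
}

#' Simulate one LC-DAD injection
#'
#' Generates the full diode-array absorbance matrix for one injection of
#' the configured analytes at the given concentrations, plus the
#' unretained dead-time marker. Each compound contributes a (optionally
#' exponentially tailed) Gaussian peak at its retention time whose
#' integrated area at the compound's detection wavelength equals
#' `slope * C + intercept` (zero for `C = 0`); across wavelengths the
#' peak scales by the compound's UV band profile. A linear baseline
#' drift and additive i.i.d. Gaussian noise are applied on top. The
#' run is fully reproducible for a fixed config seed.
#'
#' @param config A [RunConfig-class].
#' @param concentrations Named numeric vector, ug/mL, one entry per
#'   configured analyte (names must match; all values >= 0).
#' @return A [DADRun-class] with ground truth. If any two peaks lie
#'   closer than `2 * (sigma_i + sigma_j)` the run is flagged (the
#'   downstream method assumes baseline resolution) and a warning is
#'   emitted.
#' @examples
#' cfg <- defaultRunConfig(seed = 7)
#' conc <- c(azasetron = 20, granisetron = 20, tropisetron = 20,
#'           ondansetron = 20, ramosetron = 10)
#' run <- simulateRun(cfg, conc)
#' groundTruth(run)
#' @export
simulateRun <- function(config, concentrations) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  anames <- vapply(config@analytes, analyteName, character(1))
  if (is.null(names(concentrations)) ||
      !all(anames %in% names(concentrations)))
    stop("'concentrations' must be named and cover every configured analyte")
  concentrations <- concentrations[anames]
  if (any(concentrations < 0))
    stop("negative concentrations are not allowed")

  set.seed(config@seed)
  tm <- seq(0, config@runLength, by = 1 / config@samplingRate)
  wl <- config@wavelengthGrid
  dad <- matrix(0, nrow = length(tm), ncol = length(wl))

  compounds <- c(config@analytes, list(config@marker))
  conc <- c(concentrations, config@markerConcentration)
  nC <- length(compounds)

  ## one multiplicative response factor per compound per injection
  respFac <- if (config@responseRsdPct > 0)
    1 + stats::rnorm(nC, 0, config@responseRsdPct / 100) else rep(1, nC)

  gt <- data.frame(
    analyte = vapply(compounds, analyteName, character(1)),
    concentration = as.numeric(conc),
    nominalArea = 0, simulatedArea = 0, apexTime = NA_real_,
    detectionWavelength = vapply(compounds, function(a)
      a@detectionWavelength, numeric(1)),
    stringsAsFactors = FALSE
  )

  for (k in seq_len(nC)) {
    a <- compounds[[k]]
    C <- conc[[k]]
    if (C <= 0) next
    nominal <- a@slope * C + a@intercept
    area <- nominal * respFac[k]
    shape <- .unitPeak(tm, a@retentionTime, a@sigma, a@tau)
    profile <- .bandProfile(a@uvBands, wl)
    atDet <- .bandProfile(a@uvBands, a@detectionWavelength)
    if (atDet <= 0)
      stop("analyte '", a@name,
           "' has no UV absorbance at its detection wavelength")
    dad <- dad + outer(area * shape, profile / atDet)
    gt$nominalArea[k] <- nominal
    gt$simulatedArea[k] <- area
    gt$apexTime[k] <- if (a@tau > 0) tm[which.max(shape)] else a@retentionTime
  }

  if (config@baselineDrift != 0)
    dad <- dad + config@baselineDrift * tm
  if (config@noiseSd > 0)
    dad <- dad + matrix(stats::rnorm(length(dad), 0, config@noiseSd),
                        nrow = length(tm))

  ## flag insufficient spacing between simulated peaks
  flags <- character()
  present <- which(conc > 0)
  if (length(present) >= 2) {
    for (i in utils::head(present, -1)) for (j in present[present > i]) {
      ai <- compounds[[i]]; aj <- compounds[[j]]
      if (abs(ai@retentionTime - aj@retentionTime) <
          2 * (ai@sigma + aj@sigma)) {
        flags <- c(flags, sprintf("peaks '%s' and '%s' closer than 2*(sigma_i+sigma_j)",
                                  ai@name, aj@name))
      }
    }
  }
  if (length(flags))
    warning("baseline resolution assumption violated: ",
            paste(flags, collapse = "; "))

  new("DADRun", rtime = tm, wavelength = wl, absorbance = dad,
      groundTruth = gt, config = config, flags = flags)
}

#' Extract a single-wavelength chromatogram from a DAD run
#'
#' Returns the absorbance trace at the grid wavelength nearest to the
#' requested one (the snap is recorded in the chromatogram metadata).
#' Requests outside the grid range are rejected.
#'
#' @param run A [DADRun-class].
#' @param wavelength Requested wavelength, nm.
#' @return A [Chromatogram-class].
#' @examples
#' run <- simulateRun(defaultRunConfig(seed = 1),
#'                    c(azasetron = 0, granisetron = 0, tropisetron = 0,
#'                      ondansetron = 20, ramosetron = 0))
#' chr <- extractTrace(run, 307)
#' @export
extractTrace <- function(run, wavelength) {
  stopifnot(is(run, "DADRun"))
  wl <- run@wavelength
  if (wavelength < min(wl) - 1e-9 || wavelength > max(wl) + 1e-9)
    stop("wavelength ", wavelength, " nm is outside the recorded grid (",
         min(wl), "-", max(wl), " nm)")
  j <- which.min(abs(wl - wavelength))
  Chromatogram(run@rtime, run@absorbance[, j], wavelength = wl[j],
               metadata = list(requestedWavelength = wavelength,
                               snapped = !isTRUE(all.equal(wl[j], wavelength))))
}

#' Extract the apex UV spectrum at a time point
#'
#' Takes the wavelength slice of the DAD matrix at the time nearest
#' `apexTime` and subtracts, per wavelength, a local linear baseline
#' interpolated between two flanking windows outside the peak.
#'
#' @param run A [DADRun-class].
#' @param apexTime Minutes; must lie within the run.
#' @param flank Distance from the apex to the flanking baseline
#'   windows, minutes (default 0.45, clear of a peak of sd up to
#'   ~0.11 min).
#' @param window Width of each flanking window, minutes.
#' @return A [SpectrumUV-class]. If the resulting spectrum is all near
#'   zero (no signal at `apexTime`) a warning is emitted and the
#'   attribute `"nearZero"` is set to `TRUE`.
#' @export
extractApexSpectrum <- function(run, apexTime, flank = 0.45, window = 0.08) {
  stopifnot(is(run, "DADRun"))
  tm <- run@rtime
  if (apexTime < tm[1] || apexTime > tm[length(tm)])
    stop("apexTime outside the run")
  i <- which.min(abs(tm - apexTime))
  slice <- run@absorbance[i, ]

  meanWindow <- function(lo, hi) {
    sel <- tm >= lo & tm <= hi
    if (!any(sel)) return(NULL)
    list(t = mean(tm[sel]), a = colMeans(run@absorbance[sel, , drop = FALSE]))
  }
  left <- meanWindow(apexTime - flank - window, apexTime - flank)
  right <- meanWindow(apexTime + flank, apexTime + flank + window)
  base <- if (!is.null(left) && !is.null(right)) {
    w <- (apexTime - left$t) / (right$t - left$t)
    (1 - w) * left$a + w * right$a
  } else if (!is.null(left)) left$a
  else if (!is.null(right)) right$a
  else rep(0, length(slice))

  spec <- SpectrumUV(run@wavelength, slice - base)
  nearZero <- max(abs(absorbance(spec))) <
    max(5 * run@config@noiseSd, 1e-8)
  if (nearZero)
    warning("apex spectrum at ", signif(apexTime, 4),
            " min is all near zero (no signal)")
  attr(spec, "nearZero") <- nearZero
  spec
}
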