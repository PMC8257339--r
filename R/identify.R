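## Double-indicator qualitative identification: dead-time-corrected
## relative retention time plus UV spectral cosine similarity on the
## raw and first-derivative spectra.

#' Cosine (angle) similarity of two UV spectra
#'
#' `C_ij = sum(X_ki * X_kj) / sqrt(sum(X_ki^2) * sum(X_kj^2))`: the
#' cosine of the angle between the two absorbance vectors. Values near
#' 1 indicate near-identical spectral shape (the measure is invariant
#' to overall scale), values near 0 strongly different spectra.
#' Spectra on different grids are resampled by linear interpolation to
#' a common 1 nm grid over the overlapping range, which must cover at
#' least 80% of each spectrum's range.
#'
#' @param s1,s2 [SpectrumUV-class] objects; neither may be all zero.
#' @param step Resampling step in nm when the grids differ (default 1).
#' @return A single number in \[-1, 1\]; symmetric in its arguments.
#' @examples
#' a <- SpectrumUV(1:3, c(1, 2, 3))
#' b <- SpectrumUV(1:3, c(2, 3, 4))
#' cosineSimilarity(a, b)  # 0.9926
#' @export
cosineSimilarity <- function(s1, s2, step = 1) {
  stopifnot(is(s1, "SpectrumUV"), is(s2, "SpectrumUV"))
  w1 <- s1@wavelength; w2 <- s2@wavelength
  if (isTRUE(all.equal(w1, w2))) {
    x <- s1@absorbance; y <- s2@absorbance
  } else {
    lo <- max(min(w1), min(w2))
    hi <- min(max(w1), max(w2))
    r1 <- diff(range(w1)); r2 <- diff(range(w2))
    if (hi <= lo || (hi - lo) < 0.8 * min(r1, r2) ||
        (hi - lo) < 0.8 * max(r1, r2))
      stop("spectral ranges overlap by less than 80%")
    grid <- seq(lo, hi, by = step)
    x <- stats::approx(w1, s1@absorbance, xout = grid)$y
    y <- stats::approx(w2, s2@absorbance, xout = grid)$y
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine similarity is undefined for an all-zero spectrum")
  max(-1, min(1, sum(x * y) / (nx * ny)))
}

#' First-derivative UV spectrum
#'
#' dA/d(lambda) by Savitzky-Golay differentiation (window 7, order 2)
#' on the spectrum's uniform grid; spectra shorter than the window fall
#' back to central differences with one-sided differences at the
#' endpoints (flagged via the `"fallback"` attribute). Derivative
#' spectra magnify shape differences between otherwise similar
#' absorption spectra, which is why the derivative similarity is the
#' sharper of the two identification indicators.
#'
#' @param s A [SpectrumUV-class] on a uniform wavelength grid.
#' @param windowPoints Savitzky-Golay window (default 7).
#' @param polyOrder Savitzky-Golay order (default 2).
#' @return A [SpectrumUV-class] holding dA/d(lambda) on the same grid.
#' @export
firstDerivative <- function(s, windowPoints = 7, polyOrder = 2) {
  stopifnot(is(s, "SpectrumUV"))
  dw <- diff(s@wavelength)
  if (length(dw) < 1) stop("spectrum too short to differentiate")
  if ((max(dw) - min(dw)) > 1e-6)
    stop("first derivative requires a uniform wavelength grid")
  n <- length(s@wavelength)
  fallback <- n < windowPoints
  d <- if (!fallback) {
    signal::sgolayfilt(s@absorbance, p = polyOrder, n = windowPoints,
                       m = 1, ts = dw[1])
  } else {
    a <- s@absorbance
    c((a[2] - a[1]) / dw[1],
      if (n > 2) (a[3:n] - a[1:(n - 2)]) / (2 * dw[1]) else NULL,
      (a[n] - a[n - 1]) / dw[1])
  }
  out <- SpectrumUV(s@wavelength, d, analyte = s@analyte)
  attr(out, "fallback") <- fallback
  out
}

#' Dead-time-corrected relative retention time
#'
#' `RRT = (t_x - t_0) / (t_i - t_0)` with `t_0` the dead time (elution
#' of the unretained marker), `t_i` the internal reference's retention
#' time and `t_x` the analyte's. Correcting for the dead volume makes
#' the ratio invariant under affine changes of the time axis (flow or
#' instrument differences), which is what makes it usable for
#' identification across instruments.
#'
#' @param tx Analyte retention time, minutes (>= `t0`).
#' @param ti Internal-reference retention time, minutes (> `t0`).
#' @param t0 Dead time, minutes.
#' @return The dimensionless RRT (full precision; report to 3
#'   decimals).
#' @examples
#' relativeRetentionTime(4.562, 9.0, 1.2)  # 0.431
#' @export
relativeRetentionTime <- function(tx, ti, t0) {
  if (ti <= t0)
    stop("reference retention time must exceed the dead time")
  if (any(tx < t0))
    stop("analyte retention time cannot precede the dead time")
  (tx - t0) / (ti - t0)
}

#' Build a reference identification library from a configuration
#'
#' Simulates one noiseless run of every configured analyte, extracts
#' each apex UV spectrum and computes the reference relative retention
#' times against the configured dead-time marker and internal
#' reference.
#'
#' @param config A [RunConfig-class] (noise settings are ignored; the
#'   library run is generated noiseless).
#' @param reference Internal reference analyte name (default
#'   `"ondansetron"`).
#' @param concentration ug/mL used for the library injection.
#' @return A list with one entry per analyte, each holding `analyte`,
#'   `rrt` and `spectrum` ([SpectrumUV-class]), plus attributes `t0`
#'   and `ti`.
#' @export
buildReferenceLibrary <- function(config, reference = "ondansetron",
                                  concentration = 20) {
  stopifnot(is(config, "RunConfig"))
  anames <- vapply(config@analytes, analyteName, character(1))
  if (!reference %in% anames)
    stop("reference analyte '", reference, "' is not configured")
  clean <- initialize(config, noiseSd = 0, baselineDrift = 0,
                      responseRsdPct = 0)
  conc <- stats::setNames(rep(concentration, length(anames)), anames)
  run <- simulateRun(clean, conc)
  gt <- groundTruth(run)
  t0 <- gt$apexTime[gt$analyte == "marker"]
  ti <- gt$apexTime[gt$analyte == reference]
  lib <- lapply(anames, function(a) {
    tx <- gt$apexTime[gt$analyte == a]
    sp <- extractApexSpectrum(run, tx)
    sp@analyte <- a
    list(analyte = a, rrt = relativeRetentionTime(tx, ti, t0),
         spectrum = sp)
  })
  names(lib) <- anames
  attr(lib, "t0") <- t0
  attr(lib, "ti") <- ti
  attr(lib, "reference") <- reference
  lib
}

#' Identify a peak by the RRT / UV-similarity double indicator
#'
#' Computes the peak's dead-time-corrected relative retention time and
#' matches it against a reference library; for the best-matching
#' candidate the raw and first-derivative spectral cosine similarities
#' are computed. The RRT indicator passes when the relative deviation
#' from the library RRT is within `rrtTolPct`; the spectral indicator
#' passes when both similarities reach their thresholds; the peak is
#' identified only when both indicators pass. If several candidates
#' fall inside the RRT window the match is flagged ambiguous and the
#' derivative similarity is used as the tie-breaker.
#'
#' @param peak One row of a [detectPeaks()] table.
#' @param apexSpectrum [SpectrumUV-class] at the peak apex.
#' @param library A library from [buildReferenceLibrary()] (or a list
#'   of `list(analyte, rrt, spectrum)` entries).
#' @param ti Internal-reference retention time in this run, minutes.
#' @param t0 Dead time in this run, minutes.
#' @param rrtTolPct RRT tolerance, percent (default 5, chosen to cover
#'   the worst observed cross-instrument RRT variability with margin).
#' @param rawSimMin Minimum raw spectral similarity (default 0.99).
#' @param derivSimMin Minimum first-derivative similarity (default
#'   0.90). The defaults sit between typical self- and
#'   cross-similarities of the assay's analytes.
#' @return An [IdentificationResult-class].
#' @export
identifyPeak <- function(peak, apexSpectrum, library, ti, t0,
                         rrtTolPct = 5, rawSimMin = 0.99,
                         derivSimMin = 0.90) {
  if (!length(library)) stop("identification library is empty")
  if (rrtTolPct <= 0 || rawSimMin > 1 || derivSimMin > 1)
    stop("thresholds out of range")
  rrt <- relativeRetentionTime(peak$apexTime, ti, t0)
  refRrt <- vapply(library, function(e) e$rrt, numeric(1))
  relDev <- abs(rrt - refRrt) / refRrt
  inWindow <- which(relDev <= rrtTolPct / 100)
  ambiguous <- length(inWindow) > 1

  simPair <- function(entry) {
    raw <- cosineSimilarity(apexSpectrum, entry$spectrum)
    deriv <- cosineSimilarity(firstDerivative(apexSpectrum),
                              firstDerivative(entry$spectrum))
    c(raw = raw, deriv = deriv)
  }

  if (ambiguous) {
    ## spectrum as tie-breaker among RRT-compatible candidates
    sims <- vapply(library[inWindow], simPair, numeric(2))
    best <- inWindow[which.max(sims["deriv", ])]
    sim <- sims[, which.max(sims["deriv", ])]
  } else {
    best <- if (length(inWindow) == 1) inWindow else which.min(relDev)
    sim <- simPair(library[[best]])
  }
  entry <- library[[best]]
  rrtPass <- relDev[best] <= rrtTolPct / 100
  spectrumPass <- sim[["raw"]] >= rawSimMin && sim[["deriv"]] >= derivSimMin
  new("IdentificationResult",
      candidate = entry$analyte, rrt = rrt, rrtReference = entry$rrt,
      rawSimilarity = sim[["raw"]], derivSimilarity = sim[["deriv"]],
      rrtPass = rrtPass, spectrumPass = spectrumPass,
      identified = rrtPass && spectrumPass, ambiguous = ambiguous)
}

#' Pairwise spectral similarity matrices for a library
#'
#' Raw and first-derivative cosine-similarity matrices across a
#' reference library, mirroring the conventional presentation with a
#' unit diagonal.
#'
#' @param library A library from [buildReferenceLibrary()].
#' @return A list of two symmetric matrices, `raw` and `deriv`.
#' @export
similarityMatrix <- function(library) {
  n <- length(library)
  nm <- vapply(library, function(e) e$analyte, character(1))
  raw <- deriv <- matrix(1, n, n, dimnames = list(nm, nm))
  dspec <- lapply(library, function(e) firstDerivative(e$spectrum))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      raw[i, j] <- raw[j, i] <-
        cosineSimilarity(library[[i]]$spectrum, library[[j]]$spectrum)
      deriv[i, j] <- deriv[j, i] <- cosineSimilarity(dspec[[i]], dspec[[j]])
    }
  }
  list(raw = raw, deriv = deriv)
}
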