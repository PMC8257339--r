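## Peak processing on single-wavelength chromatograms: Savitzky-Golay
## smoothing, iterative-clipping baseline estimation, apex detection
## with valley/baseline-return bounding and trapezoidal integration,
## pharmacopoeial S/N and half-height resolution.

.checkUniform <- function(chrom, what = "this operation") {
  dt <- diff(chrom@rtime)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6)
    stop(what, " requires a uniform time grid (tolerance 1e-6 min)")
  invisible(dt[1])
}

#' Savitzky-Golay smoothing of a chromatogram
#'
#' Polynomial-filter smoothing on the chromatogram's own grid.
#' Endpoints are handled by the filter's built-in polynomial endpoint
#' fits, so traces that are exactly polynomial up to `polyOrder` are
#' reproduced unchanged.
#'
#' @param chrom A [Chromatogram-class] on a uniform time grid.
#' @param windowPoints Odd window length in points (default 7); must
#'   exceed `polyOrder` and be shorter than the trace.
#' @param polyOrder Polynomial order (default 2).
#' @return A smoothed [Chromatogram-class] on the same grid.
#' @export
smoothChromatogram <- function(chrom, windowPoints = 7, polyOrder = 2) {
  stopifnot(is(chrom, "Chromatogram"))
  if (windowPoints %% 2 == 0)
    stop("'windowPoints' must be odd")
  if (windowPoints <= polyOrder)
    stop("'windowPoints' must exceed 'polyOrder'")
  if (windowPoints >= length(chrom@rtime))
    stop("'windowPoints' must be shorter than the trace")
  .checkUniform(chrom, "smoothing")
  sm <- signal::sgolayfilt(chrom@intensity, p = polyOrder, n = windowPoints)
  initialize(chrom, intensity = sm,
             metadata = c(chrom@metadata,
                          list(smoothed = c(window = windowPoints,
                                            order = polyOrder))))
}

#' Estimate the chromatographic baseline
#'
#' Iterative polynomial fitting with asymmetric clipping: a polynomial
#' (default a line, adequate for linear drift) is fitted to all points,
#' points far above the fit are discarded, and the fit is repeated
#' until the retained set stabilises. Peak points are progressively
#' excluded so the fit converges onto the peak-free baseline.
#'
#' @param chrom A [Chromatogram-class].
#' @param degree Polynomial degree of the baseline model (default 1).
#' @param maxIter Maximum clipping iterations.
#' @return A [Chromatogram-class] holding the baseline on the same
#'   grid; its metadata carries `baselinePoints` (logical mask of
#'   points treated as baseline) and `noiseSd` (sd of the residuals on
#'   those points). If fewer than 20% of points survive clipping a
#'   flat baseline at the global minimum is returned with a warning.
#' @export
estimateBaseline <- function(chrom, degree = 1, maxIter = 100) {
  stopifnot(is(chrom, "Chromatogram"))
  tm <- chrom@rtime
  y <- chrom@intensity
  n <- length(y)
  ts <- (tm - mean(tm)) / (diff(range(tm)) / 2 + .Machine$double.eps)
  X <- outer(ts, 0:degree, `^`)
  keep <- rep(TRUE, n)
  for (it in seq_len(maxIter)) {
    cf <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
    cf[is.na(cf)] <- 0
    b <- drop(X %*% cf)
    r <- y - b
    rn <- r[keep & r <= 0]
    sigma <- if (length(rn)) sqrt(mean(rn^2)) else 0
    newKeep <- r <= 3 * sigma + 1e-12
    if (identical(newKeep, keep)) break
    keep <- newKeep
    if (sum(keep) < max(degree + 1, 5)) break
  }
  if (mean(keep) < 0.2) {
    warning("fewer than 20% baseline points; returning a flat baseline ",
            "at the global minimum")
    b <- rep(min(y), n)
    keep <- y <= min(y) + 1e-12
    sigma <- 0
  } else {
    sigma <- stats::sd(y[keep] - b[keep])
    if (is.na(sigma)) sigma <- 0
  }
  Chromatogram(tm, b, wavelength = chrom@wavelength,
               metadata = list(baselinePoints = keep, noiseSd = sigma))
}

#' Baseline-correct a chromatogram
#'
#' Convenience wrapper subtracting [estimateBaseline()] from the trace.
#'
#' @inheritParams estimateBaseline
#' @return A baseline-corrected [Chromatogram-class]; metadata carries
#'   the baseline's `baselinePoints` and `noiseSd`.
#' @export
baselineCorrect <- function(chrom, degree = 1) {
  bl <- estimateBaseline(chrom, degree = degree)
  initialize(chrom, intensity = chrom@intensity - bl@intensity,
             metadata = c(chrom@metadata, bl@metadata))
}

#' Detect and integrate chromatographic peaks
#'
#' Estimates and subtracts the baseline, smooths the residual signal,
#' and reports every local maximum whose height exceeds
#' `minSnr * N` where `N = 2 * sd` of the baseline noise (the S/N
#' denominator used throughout the package). Peak boundaries are placed
#' at the first valley or at return to baseline (signal below 1% of the
#' peak height), whichever comes first; areas are trapezoidal over the
#' baseline-corrected signal between the boundaries. Apex times are
#' refined by parabolic interpolation through the three samples around
#' the maximum.
#'
#' @param chrom A [Chromatogram-class] on a uniform grid.
#' @param minSnr Minimum signal-to-noise ratio (height / (2 * noise
#'   sd)) for a peak to be reported (default 10).
#' @param minWidth Minimum peak base width, minutes (default 0.02).
#' @param smoothWindow Savitzky-Golay window in points used for apex
#'   finding (default 7; 0 disables smoothing).
#' @param polyOrder Savitzky-Golay order (default 2).
#' @return A `data.frame` with columns `label`, `apexTime`,
#'   `startTime`, `endTime`, `height`, `area`, `snr`, sorted by apex
#'   time; zero rows when no peak qualifies.
#' @examples
#' run <- simulateRun(defaultRunConfig(seed = 1),
#'                    c(azasetron = 20, granisetron = 20, tropisetron = 20,
#'                      ondansetron = 20, ramosetron = 10))
#' detectPeaks(extractTrace(run, 307))
#' @export
detectPeaks <- function(chrom, minSnr = 10, minWidth = 0.02,
                        smoothWindow = 7, polyOrder = 2) {
  stopifnot(is(chrom, "Chromatogram"))
  .checkUniform(chrom, "peak detection")
  tm <- chrom@rtime
  n <- length(tm)
  bl <- estimateBaseline(chrom)
  y <- chrom@intensity - bl@intensity
  noiseSd <- bl@metadata$noiseSd
  N <- 2 * noiseSd
  ys <- if (smoothWindow > 0 && smoothWindow < n && smoothWindow > polyOrder)
    signal::sgolayfilt(y, p = polyOrder, n = smoothWindow) else y

  thr <- max(minSnr * N, 1e-3 * max(ys), 1e-9)
  apexes <- which(ys > thr)
  apexes <- apexes[apexes > 1 & apexes < n]
  apexes <- apexes[ys[apexes] >= ys[apexes - 1] & ys[apexes] > ys[apexes + 1]]
  if (!length(apexes)) {
    return(data.frame(label = character(), apexTime = numeric(),
                      startTime = numeric(), endTime = numeric(),
                      height = numeric(), area = numeric(),
                      snr = numeric(), stringsAsFactors = FALSE))
  }

  ## descend from the apex to the first genuine valley (running minimum
  ## exceeded by more than a noise-sized tolerance) or to baseline
  ## return (signal below 1% of the peak height), whichever comes first
  tol <- max(N, 1e-12)
  bound <- function(apex, h) {
    walk <- function(step, limit) {
      k <- apex; minv <- ys[apex]; kmin <- apex
      while (k != limit && ys[k] >= 0.01 * h) {
        k <- k + step
        if (ys[k] < minv) { minv <- ys[k]; kmin <- k }
        if (ys[k] > minv + tol) return(kmin)
      }
      k
    }
    c(walk(-1L, 1L), walk(1L, n))
  }

  ## strongest first; suppress secondary maxima inside an already
  ## claimed peak region (noise ripples on a flank)
  ord <- apexes[order(ys[apexes], decreasing = TRUE)]
  claimed <- rep(FALSE, n)
  rows <- list()
  for (apex in ord) {
    if (claimed[apex]) next
    h <- ys[apex]
    be <- bound(apex, h)
    claimed[be[1]:be[2]] <- TRUE
    ## parabolic apex refinement
    y3 <- ys[(apex - 1):(apex + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    shift <- if (denom < 0) 0.5 * (y3[1] - y3[3]) / denom else 0
    shift <- max(-0.5, min(0.5, shift))
    dt <- tm[2] - tm[1]
    rows[[length(rows) + 1]] <- data.frame(
      label = NA_character_,
      apexTime = tm[apex] + shift * dt,
      startTime = tm[be[1]], endTime = tm[be[2]],
      height = h,
      area = pracma::trapz(tm[be[1]:be[2]], y[be[1]:be[2]]),
      snr = if (N > 0) h / N else Inf,
      stringsAsFactors = FALSE
    )
  }
  pk <- do.call(rbind, rows)
  pk <- pk[pk$endTime - pk$startTime >= minWidth &
           pk$height > 0 & pk$area > 0, , drop = FALSE]
  pk <- pk[order(pk$apexTime), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Signal-to-noise ratio of a detected peak
#'
#' `S/N = height / (2 * sd)` of the baseline-corrected signal inside a
#' peak-free blank window — the pharmacopoeial convention under which
#' the detection limit sits at S/N = 3 and the quantification limit at
#' S/N = 10.
#'
#' @param peak One row of a [detectPeaks()] table (or any list with
#'   `height`, `startTime`, `endTime`).
#' @param chrom The [Chromatogram-class] the peak was detected on.
#' @param blankWindow Numeric `c(from, to)` minutes; must not overlap
#'   the peak.
#' @return A single number; `Inf` for a noiseless blank.
#' @export
signalToNoise <- function(peak, chrom, blankWindow) {
  stopifnot(is(chrom, "Chromatogram"), length(blankWindow) == 2)
  blankWindow <- sort(as.numeric(blankWindow))
  if (blankWindow[1] < peak$endTime && blankWindow[2] > peak$startTime)
    stop("blank window overlaps the peak (",
         signif(peak$startTime, 4), "-", signif(peak$endTime, 4), " min)")
  bl <- estimateBaseline(chrom)
  y <- chrom@intensity - bl@intensity
  sel <- chrom@rtime >= blankWindow[1] & chrom@rtime <= blankWindow[2]
  if (sum(sel) < 3)
    stop("blank window contains fewer than 3 points")
  s <- stats::sd(y[sel])
  ## residuals at numerical-precision level mean a noiseless blank
  if (s <= 1e-9 * max(abs(chrom@intensity), 1)) return(Inf)
  peak$height / (2 * s)
}

.halfWidth <- function(tm, y, apexIdx, peakLabel = "peak") {
  h <- y[apexIdx]
  half <- h / 2
  ## left crossing
  l <- apexIdx
  while (l > 1 && y[l] > half) l <- l - 1
  if (y[l] > half)
    stop("cannot resolve half-height width for ", peakLabel,
         " (left flank never reaches half height)")
  tl <- tm[l] + (tm[l + 1] - tm[l]) * (half - y[l]) / (y[l + 1] - y[l])
  r <- apexIdx
  n <- length(y)
  while (r < n && y[r] > half) r <- r + 1
  if (y[r] > half)
    stop("cannot resolve half-height width for ", peakLabel,
         " (right flank never reaches half height)")
  tr <- tm[r - 1] + (tm[r] - tm[r - 1]) * (y[r - 1] - half) / (y[r - 1] - y[r])
  tr - tl
}

#' Chromatographic resolution between two peaks
#'
#' European Pharmacopoeia half-height convention:
#' `Rs = 1.18 * (t2 - t1) / (w1 + w2)` with `w` the full width at half
#' height of each peak, measured on the baseline-corrected trace. For
#' a Gaussian peak `w = 2.355 * sigma`, and `Rs > 1.5` indicates
#' baseline separation.
#'
#' @param peak1,peak2 Rows of a [detectPeaks()] table with
#'   `peak1$apexTime <= peak2$apexTime`.
#' @param chrom The [Chromatogram-class] both peaks were detected on.
#' @return A single non-negative number (0 when the apexes coincide).
#' @export
peakResolution <- function(peak1, peak2, chrom) {
  stopifnot(is(chrom, "Chromatogram"))
  if (peak1$apexTime > peak2$apexTime)
    stop("peak1 must elute before peak2")
  if (peak1$apexTime == peak2$apexTime) return(0)
  bl <- estimateBaseline(chrom)
  y <- chrom@intensity - bl@intensity
  tm <- chrom@rtime
  i1 <- which.min(abs(tm - peak1$apexTime))
  i2 <- which.min(abs(tm - peak2$apexTime))
  w1 <- .halfWidth(tm, y, i1, sprintf("peak at %.3f min", peak1$apexTime))
  w2 <- .halfWidth(tm, y, i2, sprintf("peak at %.3f min", peak2$apexTime))
  1.18 * (peak2$apexTime - peak1$apexTime) / (w1 + w2)
}
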