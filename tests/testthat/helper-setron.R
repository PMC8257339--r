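## Shared fixtures. The published regression lines of the assay are
## frozen here independently of the package's built-in roster so tests
## compare against constants, not against the code under test.

table1 <- data.frame(
  analyte   = c("azasetron", "granisetron", "tropisetron",
                "ondansetron", "ramosetron"),
  slope     = c(0.6321, 0.6957, 1.0634, 1.8585, 2.3167),
  intercept = c(1.3833, 0.5444, 4.8592, 5.2914, 8.6551),
  stringsAsFactors = FALSE
)

stdLevels <- c(5, 10, 20, 50, 75, 100)

concStd <- c(azasetron = 20, granisetron = 20, tropisetron = 20,
             ondansetron = 20, ramosetron = 10)

## curves fitted on noiseless points generated from the frozen lines
table1Curves <- function() {
  curves <- lapply(seq_len(nrow(table1)), function(i) {
    fitCalibration(stdLevels,
                   table1$slope[i] * stdLevels + table1$intercept[i],
                   analyte = table1$analyte[i])
  })
  names(curves) <- table1$analyte
  curves
}

## reduced wavelength grid covering the detection wavelengths only;
## much faster than the full 220-400 nm DAD grid for campaigns that do
## not need apex spectra
fastConfig <- function(seed, ...) {
  defaultRunConfig(seed = seed, wavelengthGrid = c(260, 285, 302, 307),
                   ...)
}

## proportional-response variant (intercepts zeroed): isolates the
## single-marker algebra from the proportionality bias
zeroInterceptConfig <- function(seed, ...) {
  cfg <- fastConfig(seed, ...)
  cfg@analytes <- lapply(cfg@analytes, function(a)
    initialize(a, intercept = 0))
  names(cfg@analytes) <- vapply(cfg@analytes, analyteName, character(1))
  cfg
}

## unit-area Gaussian chromatogram fixture
gaussChrom <- function(mu = 5, sigma = 0.1, area = 20, n = 1200,
                       tmax = 10, noiseSd = 0, offset = 0, drift = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- seq(0, tmax, length.out = n)
  y <- area * stats::dnorm(tm, mu, sigma) + offset + drift * tm
  if (noiseSd > 0) y <- y + stats::rnorm(n, 0, noiseSd)
  Chromatogram(tm, y, wavelength = 307)
}
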