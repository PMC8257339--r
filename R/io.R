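## CSV dialects: per-wavelength traces (`time,absorbance`), long-form
## DAD matrices (`time,wavelength,absorbance`), peak tables, spectral
## libraries and ground-truth sidecars. All files carry a header row
## and full-precision floats.

#' Write a chromatogram trace CSV
#'
#' Two columns, `time` (minutes) and `absorbance` (mAU), header row
#' mandatory, full precision.
#'
#' @param chrom A [Chromatogram-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTraceCSV <- function(chrom, path) {
  stopifnot(is(chrom, "Chromatogram"))
  utils::write.csv(data.frame(time = chrom@rtime,
                              absorbance = chrom@intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatogram trace CSV
#'
#' Expects columns `time` and `absorbance`; the time axis must be
#' strictly increasing (the offending row is named otherwise).
#'
#' @param path Input file path.
#' @param wavelength Optional detection wavelength to attach, nm.
#' @return A [Chromatogram-class].
#' @export
readTraceCSV <- function(path, wavelength = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("time", "absorbance") %in% names(df)))
    stop("trace CSV must have columns 'time' and 'absorbance': ", path)
  bad <- which(diff(df$time) <= 0)
  if (length(bad))
    stop("non-monotone time axis at row ", bad[1] + 1, " of ", path)
  suppressWarnings(
    Chromatogram(df$time, df$absorbance, wavelength = wavelength,
                 metadata = list(source = path)))
}

#' Write a DAD run in long form
#'
#' Columns `time,wavelength,absorbance`, one row per matrix cell.
#'
#' @param run A [DADRun-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeRunLongCSV <- function(run, path) {
  stopifnot(is(run, "DADRun"))
  df <- data.frame(
    time = rep(run@rtime, times = length(run@wavelength)),
    wavelength = rep(run@wavelength, each = length(run@rtime)),
    absorbance = as.vector(run@absorbance))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-form DAD matrix
#'
#' @param path CSV with columns `time,wavelength,absorbance`.
#' @param config A [RunConfig-class] to attach (required by
#'   spectrum-extraction helpers); ground truth is left empty.
#' @return A [DADRun-class].
#' @export
readRunLongCSV <- function(path, config) {
  df <- utils::read.csv(path)
  if (!all(c("time", "wavelength", "absorbance") %in% names(df)))
    stop("long-form run CSV needs columns time, wavelength, absorbance")
  tm <- sort(unique(df$time))
  wl <- sort(unique(df$wavelength))
  mat <- matrix(NA_real_, length(tm), length(wl))
  mat[cbind(match(df$time, tm), match(df$wavelength, wl))] <- df$absorbance
  if (anyNA(mat))
    stop("long-form run CSV is not a complete time x wavelength grid")
  new("DADRun", rtime = tm, wavelength = wl, absorbance = mat,
      groundTruth = data.frame(), config = config, flags = character())
}

#' Write a detected peak table
#'
#' Columns `label,apex_time,start,end,height,area,snr`.
#'
#' @param peaks A [detectPeaks()] data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePeakTableCSV <- function(peaks, path) {
  df <- data.frame(label = peaks$label, apex_time = peaks$apexTime,
                   start = peaks$startTime, end = peaks$endTime,
                   height = peaks$height, area = peaks$area,
                   snr = peaks$snr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all standard outputs of a simulated run
#'
#' Writes one trace CSV per analyte (at its detection wavelength), a
#' composite max-absorbance trace (the DAD "max-plot", on which every
#' compound including the dead-time marker is visible), the full
#' long-form matrix, and a ground-truth sidecar CSV.
#'
#' @param run A [DADRun-class].
#' @param dir Output directory (created if needed).
#' @param long Write the (large) long-form matrix too (default TRUE).
#' @return Character vector of the files written, invisibly.
#' @export
writeRunCSV <- function(run, dir, long = TRUE) {
  stopifnot(is(run, "DADRun"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (a in run@config@analytes) {
    f <- file.path(dir, paste0("trace_", a@name, ".csv"))
    writeTraceCSV(extractTrace(run, a@detectionWavelength), f)
    files <- c(files, f)
  }
  comp <- suppressWarnings(
    Chromatogram(run@rtime, apply(run@absorbance, 1, max),
                 metadata = list(kind = "max-plot")))
  f <- file.path(dir, "trace_composite.csv")
  writeTraceCSV(comp, f)
  files <- c(files, f)
  if (long) {
    f <- file.path(dir, "dad_long.csv")
    writeRunLongCSV(run, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "ground_truth.csv")
  utils::write.csv(run@groundTruth, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  invisible(files)
}

#' Write a spectral library to disk
#'
#' One `wavelength,absorbance` CSV per analyte plus an index CSV with
#' the reference RRTs and file names.
#'
#' @param library A library from [buildReferenceLibrary()].
#' @param dir Output directory.
#' @return The index file path, invisibly.
#' @export
writeSpectralLibraryCSV <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(analyte = character(), rrt = numeric(),
                    file = character())
  for (e in library) {
    f <- paste0("spectrum_", e$analyte, ".csv")
    utils::write.csv(data.frame(wavelength = wavelength(e$spectrum),
                                absorbance = absorbance(e$spectrum)),
                     file.path(dir, f), row.names = FALSE, quote = FALSE)
    idx <- rbind(idx, data.frame(analyte = e$analyte, rrt = e$rrt,
                                 file = f))
  }
  idxPath <- file.path(dir, "library_index.csv")
  utils::write.csv(idx, idxPath, row.names = FALSE, quote = FALSE)
  invisible(idxPath)
}

#' Read a spectral library written by [writeSpectralLibraryCSV()]
#'
#' @param dir Directory holding `library_index.csv` and the per-analyte
#'   spectrum CSVs.
#' @return A library list compatible with [identifyPeak()].
#' @export
readSpectralLibraryCSV <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "library_index.csv"))
  lib <- lapply(seq_len(nrow(idx)), function(i) {
    sp <- utils::read.csv(file.path(dir, idx$file[i]))
    list(analyte = idx$analyte[i], rrt = idx$rrt[i],
         spectrum = SpectrumUV(sp$wavelength, sp$absorbance,
                               analyte = idx$analyte[i]))
  })
  names(lib) <- idx$analyte
  lib
}
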