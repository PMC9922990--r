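#' Convert a power spectrum to transmittance against a reference
#'
#' Transmittance is the elementwise ratio of sample power to the background
#' (reference) power recorded with no leaf in the beam. Instruments sometimes
#' report sample power above the reference at individual frequencies; such
#' points are clipped to 1 with a warning so absorbance stays non-negative,
#' rather than rejecting the spectrum.
#'
#' @param sample_power numeric vector (or samples x frequencies matrix) of
#'   detected power, >= 0.
#' @param reference_power numeric vector of background power on the same
#'   grid, strictly positive.
#' @return Transmittance of the same shape as \code{sample_power}, in (0, 1].
#' @export
powerToTransmittance <- function(sample_power, reference_power) {
  if (is.matrix(sample_power)) {
    if (ncol(sample_power) != length(reference_power))
      stop("sample and reference are on different grids")
  } else if (length(sample_power) != length(reference_power)) {
    stop("sample and reference are on different grids")
  }
  if (any(!is.finite(reference_power)) || any(reference_power <= 0))
    stop("reference power must be strictly positive everywhere")
  if (any(!is.finite(sample_power)) || any(sample_power < 0))
    stop("sample power must be finite and non-negative")
  tr <- if (is.matrix(sample_power)) {
    sweep(sample_power, 2L, reference_power, "/")
  } else sample_power / reference_power
  n_over <- sum(tr > 1)
  if (n_over > 0L) {
    warning(sprintf(
      "%d transmittance value(s) exceeded 1 (sample power above reference); clipped to 1",
      n_over))
    tr[tr > 1] <- 1
  }
  # zero sample power would give T = 0, outside (0, 1]; floor at the
  # smallest representable positive ratio
  tr[tr == 0] <- .Machine$double.xmin
  tr
}

#' Convert between transmittance and absorbance
#'
#' Absorbance is defined as \eqn{A = -\log_{10} T}; the two functions are
#' exact inverses to machine precision.
#'
#' @param T transmittance values in (0, 1].
#' @param A absorbance values >= 0.
#' @return Absorbance (resp. transmittance) of the same shape.
#' @examples
#' transmittanceToAbsorbance(c(1, 0.1, 0.01))  # 0 1 2
#' @export
transmittanceToAbsorbance <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("transmittance must be finite and strictly positive")
  if (any(T > 1 + 1e-12))
    stop("transmittance must not exceed 1")
  -log10(T)
}

#' @rdname transmittanceToAbsorbance
#' @export
absorbanceToTransmittance <- function(A) {
  if (any(!is.finite(A)) || any(A < 0))
    stop("absorbance must be finite and non-negative")
  10^(-A)
}

.parseFreqHeaders <- function(nms) {
  f <- suppressWarnings(as.numeric(sub("^f_", "", nms)))
  if (any(is.na(f)))
    stop("column header(s) not parseable as THz frequencies: ",
         paste(nms[is.na(f)], collapse = ", "))
  f
}

#' Read / write a single-channel spectra table
#'
#' Wide CSV layout: first column \code{sample_id}, remaining columns one per
#' frequency with headers \code{f_<THz to 4 decimals>}. Frequencies must be
#' strictly increasing and uniformly spaced; the round trip
#' \code{readSpectra(writeSpectra(...))} is lossless to 12 significant
#' digits.
#'
#' @param path CSV file path.
#' @param dimension optical channel the file holds: \code{"power"},
#'   \code{"absorbance"} or \code{"transmittance"}.
#' @return \code{readSpectra}: a list with \code{dimension}, \code{grid}
#'   ([FrequencyGrid-class]), \code{values} (samples x frequencies matrix
#'   with sample ids as rownames) and \code{sample_ids}.
#' @export
readSpectra <- function(path, dimension = c("power", "absorbance",
                                            "transmittance")) {
  dimension <- match.arg(dimension)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("spectra file needs sample_id plus >= 2 frequencies")
  ids <- as.character(df[[1L]])
  f <- .parseFreqHeaders(colnames(df)[-1L])
  d <- diff(f)
  if (any(d <= 0)) {
    bad <- colnames(df)[-1L][which(d <= 0)[1L] + 1L]
    stop("frequency columns not strictly increasing at column '", bad, "'")
  }
  if (max(abs(d - d[1L])) > 1e-4) {
    bad <- colnames(df)[-1L][which.max(abs(d - d[1L])) + 1L]
    stop("frequency columns not uniformly spaced at column '", bad, "'")
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d (sample '%s'), column '%s'",
                 idx[1L], ids[idx[1L]], colnames(vals)[idx[2L]]))
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  step <- mean(d)
  grid <- new("FrequencyGrid", start = f[1L], stop = f[length(f)],
              step = step, points = f[1L] + step * (seq_along(f) - 1L))
  colnames(vals) <- sprintf("f_%.4f", freqPoints(grid))
  list(dimension = dimension, grid = grid, values = vals, sample_ids = ids)
}

#' @rdname readSpectra
#' @param values samples x frequencies matrix (rownames = sample ids).
#' @param grid the [FrequencyGrid-class] the columns live on.
#' @export
writeSpectra <- function(values, grid, path) {
  stopifnot(is.matrix(values), ncol(values) == length(grid))
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(values)))
  df <- data.frame(sample_id = ids, format(values, digits = 12, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", sprintf("f_%.4f", freqPoints(grid)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match requested frequencies to grid columns
#'
#' Nearest-neighbour matching within half a grid step, the rule used when a
#' published band list (printed to 2 decimals) is resolved on an instrument
#' grid.
#'
#' @param freqs frequencies to look up (THz).
#' @param grid a [FrequencyGrid-class].
#' @return integer column indices into the grid.
#' @export
matchFrequencies <- function(freqs, grid) {
  p <- freqPoints(grid)
  half <- freqStep(grid) / 2
  vapply(freqs, function(f) {
    i <- which.min(abs(p - f))
    if (abs(p[i] - f) > half + 1e-12)
      stop(sprintf("frequency %.4f THz is not on the grid (nearest %.4f)",
                   f, p[i]))
    i
  }, integer(1L))
}

#' Write / read a full dataset as plain CSV files
#'
#' One wide CSV per optical channel (\code{power.csv}, \code{absorbance.csv},
#' \code{transmittance.csv}) plus \code{labels.csv} with columns
#' \code{sample_id, stress_level, m1_g, m2_g, moisture_pct}.
#'
#' @param x a [THzSpectra-class].
#' @param dir output (resp. input) directory.
#' @return \code{writeDataset}: the directory, invisibly;
#'   \code{readDataset}: a [THzSpectra-class].
#' @export
writeDataset <- function(x, dir) {
  stopifnot(is(x, "THzSpectra"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- frequencyGrid(x)
  for (nm in SummarizedExperiment::assayNames(x))
    writeSpectra(spectraMatrix(x, nm), grid,
                 file.path(dir, paste0(nm, ".csv")))
  write.csv(moistureLabels(x), file.path(dir, "labels.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  files <- file.path(dir, paste0(.THZ_DIMENSIONS, ".csv"))
  have <- .THZ_DIMENSIONS[file.exists(files)]
  if (length(have) == 0L) stop("no channel CSVs found in ", dir)
  parts <- lapply(have, function(nm)
    readSpectra(file.path(dir, paste0(nm, ".csv")), nm))
  grid <- parts[[1L]]$grid
  assays <- lapply(parts, `[[`, "values")
  names(assays) <- have
  labf <- file.path(dir, "labels.csv")
  lab <- if (file.exists(labf)) read.csv(labf, stringsAsFactors = FALSE)
  THzSpectra(assays, grid = grid, sampleData = lab)
}
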