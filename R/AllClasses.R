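#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats coef cor lm predict prcomp rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

#' Uniform frequency grid for terahertz spectra
#'
#' An evenly spaced, strictly increasing set of frequency points (THz) shared
#' by all spectra in an analysis. The default covers the 0.5--1.5 THz window
#' at the instrument sampling interval of 0.0038 THz, giving 264 points.
#'
#' @slot start numeric(1), first frequency (THz).
#' @slot stop numeric(1), upper bound of the window (THz); the last grid point
#'   is the largest multiple of \code{step} above \code{start} not exceeding
#'   \code{stop}.
#' @slot step numeric(1), spacing between adjacent points (THz).
#' @slot points numeric vector of frequencies (THz).
#'
#' @seealso [frequencyGrid()]
#' @exportClass FrequencyGrid
setClass("FrequencyGrid",
  representation(start = "numeric", stop = "numeric", step = "numeric",
                 points = "numeric"))

setValidity("FrequencyGrid", function(object) {
  p <- object@points
  if (length(p) < 2L) return("grid needs at least two points")
  d <- diff(p)
  if (any(d <= 0)) return("frequency points must be strictly increasing")
  if (max(abs(d - object@step)) > 1e-9)
    return("frequency points must be uniformly spaced at 'step'")
  if (abs(p[1L] - object@start) > 1e-9)
    return("first point must equal 'start'")
  if (p[length(p)] > object@stop + 1e-9)
    return("points must not exceed 'stop'")
  TRUE
})

#' Construct or extract a frequency grid
#'
#' Called with numeric bounds, builds a uniform grid; called with a
#' [THzSpectra-class] object, returns the grid the object carries.
#'
#' @param start first frequency in THz (default 0.5), or a
#'   \code{THzSpectra}/\code{FrequencyGrid} object to extract the grid from.
#' @param stop upper window bound in THz. Default 1.5 THz.
#' @param step sampling interval in THz. Default 0.0038 THz.
#' @return A [FrequencyGrid-class] object.
#' @examples
#' g <- frequencyGrid()
#' length(freqPoints(g))  # 264
#' @export
frequencyGrid <- function(start = 0.5, stop = 1.5, step = 0.0038) {
  if (is(start, "FrequencyGrid")) return(start)
  if (is(start, "THzSpectra")) return(S4Vectors::metadata(start)$grid)
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            step > 0, stop > start)
  n <- floor((stop - start) / step + 1e-9) + 1L
  pts <- start + step * (seq_len(n) - 1L)
  new("FrequencyGrid", start = start, stop = stop, step = step, points = pts)
}

#' @describeIn frequencyGrid frequency points (THz) of a grid.
#' @param grid a \code{FrequencyGrid}.
#' @export
freqPoints <- function(grid) {
  stopifnot(is(grid, "FrequencyGrid"))
  grid@points
}

#' @describeIn frequencyGrid grid spacing (THz).
#' @export
freqStep <- function(grid) {
  stopifnot(is(grid, "FrequencyGrid"))
  grid@step
}

#' @describeIn frequencyGrid number of frequency points.
#' @param x a \code{FrequencyGrid}.
#' @export
setMethod("length", "FrequencyGrid", function(x) length(x@points))

#' @rdname FrequencyGrid-class
#' @param object a \code{FrequencyGrid}.
#' @export
setMethod("show", "FrequencyGrid", function(object) {
  p <- object@points
  cat(sprintf("FrequencyGrid: %d points, %.4f-%.4f THz, step %.4f THz\n",
              length(p), p[1L], p[length(p)], object@step))
})

#' Restrict a grid (and optionally spectra) to an analysis window
#'
#' @param grid a [FrequencyGrid-class].
#' @param lo,hi window bounds (THz), inclusive within half a grid step.
#' @param values optional samples x frequencies matrix on \code{grid};
#'   restricted to the same columns when supplied.
#' @return The restricted grid, or \code{list(grid=, values=)} when
#'   \code{values} is given.
#' @export
restrictToWindow <- function(grid, lo = 0.5, hi = 1.5, values = NULL) {
  p <- freqPoints(grid)
  half <- grid@step / 2
  keep <- p >= lo - half & p <= hi + half
  if (sum(keep) < 2L) stop("window retains fewer than two frequency points")
  sub <- new("FrequencyGrid", start = p[keep][1L], stop = hi,
             step = grid@step, points = p[keep])
  if (is.null(values)) return(sub)
  stopifnot(ncol(values) == length(p))
  list(grid = sub, values = values[, keep, drop = FALSE])
}

.THZ_DIMENSIONS <- c("power", "absorbance", "transmittance")

#' Container for multi-channel terahertz leaf spectra
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are
#' frequency points, columns are leaf samples, and assays hold one or more of
#' the three optical channels (\code{power}, \code{absorbance},
#' \code{transmittance}). The shared [FrequencyGrid-class] lives in
#' \code{metadata(x)$grid} and per-sample moisture labels (stress level,
#' fresh/dry mass, dry-basis moisture \%) in \code{colData}.
#'
#' Channel value contracts: transmittance in (0, 1]; power and absorbance
#' finite and non-negative.
#'
#' @seealso [THzSpectra()], [spectraMatrix()], [simulateDataset()]
#' @exportClass THzSpectra
setClass("THzSpectra", contains = "SummarizedExperiment")

setValidity("THzSpectra", function(object) {
  grid <- S4Vectors::metadata(object)$grid
  if (!is(grid, "FrequencyGrid"))
    return("metadata(x)$grid must be a FrequencyGrid")
  if (nrow(object) != length(grid))
    return("row count must equal the number of grid frequencies")
  an <- SummarizedExperiment::assayNames(object)
  if (length(an) == 0L || !all(an %in% .THZ_DIMENSIONS))
    return(sprintf("assay names must be among: %s",
                   paste(.THZ_DIMENSIONS, collapse = ", ")))
  for (nm in an) {
    a <- SummarizedExperiment::assay(object, nm)
    if (!all(is.finite(a)))
      return(sprintf("assay '%s' contains non-finite values", nm))
    if (nm == "transmittance" && (any(a <= 0) || any(a > 1 + 1e-12)))
      return("transmittance values must lie in (0, 1]")
    if (nm != "transmittance" && any(a < 0))
      return(sprintf("assay '%s' must be non-negative", nm))
  }
  TRUE
})

#' Build a THzSpectra object from per-channel matrices
#'
#' @param assays named list of samples x frequencies matrices; names among
#'   \code{power}, \code{absorbance}, \code{transmittance}. Matrices are
#'   stored transposed (frequencies x samples) as is usual for
#'   SummarizedExperiment; [spectraMatrix()] returns the samples-by-frequency
#'   orientation used throughout the modeling functions.
#' @param grid the common [FrequencyGrid-class].
#' @param sampleData optional data.frame/DataFrame of per-sample labels
#'   (one row per sample); a \code{sample_id} column becomes the column names.
#' @return A [THzSpectra-class] object.
#' @export
THzSpectra <- function(assays, grid, sampleData = NULL) {
  stopifnot(is.list(assays), length(assays) >= 1L, !is.null(names(assays)))
  n <- nrow(assays[[1L]])
  ids <- rownames(assays[[1L]])
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  tr <- lapply(assays, function(m) {
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == length(grid))
    t(m)
  })
  if (is.null(sampleData)) {
    cd <- S4Vectors::DataFrame(row.names = ids)
  } else {
    cd <- S4Vectors::DataFrame(sampleData)
    if ("sample_id" %in% colnames(cd)) ids <- as.character(cd$sample_id)
    rownames(cd) <- ids
  }
  tr <- lapply(tr, function(m) { colnames(m) <- ids; m })
  rd <- S4Vectors::DataFrame(frequency_THz = freqPoints(grid))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = tr, rowData = rd, colData = cd,
    metadata = list(grid = grid))
  new("THzSpectra", se)
}

#' Accessors for THzSpectra
#'
#' \code{spectraMatrix} extracts one optical channel as a samples x
#' frequencies matrix (the orientation all modeling functions use);
#' \code{frequencyGrid} returns the shared grid; \code{moistureLabels} the
#' per-sample label table; \code{moisture} the dry-basis moisture vector (\%).
#'
#' @param x a [THzSpectra-class] object.
#' @param dimension one of \code{"power"}, \code{"absorbance"},
#'   \code{"transmittance"}.
#' @return See each description.
#' @export
spectraMatrix <- function(x, dimension) {
  stopifnot(is(x, "THzSpectra"))
  dimension <- match.arg(dimension, .THZ_DIMENSIONS)
  m <- t(SummarizedExperiment::assay(x, dimension))
  colnames(m) <- sprintf("f_%.4f", freqPoints(frequencyGrid(x)))
  m
}

#' @rdname spectraMatrix
#' @export
moistureLabels <- function(x) {
  stopifnot(is(x, "THzSpectra"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @rdname spectraMatrix
#' @export
moisture <- function(x) {
  lab <- moistureLabels(x)
  if (!"moisture_pct" %in% colnames(lab))
    stop("no 'moisture_pct' column in the sample labels")
  setNames(lab$moisture_pct, rownames(lab))
}

#' @rdname THzSpectra-class
#' @param object a \code{THzSpectra}.
#' @export
setMethod("show", "THzSpectra", function(object) {
  cat(sprintf("THzSpectra: %d samples x %d frequencies\n",
              ncol(object), nrow(object)))
  cat("  channels:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
  show(frequencyGrid(object))
  lab <- SummarizedExperiment::colData(object)
  if (ncol(lab)) cat("  labels:", paste(colnames(lab), collapse = ", "), "\n")
})
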