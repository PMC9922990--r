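#' Gravimetric dry-basis moisture content
#'
#' \eqn{w = (m_1 - m_2)/m_2 \times 100}, with \eqn{m_1} the fresh and
#' \eqn{m_2} the oven-dry leaf mass in grams. Vectorized.
#'
#' @param m1 fresh mass (g).
#' @param m2 dry mass (g), > 0 and <= m1.
#' @return dry-basis moisture content in percent.
#' @examples
#' moistureContent(2, 1)    # 100
#' moistureContent(3.6, 0.9)  # 300
#' @export
moistureContent <- function(m1, m2) {
  if (any(!is.finite(m1)) || any(!is.finite(m2))) stop("masses must be finite")
  if (any(m2 <= 0)) stop("dry mass m2 must be positive")
  if (any(m1 < m2))
    stop("fresh mass below dry mass (evaporation or weighing fault)")
  (m1 - m2) / m2 * 100
}

#' Average replicate scans of one sample
#'
#' @param scans k x n_freq matrix, one row per replicate scan.
#' @return columnwise mean spectrum (numeric vector).
#' @export
averageReplicates <- function(scans) {
  if (!is.matrix(scans)) scans <- rbind(scans)
  if (!all(is.finite(scans))) stop("replicate scans must be finite")
  colMeans(scans)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: within each sliding window of
#' \code{window} points a polynomial of degree \code{polyorder} is fitted and
#' the centre point replaced by its fitted value; near the boundaries the
#' local polynomial is evaluated at the edge positions so the output keeps
#' the full spectrum length (no trimming at 0.5 / 1.5 THz). Implemented via
#' \code{signal::sgolayfilt}.
#'
#' @param x numeric vector (one spectrum) or samples x frequencies matrix
#'   (each row smoothed independently).
#' @param window odd window width in points, > polyorder. Default 5.
#' @param polyorder polynomial degree. Default 2.
#' @return smoothed object of the same shape.
#' @export
sgSmooth <- function(x, window = 5L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("window must exceed polyorder")
  if (is.matrix(x)) {
    if (ncol(x) < window) stop("spectrum shorter than the smoothing window")
    out <- t(apply(x, 1L, signal::sgolayfilt, p = polyorder, n = window))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) < window) stop("spectrum shorter than the smoothing window")
  signal::sgolayfilt(x, p = polyorder, n = window)
}

#' Smooth every channel of a THzSpectra object
#'
#' @param x a [THzSpectra-class].
#' @inheritParams sgSmooth
#' @return a new [THzSpectra-class] with each assay row-wise smoothed
#'   (transmittance re-clipped into (0, 1] if smoothing overshoots).
#' @export
smoothSpectra <- function(x, window = 5L, polyorder = 2L) {
  stopifnot(is(x, "THzSpectra"))
  grid <- frequencyGrid(x)
  sm <- lapply(SummarizedExperiment::assayNames(x), function(nm) {
    m <- sgSmooth(spectraMatrix(x, nm), window, polyorder)
    if (nm == "transmittance") m <- pmin(pmax(m, .Machine$double.xmin), 1)
    if (nm != "transmittance") m <- pmax(m, 0)
    m
  })
  names(sm) <- SummarizedExperiment::assayNames(x)
  THzSpectra(sm, grid = grid,
             sampleData = as.data.frame(SummarizedExperiment::colData(x)))
}

#' Choose the Savitzky-Golay window by downstream calibration quality
#'
#' For each candidate window the spectra are smoothed and passed to a
#' downstream fit (by default: SPXY 3:1 split followed by a
#' partial-least-squares calibration on the full band, reported as
#' calibration Rc / RMSEC). The window with the highest Rc wins; ties go to
#' the smaller window, which also preserves more spectral detail.
#'
#' @param spectra samples x frequencies matrix (one optical channel).
#' @param y response vector (moisture \%).
#' @param candidates odd window widths to compare. Default c(5, 7, 9, 11).
#' @param polyorder polynomial degree handed to [sgSmooth()].
#' @param downstream function(X_smoothed, y) returning
#'   \code{list(Rc =, RMSEC =)}; \code{NULL} uses the default harness.
#' @return list with \code{window} (chosen width) and \code{table}
#'   (data.frame: window, Rc, RMSEC, one row per candidate; failed candidates
#'   carry NA).
#' @export
selectSgWindow <- function(spectra, y, candidates = c(5L, 7L, 9L, 11L),
                           polyorder = 2L, downstream = NULL) {
  stopifnot(is.matrix(spectra), nrow(spectra) == length(y))
  if (any(candidates %% 2L == 0L) || any(candidates <= polyorder))
    stop("candidates must be odd and exceed polyorder")
  if (is.null(downstream)) downstream <- function(X, y) {
    n_cal <- roundHalfUp(0.75 * nrow(X))
    sp <- spxySplit(X, y, n_cal)
    Xc <- X[sp$calibration, , drop = FALSE]
    yc <- y[sp$calibration]
    fit <- plsFit(Xc, yc, ncomp = min(10L, nrow(Xc) - 1L, ncol(Xc)))
    pred <- plsPredict(fit, Xc)
    list(Rc = cor(pred, yc), RMSEC = sqrt(mean((pred - yc)^2)))
  }
  rows <- lapply(candidates, function(wd) {
    res <- tryCatch(downstream(sgSmooth(spectra, wd, polyorder), y),
                    error = function(e) list(Rc = NA_real_, RMSEC = NA_real_))
    data.frame(window = wd, Rc = res$Rc, RMSEC = res$RMSEC)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$Rc))
  if (length(ok) == 0L) stop("every candidate window failed downstream")
  # highest Rc; ties (within double rounding) to the smaller window
  best <- ok[order(-round(tab$Rc[ok], 12L), tab$window[ok])][1L]
  list(window = tab$window[best], table = tab)
}

#' Round-half-up at 0.5 (so 0.75 x 80 gives exactly 60)
#' @param x numeric.
#' @return integer.
#' @keywords internal
roundHalfUp <- function(x) as.integer(floor(x + 0.5))
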