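#' Calibration / prediction partitions by Kennard-Stone and SPXY
#'
#' Both algorithms are deterministic max-min designs. Kennard-Stone seeds the
#' calibration set with the two samples at maximal Euclidean distance in
#' predictor space and then repeatedly adds the sample whose minimum distance
#' to the already-selected set is largest. SPXY runs the same recursion on
#' the joint distance
#' \deqn{d(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y,}
#' so the calibration set also spans the response range. All argmax ties are
#' broken by the lowest sample index, making the partitions reproducible
#' without a seed. At the conventional 3:1 ratio, 80 samples split 60/20.
#'
#' @param X samples x features matrix.
#' @param n_cal calibration-set size, in \code{[2, n - 1]}.
#' @param y response vector (SPXY only), finite.
#' @return An object of class \code{SplitResult}: list with integer indices
#'   \code{calibration} (in selection order) and \code{prediction}
#'   (ascending), matching \code{*_ids} when \code{X} has rownames,
#'   \code{method} and \code{ratio}.
#' @examples
#' ksSplit(matrix(c(0, 1, 2, 10)), 2)$calibration  # samples 1 and 4
#' @export
ksSplit <- function(X, n_cal) {
  X <- as.matrix(X)
  .maxminSplit(as.matrix(stats::dist(X)), n_cal, "KS", rownames(X))
}

#' @rdname ksSplit
#' @export
spxySplit <- function(X, y, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(is.finite(y)))
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0)
    stop("all samples identical in both X and y; no split possible")
  d <- 0
  if (mx > 0) d <- d + dx / mx
  if (my > 0) d <- d + dy / my
  .maxminSplit(d, n_cal, "SPXY", rownames(X))
}

# shared max-min recursion on a full distance matrix; ties -> lowest index
.maxminSplit <- function(D, n_cal, method, ids = NULL) {
  n <- nrow(D)
  n_cal <- as.integer(n_cal)
  if (n_cal < 2L || n_cal > n - 1L)
    stop(sprintf("n_cal must be in [2, %d], got %d", n - 1L, n_cal))
  # seed pair: maximal distance, lexicographically smallest on ties
  up <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[up]
  best <- up[order(-dv, up[, 1L], up[, 2L])[1L], ]
  sel <- as.integer(c(best[[1L]], best[[2L]]))
  mind <- unname(pmin(D[, sel[1L]], D[, sel[2L]]))
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    # which.max takes the first (lowest) index on ties
    nxt <- as.integer(which.max(mind))
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  pred <- setdiff(seq_len(n), sel)
  structure(list(
    calibration = sel, prediction = pred,
    calibration_ids = if (!is.null(ids)) ids[sel],
    prediction_ids = if (!is.null(ids)) ids[pred],
    method = method, ratio = n_cal / n), class = "SplitResult")
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("SplitResult (%s): %d calibration / %d prediction samples\n",
              x$method, length(x$calibration), length(x$prediction)))
  invisible(x)
}

#' Compare KS and SPXY splits by downstream calibration quality
#'
#' For each optical channel and each splitting algorithm, partitions the
#' samples 3:1 (by default), fits a calibration model on the calibration set
#' and tabulates Rc / RMSEC — the layout used to pick the splitter before
#' any band selection. The default downstream model is the internal
#' full-band PLS calibration.
#'
#' @param spectraList named list of samples x features matrices (typically
#'   power / absorbance / transmittance) or a [THzSpectra-class].
#' @param y response vector (moisture \%).
#' @param ratio calibration fraction. Default 0.75.
#' @param downstream function(X_cal, y_cal) -> list(Rc =, RMSEC =); NULL for
#'   the default PLS harness.
#' @return data.frame with columns dimension, method, Rc, RMSEC (6 rows for
#'   three channels).
#' @export
compareSplitMethods <- function(spectraList, y, ratio = 0.75,
                                downstream = NULL) {
  if (is(spectraList, "THzSpectra")) {
    nms <- SummarizedExperiment::assayNames(spectraList)
    x <- spectraList
    spectraList <- lapply(nms, function(nm) spectraMatrix(x, nm))
    names(spectraList) <- nms
  }
  if (is.null(downstream)) downstream <- function(Xc, yc) {
    fit <- plsFit(Xc, yc, ncomp = min(10L, nrow(Xc) - 1L, ncol(Xc)))
    pred <- plsPredict(fit, Xc)
    list(Rc = cor(pred, yc), RMSEC = sqrt(mean((pred - yc)^2)))
  }
  rows <- list()
  for (dim_ in names(spectraList)) {
    X <- spectraList[[dim_]]
    n_cal <- roundHalfUp(ratio * nrow(X))
    for (m in c("KS", "SPXY")) {
      sp <- if (m == "KS") ksSplit(X, n_cal) else spxySplit(X, y, n_cal)
      cell <- tryCatch(
        downstream(X[sp$calibration, , drop = FALSE], y[sp$calibration]),
        error = function(e) list(Rc = NA_real_, RMSEC = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = dim_, method = m, Rc = cell$Rc, RMSEC = cell$RMSEC)
    }
  }
  do.call(rbind, rows)
}
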