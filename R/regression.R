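#' Multiple linear regression on selected frequency bands
#'
#' Ordinary least squares of moisture on the handful of SCARS-selected
#' bands of one optical channel. The design (with intercept) must be full
#' rank; collinear columns are reported by name rather than silently
#' dropped.
#'
#' @param X_sel n x p matrix of selected-band intensities (column names kept
#'   as frequency labels).
#' @param y response vector (moisture \%).
#' @param selected_frequencies optional THz values labelling the columns.
#' @param dimension optional optical-channel tag.
#' @return object of class \code{MlrModel}: \code{intercept},
#'   \code{coefficients}, \code{selected_frequencies}, \code{dimension}.
#' @examples
#' X <- cbind(x1 = rnorm(20), x2 = rnorm(20))
#' m <- mlrFit(X, 2 * X[, 1] - 3 * X[, 2] + 5)
#' @export
mlrFit <- function(X_sel, y, selected_frequencies = NULL, dimension = NULL) {
  X_sel <- as.matrix(X_sel)
  n <- nrow(X_sel); p <- ncol(X_sel)
  stopifnot(length(y) == n)
  if (n <= p + 1L)
    stop(sprintf("need more samples (%d) than predictors + 1 (%d)", n, p + 1L))
  design <- cbind(`(Intercept)` = 1, X_sel)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrd, y)
  structure(list(intercept = unname(beta[1L]),
                 coefficients = beta[-1L],
                 selected_frequencies = selected_frequencies,
                 dimension = dimension), class = "MlrModel")
}

#' @export
predict.MlrModel <- function(object, newdata, ...) {
  as.vector(as.matrix(newdata) %*% object$coefficients + object$intercept)
}

#' @export
print.MlrModel <- function(x, ...) {
  cat(sprintf("MlrModel%s: %d bands, intercept %.4g\n",
              if (is.null(x$dimension)) "" else paste0(" (", x$dimension, ")"),
              length(x$coefficients), x$intercept))
  invisible(x)
}

#' Correlation / RMSE fit metrics
#'
#' The chemometric convention: R is the Pearson correlation between
#' predicted and measured response, RMSE its root-mean-square error, tagged
#' Rc/RMSEC on the calibration set and Rp/RMSEP on the prediction set. A
#' zero-variance response or prediction leaves \code{r} as NA with
#' \code{r_defined = FALSE} — never a silent 0.
#'
#' @param predicted,measured numeric vectors of equal length.
#' @param set \code{"calibration"} or \code{"prediction"}.
#' @return list of class \code{FitMetrics}: \code{r}, \code{rmse},
#'   \code{set}, \code{r_defined}.
#' @export
fitMetrics <- function(predicted, measured,
                       set = c("calibration", "prediction")) {
  set <- match.arg(set)
  stopifnot(length(predicted) == length(measured),
            all(is.finite(predicted)), all(is.finite(measured)))
  rmse <- sqrt(mean((predicted - measured)^2))
  defined <- sd(predicted) > 0 && sd(measured) > 0
  r <- if (defined) cor(predicted, measured) else NA_real_
  structure(list(r = r, rmse = rmse, set = set, r_defined = defined),
            class = "FitMetrics")
}

#' @export
print.FitMetrics <- function(x, ...) {
  tag <- if (x$set == "calibration") c("Rc", "RMSEC") else c("Rp", "RMSEP")
  cat(sprintf("%s = %.4f, %s = %.4f\n", tag[1L], x$r, tag[2L], x$rmse))
  invisible(x)
}

#' Evaluate a fitted model on one sample set
#'
#' @param model anything with a \code{predict} method over a matrix.
#' @param X_sel matrix of the same columns the model was fitted on.
#' @param y measured response.
#' @param set \code{"calibration"} or \code{"prediction"}.
#' @return a [fitMetrics()] object.
#' @export
evaluateModel <- function(model, X_sel, y,
                          set = c("calibration", "prediction")) {
  fitMetrics(predict(model, X_sel), y, match.arg(set))
}

#' Per-channel single-dimension model report
#'
#' Fits one MLR per optical channel on its selected bands and tabulates Rc,
#' RMSEC, Rp, RMSEP in a 4-row by channels layout.
#'
#' @param bandMatrices named list (per channel) of samples x selected-band
#'   matrices covering ALL samples.
#' @param y full response vector.
#' @param split a \code{SplitResult} shared by the three channels.
#' @return list with \code{table} (4 x channels data.frame, rownames Rc,
#'   RMSEC, Rp, RMSEP) and \code{models} (named list of \code{MlrModel}).
#' @export
singleDimensionReport <- function(bandMatrices, y, split) {
  stopifnot(is.list(bandMatrices), !is.null(names(bandMatrices)),
            inherits(split, "SplitResult"))
  cal <- split$calibration; prd <- split$prediction
  models <- list()
  tab <- matrix(NA_real_, 4L, length(bandMatrices),
                dimnames = list(c("Rc", "RMSEC", "Rp", "RMSEP"),
                                names(bandMatrices)))
  for (nm in names(bandMatrices)) {
    X <- as.matrix(bandMatrices[[nm]])
    res <- tryCatch({
      m <- mlrFit(X[cal, , drop = FALSE], y[cal], dimension = nm)
      mc <- evaluateModel(m, X[cal, , drop = FALSE], y[cal], "calibration")
      mp <- evaluateModel(m, X[prd, , drop = FALSE], y[prd], "prediction")
      list(model = m, cell = c(mc$r, mc$rmse, mp$r, mp$rmse))
    }, error = function(e) list(model = NULL,
                                cell = rep(NA_real_, 4L)))
    models[[nm]] <- res$model
    tab[, nm] <- res$cell
  }
  list(table = as.data.frame(tab), models = models)
}
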