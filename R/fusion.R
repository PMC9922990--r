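#' Concatenate selected bands of the three optical channels
#'
#' Builds the fused feature matrix: for each channel (fixed order power,
#' absorbance, transmittance) the SCARS-selected frequencies are resolved on
#' the grid by nearest-neighbour matching within half a step and the
#' corresponding columns are concatenated. The same frequency may appear
#' under two channels (the channels are distinct measurements) and yields
#' two distinct columns.
#'
#' @param bands named list of THz frequency vectors per channel (names among
#'   power, absorbance, transmittance); an empty element is skipped with a
#'   warning.
#' @param spectraList named list of samples x frequencies matrices on
#'   \code{grid}, or a [THzSpectra-class].
#' @param grid the [FrequencyGrid-class]; taken from the THzSpectra when one
#'   is supplied.
#' @return samples x m matrix, m = total band count, with column names
#'   \code{<channel>_<THz>} and attribute \code{labels} (data.frame with
#'   dimension and frequency_THz per column).
#' @export
fuseFeatures <- function(bands, spectraList, grid = NULL) {
  if (is(spectraList, "THzSpectra")) {
    grid <- frequencyGrid(spectraList)
    x <- spectraList
    nms <- SummarizedExperiment::assayNames(x)
    spectraList <- lapply(nms, function(nm) spectraMatrix(x, nm))
    names(spectraList) <- nms
  }
  stopifnot(is(grid, "FrequencyGrid"), is.list(bands), !is.null(names(bands)))
  order_ <- intersect(.THZ_DIMENSIONS, names(bands))
  cols <- list(); labs <- list()
  for (nm in order_) {
    f <- bands[[nm]]
    if (length(f) == 0L) {
      warning(sprintf("no bands selected for channel '%s'; skipped", nm))
      next
    }
    if (!nm %in% names(spectraList))
      stop(sprintf("no spectra supplied for channel '%s'", nm))
    idx <- matchFrequencies(f, grid)
    m <- spectraList[[nm]][, idx, drop = FALSE]
    colnames(m) <- sprintf("%s_%.2f", nm, f)
    cols[[nm]] <- m
    labs[[nm]] <- data.frame(dimension = nm,
                             frequency_THz = freqPoints(grid)[idx])
  }
  if (length(cols) == 0L) stop("all band lists empty; nothing to fuse")
  out <- do.call(cbind, cols)
  lab <- do.call(rbind, labs)
  rownames(lab) <- NULL
  if (anyDuplicated(paste(lab$dimension, lab$frequency_THz)))
    stop("duplicate (dimension, frequency) column in the fused features")
  attr(out, "labels") <- lab
  out
}

#' Fit / apply a per-feature normalizer on calibration data
#'
#' Z-score by default (calibration mean and sd per feature), optionally
#' min-max to [0, 1]. A constant feature is centred with scale 1 (all
#' zeros). The normalizer fitted on the calibration set is applied unchanged
#' to prediction data — no leakage.
#'
#' @param X_cal calibration samples x features matrix.
#' @param method \code{"zscore"} (default) or \code{"minmax"}.
#' @return \code{normalizeFit}: list of class \code{Normalizer}.
#' @export
normalizeFit <- function(X_cal, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  X_cal <- as.matrix(X_cal)
  if (method == "zscore") {
    ctr <- colMeans(X_cal)
    scl <- apply(X_cal, 2L, sd)
  } else {
    ctr <- apply(X_cal, 2L, min)
    scl <- apply(X_cal, 2L, max) - ctr
  }
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl, method = method),
            class = "Normalizer")
}

#' @rdname normalizeFit
#' @param normalizer a fitted \code{Normalizer}.
#' @param X matrix with the same features.
#' @return \code{normalizeApply}: the transformed matrix.
#' @export
normalizeApply <- function(normalizer, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(normalizer$center))
  sweep(sweep(X, 2L, normalizer$center), 2L, normalizer$scale, "/")
}

#' Principal-component reduction at a cumulative-contribution threshold
#'
#' Eigendecomposition of the calibration covariance of the (normalized)
#' fused features. Component contributions are eigenvalues over their total;
#' the retained count k is the smallest number of leading components whose
#' cumulative contribution reaches the threshold (default 95\%).
#'
#' @param X_cal normalized calibration matrix (n >= 2).
#' @param threshold cumulative-contribution cutoff in (0, 1]. Default 0.95.
#' @return object of class \code{PcaReduction}: \code{center},
#'   \code{loadings} (features x components), \code{contributions},
#'   \code{cumulative}, \code{k}, \code{cumulative_at_k}, \code{threshold}.
#' @export
pcaFit <- function(X_cal, threshold = 0.95) {
  X_cal <- as.matrix(X_cal)
  stopifnot(nrow(X_cal) >= 2L)
  ctr <- colMeans(X_cal)
  Xc <- sweep(X_cal, 2L, ctr)
  S <- crossprod(Xc) / (nrow(Xc) - 1L)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  contrib <- ev / sum(ev)
  sel <- selectComponents(contrib, threshold)
  structure(list(center = ctr, loadings = eig$vectors,
                 contributions = contrib, cumulative = cumsum(contrib),
                 k = sel$k, cumulative_at_k = sel$cumulative,
                 threshold = threshold), class = "PcaReduction")
}

#' @rdname pcaFit
#' @param reduction a fitted \code{PcaReduction}.
#' @param X normalized matrix on the same features.
#' @return \code{pcaApply}: n x k score matrix.
#' @export
pcaApply <- function(reduction, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(reduction$center))
  sweep(X, 2L, reduction$center) %*%
    reduction$loadings[, seq_len(reduction$k), drop = FALSE]
}

#' Smallest component count reaching a cumulative contribution
#'
#' @param contributions non-negative, non-increasing variance fractions
#'   summing to at most 1 (within 1e-9).
#' @param threshold cutoff in (0, 1].
#' @return list with \code{k} and \code{cumulative} (the running sum at k).
#' @examples
#' selectComponents(c(0.6, 0.3, 0.1), 0.85)  # k = 2, cumulative 0.9
#' @export
selectComponents <- function(contributions, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  stopifnot(length(contributions) >= 1L, all(is.finite(contributions)))
  if (any(contributions < -1e-12))
    stop("contributions must be non-negative")
  if (any(diff(contributions) > 1e-9))
    stop("contributions must be non-increasing")
  if (sum(contributions) > 1 + 1e-9)
    stop("contributions must sum to at most 1")
  cum <- cumsum(contributions)
  hit <- which(cum >= threshold - 1e-12)
  if (length(hit) == 0L)
    stop(sprintf("cumulative contribution (%.4f) never reaches %.4f",
                 cum[length(cum)], threshold))
  k <- hit[1L]
  list(k = k, cumulative = cum[k])
}

#' Default RBF-SVR parameter grid
#'
#' Log-spaced gamma and cost ranges with three epsilon widths, plus the
#' reference triple (g = 8.65, C = 2.41, p = 0.01) commonly reported for
#' this problem, for parity runs.
#'
#' @return data.frame with columns gamma, cost, epsilon.
#' @export
defaultSvrGrid <- function() {
  g <- expand.grid(gamma = 2^seq(-6, 6, by = 2),
                   cost = 2^seq(-4, 6, by = 2),
                   epsilon = c(0.001, 0.01, 0.1))
  rbind(g, data.frame(gamma = 8.65, cost = 2.41, epsilon = 0.01))
}

#' Grid-searched epsilon-SVR with RBF kernel
#'
#' For every (gamma, cost, epsilon) triple, computes deterministic K-fold
#' cross-validated predictions on the calibration scores and scores the
#' triple by the Pearson correlation between CV predictions and the
#' measured response (cross-validated Rc). The winner (ties: smaller cost,
#' then smaller gamma) is refitted on the full calibration data. Built on
#' \code{e1071::svm}; the response is internally scaled by \code{svm}
#' itself.
#'
#' @param Z_cal calibration score matrix (n x k).
#' @param y_cal calibration response.
#' @param grid data.frame(gamma, cost, epsilon); default [defaultSvrGrid()].
#' @param cv_folds folds for the search. Default 5.
#' @return object of class \code{SvrFit}: \code{model} (e1071 svm),
#'   \code{best} (winning triple + its CV Rc/RMSECV), \code{search}
#'   (full grid table).
#' @export
svrFit <- function(Z_cal, y_cal, grid = defaultSvrGrid(), cv_folds = 5L) {
  Z_cal <- as.matrix(Z_cal)
  n <- nrow(Z_cal)
  stopifnot(length(y_cal) == n, nrow(grid) >= 1L, cv_folds >= 2L,
            cv_folds <= n, all(grid$gamma > 0), all(grid$cost > 0),
            all(grid$epsilon >= 0))
  fold_id <- rep_len(seq_len(cv_folds), n)
  search <- grid
  search$cv_r <- NA_real_
  search$cv_rmse <- NA_real_
  search$error <- NA_character_
  for (j in seq_len(nrow(grid))) {
    pred <- rep(NA_real_, n)
    err <- tryCatch({
      for (k in seq_len(cv_folds)) {
        tr <- fold_id != k
        m <- e1071::svm(Z_cal[tr, , drop = FALSE], y_cal[tr],
                        type = "eps-regression", kernel = "radial",
                        gamma = grid$gamma[j], cost = grid$cost[j],
                        epsilon = grid$epsilon[j])
        pred[!tr] <- predict(m, Z_cal[!tr, , drop = FALSE])
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(err)) {
      search$cv_rmse[j] <- sqrt(mean((pred - y_cal)^2))
      search$cv_r[j] <- if (sd(pred) > 0) cor(pred, y_cal) else NA_real_
    } else search$error[j] <- err
  }
  ok <- which(is.finite(search$cv_r))
  if (length(ok) == 0L) {
    print(search)
    stop("every grid cell failed or produced undefined CV correlation")
  }
  best <- ok[order(-round(search$cv_r[ok], 12L), search$cost[ok],
                   search$gamma[ok])][1L]
  model <- e1071::svm(Z_cal, y_cal, type = "eps-regression",
                      kernel = "radial", gamma = grid$gamma[best],
                      cost = grid$cost[best], epsilon = grid$epsilon[best])
  structure(list(model = model, best = search[best, ], search = search),
            class = "SvrFit")
}

#' Fit the fused normalization -> PCA -> SVR pipeline
#'
#' Everything is fitted on the calibration rows only: the z-score
#' normalizer, the PCA basis (components kept to the cumulative-contribution
#' threshold) and the grid-searched RBF-SVR. Prediction rows are only ever
#' transformed with the frozen calibration parameters.
#'
#' @param fused samples x features matrix from [fuseFeatures()] (all
#'   samples).
#' @param y full response vector.
#' @param split a \code{SplitResult}.
#' @param threshold PCA cumulative-contribution cutoff. Default 0.95.
#' @param svr_grid parameter grid; default [defaultSvrGrid()].
#' @param cv_folds folds for the SVR search. Default 5.
#' @param normalize_method passed to [normalizeFit()].
#' @return object of class \code{FusionModel} with elements
#'   \code{normalizer}, \code{pca}, \code{svr}, \code{split},
#'   \code{feature_labels}.
#' @export
fitFusionModel <- function(fused, y, split, threshold = 0.95,
                           svr_grid = defaultSvrGrid(), cv_folds = 5L,
                           normalize_method = "zscore") {
  stopifnot(inherits(split, "SplitResult"), nrow(fused) == length(y))
  cal <- split$calibration
  Xc <- fused[cal, , drop = FALSE]
  norm <- normalizeFit(Xc, method = normalize_method)
  Xn <- normalizeApply(norm, Xc)
  pca <- pcaFit(Xn, threshold)
  Z <- pcaApply(pca, Xn)
  svr <- svrFit(Z, y[cal], grid = svr_grid, cv_folds = cv_folds)
  structure(list(normalizer = norm, pca = pca, svr = svr, split = split,
                 feature_labels = attr(fused, "labels")),
            class = "FusionModel")
}

#' @export
predict.FusionModel <- function(object, newdata, ...) {
  Z <- pcaApply(object$pca, normalizeApply(object$normalizer, newdata))
  as.vector(predict(object$svr$model, Z))
}

#' @export
print.FusionModel <- function(x, ...) {
  cat(sprintf(
    "FusionModel: %d fused bands -> %d PCs (cum. %.4f) -> RBF-SVR (g=%.3g, C=%.3g, p=%.3g)\n",
    length(x$normalizer$center), x$pca$k, x$pca$cumulative_at_k,
    x$svr$best$gamma, x$svr$best$cost, x$svr$best$epsilon))
  invisible(x)
}

#' Evaluate the fusion pipeline on both sample sets
#'
#' @param model a [fitFusionModel()] result.
#' @param fused the full fused feature matrix the model was built from.
#' @param y full response vector.
#' @return list with \code{calibration} and \code{prediction}
#'   ([fitMetrics()] objects) and \code{scatter} (data.frame: sample, set,
#'   measured, predicted) for plotting.
#' @export
fusionEvaluate <- function(model, fused, y) {
  stopifnot(inherits(model, "FusionModel"))
  sp <- model$split
  pc <- predict(model, fused[sp$calibration, , drop = FALSE])
  pp <- predict(model, fused[sp$prediction, , drop = FALSE])
  ids <- rownames(fused)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fused)))
  scatter <- rbind(
    data.frame(sample = ids[sp$calibration], set = "calibration",
               measured = y[sp$calibration], predicted = pc),
    data.frame(sample = ids[sp$prediction], set = "prediction",
               measured = y[sp$prediction], predicted = pp))
  list(calibration = fitMetrics(pc, y[sp$calibration], "calibration"),
       prediction = fitMetrics(pp, y[sp$prediction], "prediction"),
       scatter = scatter)
}
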