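#' Internal PLS1 regression (NIPALS)
#'
#' Lean single-response partial least squares used as the inner regressor of
#' the SCARS selector, where thousands of subsample fits need raw regression
#' coefficients. Columns are centred (not scaled); components whose score
#' variance collapses are dropped, so rank-deficient inputs degrade
#' gracefully instead of erroring.
#'
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' @param ncomp maximum number of latent variables; capped at
#'   \code{min(ncomp, n - 1, p)}.
#' @return list with \code{coef} (length p), \code{intercept},
#'   \code{ncomp} actually used, \code{xmean}, \code{ymean}.
#' @keywords internal
#' @export
plsFit <- function(X, y, ncomp = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2L, p >= 1L)
  A <- max(1L, min(as.integer(ncomp), n - 1L, p))
  xm <- colMeans(X); ym <- mean(y)
  Xd <- sweep(X, 2L, xm)
  yd <- y - ym
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  used <- 0L
  tol <- 1e-12 * max(1, sum(Xd^2))
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 < tol * 1e-6) break
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < tol) break
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    W[, a] <- w; P[, a] <- p_; q[a] <- q_
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - as.vector(t_) * q_
    used <- a
  }
  if (used == 0L) {
    beta <- numeric(p)
  } else {
    Wu <- W[, seq_len(used), drop = FALSE]
    Pu <- P[, seq_len(used), drop = FALSE]
    R <- crossprod(Pu, Wu)
    beta <- as.vector(Wu %*% solve(R, q[seq_len(used)]))
  }
  list(coef = beta, intercept = ym - sum(xm * beta), ncomp = used,
       xmean = xm, ymean = ym)
}

#' @rdname plsFit
#' @param fit a \code{plsFit} result.
#' @param newX matrix with the same columns as the training X.
#' @return \code{plsPredict}: numeric vector of predictions.
#' @keywords internal
#' @export
plsPredict <- function(fit, newX) {
  as.vector(as.matrix(newX) %*% fit$coef + fit$intercept)
}

# K-fold cross-validated RMSE of the internal PLS on (X, y).
# Folds are interleaved by sample order (deterministic).
.plsRmsecv <- function(X, y, folds = 5L, ncomp = 10L) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)
  press <- 0
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit <- plsFit(X[tr, , drop = FALSE], y[tr], ncomp = ncomp)
    pred <- plsPredict(fit, X[!tr, , drop = FALSE])
    press <- press + sum((pred - y[!tr])^2)
  }
  sqrt(press / n)
}
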