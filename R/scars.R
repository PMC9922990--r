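#' SCARS configuration
#'
#' Tuning constants of the stability competitive adaptive re-weighted
#' sampling selector: number of sampling cycles, Monte-Carlo subsampling
#' used to estimate coefficient stability, the cross-validation measuring
#' each cycle's retained subset, and the inner PLS size.
#'
#' @param n_runs number of sampling cycles N. Default 50.
#' @param subsample_fraction fraction of calibration samples per Monte-Carlo
#'   draw. Default 0.8.
#' @param n_subsamples draws B per cycle for the stability estimate.
#'   Default 30.
#' @param cv_folds folds K for the per-cycle RMSECV. Default 5.
#' @param ncomp latent variables of the inner PLS regressor (capped at the
#'   data rank per fit). Default 10.
#' @param stability_epsilon guard added to the coefficient sd so constant
#'   coefficients get stability 0 instead of 0/0. Default 1e-12.
#' @param n_repeats independent repetitions of the whole procedure; the
#'   repetition with the smallest best-cycle RMSECV is kept. Default 1.
#' @param seed integer seed for the subsampling and re-weighted draws.
#' @return list of class \code{ScarsConfig}.
#' @export
scarsConfig <- function(n_runs = 50L, subsample_fraction = 0.8,
                        n_subsamples = 30L, cv_folds = 5L, ncomp = 10L,
                        stability_epsilon = 1e-12, n_repeats = 1L,
                        seed = 1L) {
  stopifnot(n_runs >= 2L, subsample_fraction > 0, subsample_fraction < 1,
            n_subsamples >= 2L, cv_folds >= 2L, ncomp >= 1L,
            stability_epsilon > 0, n_repeats >= 1L)
  structure(list(n_runs = as.integer(n_runs),
                 subsample_fraction = subsample_fraction,
                 n_subsamples = as.integer(n_subsamples),
                 cv_folds = as.integer(cv_folds), ncomp = as.integer(ncomp),
                 stability_epsilon = stability_epsilon,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "ScarsConfig")
}

#' Exponentially decreasing retention schedule
#'
#' Fraction of the initial p variables kept at cycle i of N:
#' \eqn{r_i = a e^{-k i}} with \eqn{k = \ln(p/2)/(N-1)} and \eqn{a = e^k},
#' calibrated so all variables survive the first cycle
#' (\eqn{r_1 = 1}) and exactly two the last (\eqn{r_N = 2/p}).
#'
#' @param i cycle index, 1..N.
#' @param N total cycles.
#' @param p initial variable count, >= 2.
#' @return retention fraction in (0, 1].
#' @examples
#' edfRatio(1, 50, 264)   # 1
#' edfRatio(50, 50, 264)  # 2/264
#' @export
edfRatio <- function(i, N, p) {
  if (p < 2) stop("need at least two initial variables")
  stopifnot(all(i >= 1), all(i <= N), N >= 2)
  k <- log(p / 2) / (N - 1)
  exp(k) * exp(-k * i)
}

#' Coefficient-stability scores of the retained variables
#'
#' Draws B subsamples of the calibration set without replacement, fits the
#' inner PLS regressor on each, and scores variable j by
#' \eqn{s_j = |\mathrm{mean}_b(\beta_{jb})| / (\mathrm{sd}_b(\beta_{jb}) +
#' \epsilon)}: variables whose coefficients are large and reproducible
#' across subsamples score high. Uses the current RNG state (seeded by
#' [scarsSelect()]).
#'
#' @param X calibration matrix restricted to the retained variables (>= 2
#'   columns).
#' @param y calibration response.
#' @param config a [scarsConfig()].
#' @return numeric vector of stabilities, one per column of X.
#' @export
scarsStability <- function(X, y, config = scarsConfig()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(ncol(X) >= 2L, length(y) == n)
  m <- ceiling(config$subsample_fraction * n)
  if (m < 2L) stop("subsample too small for the inner fit")
  B <- config$n_subsamples
  coefs <- matrix(NA_real_, B, ncol(X))
  b <- 1L; attempts <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B)
      stop("could not draw a non-degenerate subsample (constant response?)")
    idx <- sample.int(n, m)
    if (var(y[idx]) == 0) next
    fit <- plsFit(X[idx, , drop = FALSE], y[idx], ncomp = config$ncomp)
    coefs[b, ] <- fit$coef
    b <- b + 1L
  }
  mu <- colMeans(coefs)
  s <- apply(coefs, 2L, sd)
  abs(mu) / (s + config$stability_epsilon)
}

#' Stability competitive adaptive re-weighted sampling (SCARS)
#'
#' Iterative band selection for spectra. Each cycle (i of N): (1) stability
#' scores of the currently retained variables are estimated by Monte-Carlo
#' subsampling; (2) forced selection keeps the top \eqn{\lceil r_i p\rceil}
#' variables by stability ([edfRatio()] schedule); (3) adaptive re-weighted
#' sampling draws p times with replacement among the kept variables, with
#' probability proportional to stability, and retains the distinct draws
#' (a stochastic perturbation of the schedule); (4) the
#' retained subset is scored by K-fold RMSECV of the inner PLS regressor.
#' The cycle with minimal RMSECV (earliest on ties) defines the selected
#' frequency bands. The prediction set is never seen: selection runs on
#' calibration data only.
#'
#' @param X_cal calibration samples x frequencies matrix.
#' @param y_cal calibration moisture (\%).
#' @param grid the [FrequencyGrid-class] labelling the columns.
#' @param config a [scarsConfig()].
#' @return object of class \code{ScarsResult}: \code{retained_sets} (per-run
#'   integer column sets), \code{forced_sizes} (post-forced-selection counts,
#'   non-increasing), \code{rmsecv}, \code{stability_trace}, \code{best_run},
#'   \code{selected_vars} (column indices of the best run),
#'   \code{selected_frequencies} (THz), \code{n_runs_done}, \code{config}.
#' @export
scarsSelect <- function(X_cal, y_cal, grid, config = scarsConfig()) {
  X_cal <- as.matrix(X_cal)
  p0 <- ncol(X_cal)
  stopifnot(p0 == length(grid), nrow(X_cal) == length(y_cal))
  if (p0 < 2L) stop("need at least two initial variables")
  if (nrow(X_cal) < config$cv_folds)
    stop("fewer calibration samples than CV folds")
  runOnce <- function() {
    retained <- seq_len(p0)
    N <- config$n_runs
    sets <- vector("list", N)
    forced_sizes <- integer(N)
    rmsecv <- rep(NA_real_, N)
    stab_trace <- vector("list", N)
    done <- 0L
    for (i in seq_len(N)) {
      stab <- scarsStability(X_cal[, retained, drop = FALSE], y_cal, config)
      stab_trace[[i]] <- setNames(stab, retained)
      n_keep <- min(ceiling(edfRatio(i, N, p0) * p0), length(retained))
      ord <- order(-stab, retained)
      forced <- retained[ord[seq_len(n_keep)]]
      forced_stab <- stab[ord[seq_len(n_keep)]]
      forced_sizes[i] <- n_keep
      prob <- if (sum(forced_stab) > 0) forced_stab else NULL
      # p0 draws (not n_keep): with many draws the duplicate-removal step
      # perturbs rather than drives the shrinkage, which the EDF schedule owns
      draw <- sample(forced, size = p0, replace = TRUE, prob = prob)
      retained <- sort(unique(draw))
      done <- i
      if (length(retained) < 2L) {
        sets[[i]] <- retained
        break
      }
      sets[[i]] <- retained
      rmsecv[i] <- .plsRmsecv(X_cal[, retained, drop = FALSE], y_cal,
                              folds = config$cv_folds, ncomp = config$ncomp)
    }
    best <- which.min(rmsecv[seq_len(done)])
    structure(list(
      retained_sets = sets[seq_len(done)],
      forced_sizes = forced_sizes[seq_len(done)],
      rmsecv = rmsecv[seq_len(done)],
      stability_trace = stab_trace[seq_len(done)],
      best_run = best, selected_vars = sets[[best]],
      selected_frequencies = freqPoints(grid)[sets[[best]]],
      n_runs_done = done, config = config), class = "ScarsResult")
  }
  .withSeed(config$seed, {
    best_res <- NULL
    for (r in seq_len(config$n_repeats)) {
      res <- runOnce()
      if (is.null(best_res) ||
          res$rmsecv[res$best_run] < best_res$rmsecv[best_res$best_run])
        best_res <- res
    }
    best_res
  })
}

#' @export
print.ScarsResult <- function(x, ...) {
  cat(sprintf(
    "ScarsResult: best run %d of %d, %d variables, RMSECV %.4f\n",
    x$best_run, x$n_runs_done, length(x$selected_vars),
    x$rmsecv[x$best_run]))
  cat("  frequencies (THz):",
      paste(sprintf("%.2f", x$selected_frequencies), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate SCARS results per optical channel
#'
#' One row per channel: the winning cycle, how many bands it retained, its
#' RMSECV, and the selected frequencies (ascending, 2-decimal THz).
#'
#' @param results named list of \code{ScarsResult} objects (names = optical
#'   channels).
#' @param grid the shared [FrequencyGrid-class] (used for validation only;
#'   each result already carries its frequencies).
#' @return data.frame: dimension, times, select, minRMSECV,
#'   frequency_points, degenerate.
#' @export
selectionReport <- function(results, grid = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    degen <- length(r$selected_vars) < 2L || !is.finite(r$rmsecv[r$best_run])
    data.frame(
      dimension = nm,
      times = r$best_run,
      select = length(r$selected_vars),
      minRMSECV = r$rmsecv[r$best_run],
      frequency_points = paste(
        sprintf("%.2f", sort(r$selected_frequencies)), collapse = ", "),
      degenerate = degen, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
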