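#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles every stage's parameters. A single integer \code{seed} is
#' mandatory and drives all stochastic stages (simulation, SCARS
#' subsampling); sub-seeds are derived from it deterministically, so two
#' runs with the same config are identical.
#'
#' @param seed integer master seed (required).
#' @param sim a [simConfig()]; its own seed is overridden by \code{seed}.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param sg_candidates window widths compared in the preprocessing report.
#' @param split_method \code{"SPXY"} or \code{"KS"} for the shared modeling
#'   split.
#' @param split_ratio calibration fraction. Default 0.75 (3:1).
#' @param scars a [scarsConfig()]; per-channel seeds derived from
#'   \code{seed}.
#' @param pca_threshold cumulative-contribution cutoff. Default 0.95.
#' @param svr_grid SVR search grid. Default [defaultSvrGrid()].
#' @param svr_folds folds of the SVR search. Default 5.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed, sim = simConfig(),
                           sg_window = 5L, sg_polyorder = 2L,
                           sg_candidates = c(5L, 7L, 9L, 11L),
                           split_method = c("SPXY", "KS"),
                           split_ratio = 0.75,
                           scars = scarsConfig(),
                           pca_threshold = 0.95,
                           svr_grid = defaultSvrGrid(), svr_folds = 5L) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an integer 'seed' is required for the stochastic stages")
  split_method <- match.arg(split_method)
  stopifnot(inherits(sim, "SimConfig"), inherits(scars, "ScarsConfig"),
            split_ratio > 0, split_ratio < 1)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_candidates = as.integer(sg_candidates),
                 split_method = split_method, split_ratio = split_ratio,
                 scars = scars, pca_threshold = pca_threshold,
                 svr_grid = svr_grid, svr_folds = as.integer(svr_folds)),
            class = "PipelineConfig")
}

# md5 of an R object via a temporary serialized file
.hashObject <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

#' Run the full moisture-modeling pipeline
#'
#' Executes simulate (or take supplied data) -> Savitzky-Golay smoothing ->
#' shared SPXY (or KS) calibration/prediction split -> SCARS band selection
#' per optical channel -> per-channel MLR -> feature fusion ->
#' normalization -> PCA -> grid-searched RBF-SVR, and returns a manifest of
#' every table plus content hashes. The shared split is computed on the
#' per-channel z-scored, concatenated smoothed spectra so all models are
#' compared on identical calibration/prediction sets.
#'
#' @param config a [pipelineConfig()].
#' @param data optional [THzSpectra-class] to analyse instead of simulating.
#' @return list of class \code{PipelineResult}: \code{manifest} (seeds,
#'   parameters, hashes, versions), \code{tables} (sg_window,
#'   split_comparison, band_selection, single_dimension, pca_contributions,
#'   fusion_metrics), \code{split}, \code{scars}, \code{mlr_models},
#'   \code{fusion_model}, \code{evaluation}, \code{data} (the smoothed
#'   spectra).
#' @export
runPipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(data)) data <- simulateDataset(config$sim)
  stopifnot(is(data, "THzSpectra"))
  grid <- frequencyGrid(data)
  y <- moisture(data)

  smoothed <- smoothSpectra(data, config$sg_window, config$sg_polyorder)
  chans <- SummarizedExperiment::assayNames(smoothed)
  mats <- lapply(chans, function(nm) spectraMatrix(smoothed, nm))
  names(mats) <- chans

  # preprocessing report: window-width study on the power channel
  sg_tab <- selectSgWindow(spectraMatrix(data, "power"), y,
                           candidates = config$sg_candidates,
                           polyorder = config$sg_polyorder)

  split_tab <- compareSplitMethods(mats, y, ratio = config$split_ratio)

  # shared modeling split on the z-scored concatenation of all channels
  zscore <- function(m) {
    s <- apply(m, 2L, sd); s[s == 0] <- 1
    sweep(sweep(m, 2L, colMeans(m)), 2L, s, "/")
  }
  Xall <- do.call(cbind, lapply(mats, zscore))
  n_cal <- roundHalfUp(config$split_ratio * nrow(Xall))
  split <- if (config$split_method == "SPXY") {
    spxySplit(Xall, y, n_cal)
  } else ksSplit(Xall, n_cal)
  cal <- split$calibration

  scars <- list()
  for (j in seq_along(chans)) {
    cfg <- config$scars
    cfg$seed <- config$seed + 1000L * j
    scars[[chans[j]]] <- scarsSelect(mats[[chans[j]]][cal, , drop = FALSE],
                                     y[cal], grid, cfg)
  }
  band_tab <- selectionReport(scars, grid)

  bandMats <- lapply(chans, function(nm)
    mats[[nm]][, scars[[nm]]$selected_vars, drop = FALSE])
  names(bandMats) <- chans
  single <- singleDimensionReport(bandMats, y, split)

  bands <- lapply(scars, function(r) r$selected_frequencies)
  fused <- fuseFeatures(bands, mats, grid)
  fusion <- fitFusionModel(fused, y, split, threshold = config$pca_threshold,
                           svr_grid = config$svr_grid,
                           cv_folds = config$svr_folds)
  ev <- fusionEvaluate(fusion, fused, y)

  pca_tab <- data.frame(component = seq_along(fusion$pca$contributions),
                        contribution = fusion$pca$contributions,
                        cumulative = fusion$pca$cumulative)
  fmetrics <- data.frame(
    model = c(chans, "fusion"),
    Rc = c(unlist(single$table["Rc", ]), ev$calibration$r),
    RMSEC = c(unlist(single$table["RMSEC", ]), ev$calibration$rmse),
    Rp = c(unlist(single$table["Rp", ]), ev$prediction$r),
    RMSEP = c(unlist(single$table["RMSEP", ]), ev$prediction$rmse))
  rownames(fmetrics) <- NULL

  tables <- list(sg_window = sg_tab$table, split_comparison = split_tab,
                 band_selection = band_tab,
                 single_dimension = single$table,
                 pca_contributions = pca_tab, fusion_metrics = fmetrics)
  manifest <- list(
    seed = config$seed,
    parameters = list(
      sg_window = sg_tab$window, sg_polyorder = config$sg_polyorder,
      split_method = config$split_method, split_ratio = config$split_ratio,
      n_cal = n_cal, scars_runs = config$scars$n_runs,
      pca_threshold = config$pca_threshold, pca_k = fusion$pca$k,
      svr = as.list(fusion$svr$best[c("gamma", "cost", "epsilon")])),
    hashes = list(data = .hashObject(lapply(chans, function(nm)
                    spectraMatrix(data, nm))),
                  split = .hashObject(split[c("calibration", "prediction")]),
                  bands = .hashObject(bands),
                  tables = .hashObject(tables)),
    versions = list(package = as.character(utils::packageVersion("thzwater")),
                    r = paste(R.version$major, R.version$minor, sep = ".")))
  structure(list(manifest = manifest, tables = tables, split = split,
                 scars = scars, mlr_models = single$models,
                 fusion_model = fusion, evaluation = ev, data = smoothed),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult (seed", x$manifest$seed, ")\n")
  cat("  fused bands:", nrow(x$fusion_model$feature_labels),
      "-> PCs:", x$fusion_model$pca$k, "\n")
  print(x$tables$fusion_metrics, digits = 4)
  invisible(x)
}
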