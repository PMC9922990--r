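# Naive O(n^3) max-min split oracle: literal restatement of the
# Kennard-Stone recursion, recomputing every candidate's minimum distance to
# the selected set from scratch at each step. Ties: lowest index.
naiveMaxMin <- function(D, n_cal) {
  n <- nrow(D)
  best <- c(1L, 2L)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (D[i, j] > D[best[1L], best[2L]]) best <- c(i, j)
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(c_) min(D[c_, sel]), numeric(1L))
    sel <- c(sel, cand[which.max(score)])
  }
  list(calibration = sel, prediction = setdiff(seq_len(n), sel))
}

naiveKs <- function(X, n_cal) {
  naiveMaxMin(as.matrix(stats::dist(X)), n_cal)
}

naiveSpxy <- function(X, y, n_cal) {
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  naiveMaxMin(dx / max(dx) + dy / max(dy), n_cal)
}

# Memoized expensive fixtures shared across test files.
.thz_cache <- new.env(parent = emptyenv())

cachedDataset <- function(seed = 42L) {
  key <- paste0("data_", seed)
  if (is.null(.thz_cache[[key]]))
    .thz_cache[[key]] <- simulateDataset(simConfig(seed = seed))
  .thz_cache[[key]]
}

cachedPipeline <- function(seed) {
  key <- paste0("pipe_", seed)
  if (is.null(.thz_cache[[key]]))
    .thz_cache[[key]] <- runPipeline(pipelineConfig(seed = seed))
  .thz_cache[[key]]
}
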