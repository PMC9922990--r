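#' Configuration of the synthetic irrigation-stress experiment
#'
#' Describes the generative model used to emulate a greenhouse water-stress
#' trial: four irrigation levels (20/40/60/80\% of a standard dose), 20
#' leaves per level, 10 replicate scans per leaf averaged, and three optical
#' channels on a common 0.5--1.5 THz grid.
#'
#' The noiseless absorbance core of a leaf with dry-basis moisture \eqn{w}
#' (\%) is \eqn{A^*(f) = a_0(f) + \beta(f) w}, with affine \eqn{a_0} and
#' \eqn{\beta > 0} increasing in frequency, so wetter leaves absorb more and
#' absorbance grows with frequency. Measured absorbance adds two noise
#' tiers. Leaf-level effects, which replicate scanning cannot average away:
#' a multiplicative thickness factor \eqn{t_i \sim N(1, \sigma_t)} on the
#' core (optical path length varies leaf to leaf) and an additive baseline
#' offset and tilt. Scan-level effects, reduced by the replicate average: a
#' per-scan common-mode offset plus small independent per-frequency noise.
#' Transmittance is \eqn{10^{-A}} of the averaged absorbance. Detected
#' power is an affine gain \eqn{c_0 + c_1 w/100} (with its own leaf- and
#' scan-level gain noise) on a smooth reference spectrum, reproducing the
#' positive power--moisture association seen on this class of instrument
#' even though a purely attenuative channel would predict the opposite
#' (\code{physical_power = TRUE} switches to power = reference x T).
#'
#' @param n_levels number of irrigation-stress levels.
#' @param irrigation_fractions fraction of the standard irrigation dose per
#'   level.
#' @param leaves_per_level leaves sampled per level.
#' @param scans_per_leaf replicate scans averaged per leaf.
#' @param grid [FrequencyGrid-class] for all channels.
#' @param moisture_means per-level mean dry-basis moisture (\%), strictly
#'   increasing with irrigation.
#' @param moisture_sd within-level moisture standard deviation (\%).
#' @param baseline_absorbance c(intercept, slope): \eqn{a_0(f) =}
#'   intercept + slope (f - 0.5).
#' @param water_coefficient c(intercept, slope): \eqn{\beta(f) =}
#'   intercept + slope (f - 0.5), absorbance units per moisture \%.
#' @param thickness_sd sd of the per-leaf multiplicative thickness factor.
#' @param baseline_offset_sd,baseline_tilt_sd sd of the per-leaf additive
#'   absorbance offset and tilt (per THz).
#' @param scan_offset_sd per-scan common-mode absorbance offset sd.
#' @param scan_noise_sd per-scan independent per-frequency absorbance noise
#'   sd.
#' @param power_gain c(c0, c1): power gain = c0 + c1 w/100, c1 > 0.
#' @param power_leaf_sd per-leaf power gain noise sd.
#' @param power_noise_sd per-scan power gain noise sd.
#' @param power_freq_noise_sd per-scan relative sd of independent
#'   per-frequency power noise (detector noise after the FFT).
#' @param reference c(amplitude, decay): background power
#'   amplitude * exp(-decay (f - 0.5)).
#' @param planted_bands NULL for the smooth model, or integer column indices
#'   (or a list \code{list(freqs = <THz>)}) marking the only frequencies
#'   that carry moisture signal. In this mode the common-mode leaf and scan
#'   effects are disabled, so every off-support absorbance column is
#'   exchangeable noise around its baseline — the known ground truth for
#'   band-selection tests.
#' @param planted_beta \eqn{\beta} at the planted frequencies.
#' @param physical_power if TRUE, power = reference x transmittance instead
#'   of the affine-gain model.
#' @param seed integer seed; [simulateDataset()] is bit-reproducible given
#'   it.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_levels = 4L,
                      irrigation_fractions = c(0.2, 0.4, 0.6, 0.8),
                      leaves_per_level = 20L,
                      scans_per_leaf = 10L,
                      grid = frequencyGrid(),
                      moisture_means = c(120, 180, 240, 300),
                      moisture_sd = 15,
                      baseline_absorbance = c(0.10, 0.30),
                      water_coefficient = c(0.002, 0.002),
                      thickness_sd = 0.05,
                      baseline_offset_sd = 0.03,
                      baseline_tilt_sd = 0.03,
                      scan_offset_sd = 0.03,
                      scan_noise_sd = 0.01,
                      power_gain = c(0.20, 0.25),
                      power_leaf_sd = 0.02,
                      power_noise_sd = 0.02,
                      power_freq_noise_sd = 0.01,
                      reference = c(1000, 1.5),
                      planted_bands = NULL,
                      planted_beta = 0.003,
                      physical_power = FALSE,
                      seed = 1L) {
  stopifnot(n_levels >= 1L, length(irrigation_fractions) == n_levels,
            length(moisture_means) == n_levels,
            leaves_per_level >= 1L, scans_per_leaf >= 1L,
            is(grid, "FrequencyGrid"), moisture_sd >= 0,
            thickness_sd >= 0, baseline_offset_sd >= 0,
            baseline_tilt_sd >= 0, scan_offset_sd >= 0, scan_noise_sd >= 0,
            power_leaf_sd >= 0, power_noise_sd >= 0,
            power_freq_noise_sd >= 0,
            length(baseline_absorbance) == 2L,
            length(water_coefficient) == 2L,
            length(power_gain) == 2L, length(reference) == 2L,
            reference[1L] > 0)
  if (n_levels > 1L && any(diff(moisture_means) <= 0))
    stop("moisture_means must be strictly increasing with irrigation")
  if (is.null(planted_bands)) {
    if (water_coefficient[1L] <= 0 || water_coefficient[2L] < 0)
      stop("water_coefficient must keep beta(f) > 0 and non-decreasing in f")
  } else {
    if (is.list(planted_bands))
      planted_bands <- matchFrequencies(planted_bands$freqs, grid)
    planted_bands <- sort(unique(as.integer(planted_bands)))
    stopifnot(all(planted_bands >= 1L), all(planted_bands <= length(grid)),
              planted_beta > 0)
  }
  if (power_gain[2L] <= 0)
    stop("power gain slope c1 must be positive (power rises with moisture)")
  if (!is.null(planted_bands)) {
    # planted mode promises off-support columns that are exchangeable noise:
    # common-mode leaf/scan effects would correlate them, so they are off
    thickness_sd <- 0; baseline_offset_sd <- 0
    baseline_tilt_sd <- 0; scan_offset_sd <- 0
  }
  structure(list(
    n_levels = as.integer(n_levels),
    irrigation_fractions = irrigation_fractions,
    leaves_per_level = as.integer(leaves_per_level),
    scans_per_leaf = as.integer(scans_per_leaf),
    grid = grid, moisture_means = moisture_means, moisture_sd = moisture_sd,
    baseline_absorbance = baseline_absorbance,
    water_coefficient = water_coefficient,
    thickness_sd = thickness_sd,
    baseline_offset_sd = baseline_offset_sd,
    baseline_tilt_sd = baseline_tilt_sd,
    scan_offset_sd = scan_offset_sd, scan_noise_sd = scan_noise_sd,
    power_gain = power_gain, power_leaf_sd = power_leaf_sd,
    power_noise_sd = power_noise_sd,
    power_freq_noise_sd = power_freq_noise_sd, reference = reference,
    planted_bands = planted_bands, planted_beta = planted_beta,
    physical_power = isTRUE(physical_power), seed = as.integer(seed)),
    class = "SimConfig")
}

#' Zero-noise variant of a configuration
#'
#' Sets every noise sd of a [simConfig()] to zero, keeping the
#' deterministic core; handy for exactness tests.
#'
#' @param config a [simConfig()].
#' @return the modified config.
#' @export
noiselessConfig <- function(config) {
  for (nm in c("moisture_sd", "thickness_sd", "baseline_offset_sd",
               "baseline_tilt_sd", "scan_offset_sd", "scan_noise_sd",
               "power_leaf_sd", "power_noise_sd", "power_freq_noise_sd"))
    config[[nm]] <- 0
  config
}

.affine <- function(coefs, f) coefs[1L] + coefs[2L] * (f - 0.5)

#' Per-frequency generative coefficients of a SimConfig
#'
#' @param config a [simConfig()] object.
#' @return list with \code{a0}, \code{beta}, \code{reference} vectors on the
#'   config grid; in planted-band mode \code{beta} is zero off the planted
#'   columns.
#' @export
simCoefficients <- function(config) {
  f <- freqPoints(config$grid)
  a0 <- .affine(config$baseline_absorbance, f)
  if (is.null(config$planted_bands)) {
    beta <- .affine(config$water_coefficient, f)
  } else {
    beta <- numeric(length(f))
    beta[config$planted_bands] <- config$planted_beta
  }
  ref <- config$reference[1L] * exp(-config$reference[2L] * (f - 0.5))
  list(a0 = a0, beta = beta, reference = ref)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw per-leaf moisture records for one stress level
#'
#' Dry-basis moisture w is Normal(mean, sd) truncated below at 0 (redrawn),
#' dry mass m2 is Uniform(0.5, 2) g, and fresh mass is reconstructed as
#' m1 = m2 (1 + w/100) so that the gravimetric formula
#' w = (m1 - m2)/m2 x 100 inverts the draw exactly. Uses the current RNG
#' state; seed at the dataset level via [simulateDataset()].
#'
#' @param config a [simConfig()].
#' @param level stress level index (1-based).
#' @param n number of leaves.
#' @return data.frame with stress_level, m1_g, m2_g, moisture_pct.
#' @export
drawMoisture <- function(config, level, n = config$leaves_per_level) {
  stopifnot(level >= 1L, level <= config$n_levels, n >= 1L)
  mu <- config$moisture_means[level]
  w <- rnorm(n, mu, config$moisture_sd)
  for (k in seq_len(100L)) {
    bad <- w < 0
    if (!any(bad)) break
    w[bad] <- rnorm(sum(bad), mu, config$moisture_sd)
  }
  w[w < 0] <- 0
  m2 <- runif(n, 0.5, 2.0)
  m1 <- m2 * (1 + w / 100)
  data.frame(stress_level = level, m1_g = m1, m2_g = m2, moisture_pct = w)
}

#' Simulate the three optical channels for one leaf
#'
#' Draws the leaf-level effects (thickness factor, baseline offset and
#' tilt, power gain noise), builds the noiseless absorbance core from the
#' config coefficients, adds per-scan common-mode and per-frequency noise
#' for \code{scans_per_leaf} replicate scans, averages them, floors any
#' negative averaged absorbance at zero (counted in attribute
#' \code{n_floored}), and derives transmittance and power.
#'
#' @param w dry-basis moisture (\%), >= 0.
#' @param config a [simConfig()].
#' @return list of numeric vectors \code{power}, \code{absorbance},
#'   \code{transmittance} on the config grid.
#' @export
simulateLeaf <- function(w, config) {
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0)
  co <- simCoefficients(config)
  f <- freqPoints(config$grid)
  nf <- length(f)
  k <- config$scans_per_leaf
  thick <- 1 + rnorm(1L, 0, config$thickness_sd)
  base_off <- rnorm(1L, 0, config$baseline_offset_sd)
  base_tilt <- rnorm(1L, 0, config$baseline_tilt_sd)
  Astar <- thick * (co$a0 + co$beta * w) + base_off + base_tilt * (f - 0.5)
  scan_off <- rnorm(k, 0, config$scan_offset_sd)
  noise <- matrix(rnorm(k * nf, 0, config$scan_noise_sd), nrow = k)
  A <- Astar + mean(scan_off) + colMeans(noise)
  n_floor <- sum(A < 0)
  if (n_floor > 0L) A[A < 0] <- 0
  Tm <- 10^(-A)
  gain_leaf <- rnorm(1L, 0, config$power_leaf_sd)
  gain_scan <- rnorm(k, 0, config$power_noise_sd)
  pfreq <- 1 + colMeans(matrix(rnorm(k * nf, 0, config$power_freq_noise_sd),
                               nrow = k))
  if (config$physical_power) {
    p <- co$reference * Tm * pmax(pfreq, 1e-6)
  } else {
    gain <- config$power_gain[1L] + config$power_gain[2L] * w / 100 +
      gain_leaf + mean(gain_scan)
    p <- co$reference * max(gain, 1e-6) * pmax(pfreq, 1e-6)
  }
  structure(list(power = p, absorbance = A, transmittance = Tm),
            n_floored = n_floor)
}

#' Simulate a full irrigation-stress dataset
#'
#' Generates \code{n_levels x leaves_per_level} leaves (80 under defaults),
#' each averaged over replicate scans, and returns them as a
#' [THzSpectra-class] with assays \code{power}, \code{absorbance},
#' \code{transmittance} and per-sample labels \code{sample_id},
#' \code{stress_level}, \code{m1_g}, \code{m2_g}, \code{moisture_pct}.
#' Bit-reproducible for a given \code{config$seed}; the caller's RNG state
#' is left untouched.
#'
#' @param config a [simConfig()].
#' @return A [THzSpectra-class] object.
#' @examples
#' thz <- simulateDataset(simConfig(seed = 7))
#' dim(spectraMatrix(thz, "absorbance"))  # 80 x 264
#' @export
simulateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  nf <- length(config$grid)
  .withSeed(config$seed, {
    labs <- do.call(rbind, lapply(seq_len(config$n_levels), function(lv)
      drawMoisture(config, lv)))
    n <- nrow(labs)
    labs <- data.frame(
      sample_id = sprintf("L%d_%02d", labs$stress_level,
                          stats::ave(seq_len(n), labs$stress_level,
                                     FUN = seq_along)),
      labs, stringsAsFactors = FALSE)
    P <- A <- Tm <- matrix(NA_real_, n, nf)
    for (i in seq_len(n)) {
      leaf <- simulateLeaf(labs$moisture_pct[i], config)
      P[i, ] <- leaf$power; A[i, ] <- leaf$absorbance
      Tm[i, ] <- leaf$transmittance
    }
    rownames(P) <- rownames(A) <- rownames(Tm) <- labs$sample_id
    THzSpectra(list(power = P, absorbance = A, transmittance = Tm),
               grid = config$grid, sampleData = labs)
  })
}

#' Default planted-band configuration for selection benchmarks
#'
#' Convenience wrapper: the smooth water coefficient is replaced by signal
#' at 6 of the 264 default frequencies (spread across the window), giving a
#' known support against which band-selection recovery is scored.
#'
#' @param seed integer seed.
#' @param n_bands number of informative frequencies.
#' @param scan_noise_sd per-scan absorbance noise of the benchmark; the
#'   default 0.05 leaves a per-variable noise sd of about 0.016 after the
#'   10-scan average, against a planted signal spread of about 0.2.
#' @param ... further arguments to [simConfig()].
#' @return list with \code{config} and the planted column indices
#'   \code{bands}.
#' @export
plantedBandConfig <- function(seed = 1L, n_bands = 6L, scan_noise_sd = 0.05,
                              ...) {
  grid <- frequencyGrid()
  idx <- round(seq(20L, length(grid) - 20L, length.out = n_bands))
  cfg <- simConfig(planted_bands = idx, seed = seed, grid = grid,
                   scan_noise_sd = scan_noise_sd, ...)
  list(config = cfg, bands = cfg$planted_bands)
}
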