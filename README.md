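# thzwater

Terahertz spectral chemometrics for leaf water content.

Water is by far the strongest absorber of terahertz radiation in plant
tissue, which makes THz time-domain spectroscopy a sensitive, non-destructive
probe of leaf water status. `thzwater` implements a complete chemometric
pipeline for estimating dry-basis leaf moisture content from three optical
channels of a THz transmission measurement — detected **power**,
**absorbance** and **transmittance** — on a common 0.5–1.5 THz grid:

1. **Container** — `THzSpectra`, an S4 class extending
   `SummarizedExperiment`: rows are frequency points, columns are leaf
   samples, assays are the optical channels, and per-sample gravimetric
   labels (fresh mass, dry mass, moisture %) live in `colData`.
2. **Preprocessing** — Savitzky–Golay smoothing (`sgSmooth`,
   `smoothSpectra`) with a window-width study (`selectSgWindow`) over
   widths 5/7/9/11.
3. **Sample partitioning** — deterministic Kennard–Stone (`ksSplit`) and
   SPXY (`spxySplit`) max-min splits at the conventional 3:1
   calibration:prediction ratio, plus a comparison report
   (`compareSplitMethods`).
4. **Band selection** — stability competitive adaptive re-weighted sampling
   (`scarsSelect`): variables are scored by the stability of their PLS
   coefficients over Monte-Carlo subsamples, the retained set shrinks along
   an exponentially decreasing schedule (`edfRatio`), and the cycle with
   minimal cross-validated error defines the selected bands.
5. **Single-channel models** — multiple linear regression on each channel's
   selected bands (`mlrFit`, `singleDimensionReport`), reported as
   Rc/RMSEC on the calibration set and Rp/RMSEP on the prediction set.
6. **Fusion model** — the selected bands of all three channels are
   concatenated (`fuseFeatures`), z-score normalized, reduced by PCA at a
   95% cumulative-contribution threshold and modeled with a grid-searched
   RBF ε-SVR (`fitFusionModel`). Every transformation is fitted on
   calibration samples only.
7. **Synthetic data** — `simulateDataset` emulates a four-level
   irrigation-stress experiment (20 leaves per level, 10 replicate scans
   averaged) with a two-tier noise model (leaf-level thickness/baseline
   effects plus scan-level noise), so the entire pipeline is testable end
   to end without instrument data. A `planted_bands` mode provides an exact
   ground truth for band-selection benchmarks.

## Worked example

```r
library(thzwater)

thz <- simulateDataset(simConfig(seed = 1))
thz
#> THzSpectra: 80 samples x 264 frequencies
#>   channels: power, absorbance, transmittance
#> FrequencyGrid: 264 points, 0.5000-1.4994 THz, step 0.0038 THz
#>   labels: sample_id, stress_level, m1_g, m2_g, moisture_pct

res <- runPipeline(pipelineConfig(seed = 1))
res
#> PipelineResult (seed 1 )
#>   fused bands: 104 -> PCs: 1
#>           model     Rc  RMSEC     Rp RMSEP
#> 1         power 0.9998  1.225 0.9862 11.85
#> 2    absorbance 0.9996  1.935 0.9154 27.59
#> 3 transmittance 0.9949  6.641 0.8977 30.73
#> 4        fusion 0.9843 11.711 0.9899 10.13

res$tables$band_selection[, c("dimension", "times", "select", "minRMSECV")]
#>       dimension times select minRMSECV
#> 1         power    16     42  4.833540
#> 2    absorbance    16     42  5.653768
#> 3 transmittance    27     20  9.977832

res$tables$sg_window
#>   window        Rc     RMSEC
#> 1      5 0.9999795 0.4472399
#> 2      7 0.9999294 0.8307087
#> 3      9 0.9998723 1.1173227
#> 4     11 0.9998314 1.2841276

res$fusion_model
#> FusionModel: 104 fused bands -> 1 PCs (cum. 0.9628) -> RBF-SVR (g=0.0625, C=64, p=0.1)
```

On this synthetic dataset the fused model's prediction-set correlation
(Rp = 0.9899) exceeds the best single-channel MLR (power, Rp = 0.9862) and
its RMSEP is the lowest of the four models — the qualitative result the
fusion architecture is designed for. Because all three channels carry the
same moisture signal, one principal component already holds 96% of the
fused variance here; on measured spectra with more heterogeneous channels
the retained count is typically larger.

The run is fully deterministic: `runPipeline` derives every stochastic
stage's seed from the single mandatory `seed`, and `res$manifest` records
parameters plus MD5 content hashes of the data, the split, the selected
bands and all report tables. Two runs with the same config produce
identical manifests.

## Reproduction

- **Tests** (includes oracle checks against naive re-implementations,
  a `mixOmics` PLS cross-check, planted-band recovery of the selector and
  the fusion-beats-single-channel benchmark over 10 seeds):

  ```sh
  Rscript -e 'testthat::test_dir("tests/testthat", package = "thzwater", load_package = "installed")'
  ```

- **Acceptance target** — the component-selection contract on the
  reference PCA contribution profile:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  # t1 = 7 components (cumulative 0.9519) -> results/acceptance.json
  ```

  writes `{"t1":{"value":7,"n":8}}`: the smallest number of principal
  components whose cumulative contribution reaches the 95% threshold.

- **Methods vignette** — `vignettes/thz-moisture-pipeline.Rmd` documents
  the generative model, every algorithmic choice and the design decisions
  (shared split, re-weighted sampling draw count, tie-breaking rules) in
  detail.
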