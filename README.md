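# fuseval

Pansharpening and fusion-quality evaluation for very-high-resolution
multispectral imagery, aimed at ecological remote sensing of vegetated,
coastal and mixed land/water ecosystems.

Pansharpening fuses a low-resolution multispectral image (MS, here the
8-band WorldView-2 layout at 1.84 m) with a co-registered panchromatic
band (PAN, 0.46 m, spanning 450–800 nm and therefore covering MS bands
2–6 only) to produce all MS bands at the PAN grid. Which algorithm gives
the best product depends on the scene: smooth water-dominated scenes
favour simple substitution methods, heterogeneous shrublands favour
spatially adaptive injection. `fuseval` packages the pieces needed to
make that comparison reproducible:

- **Four fusion algorithms** — fast intensity-hue-saturation (FIHS,
  additive injection of `PAN − I` with `I` the band mean), hyperspherical
  colour sharpening (HCS, replaces the band-vector radius by a PAN-derived
  intensity, preserving all band ratios), MTF-matched generalized
  Laplacian pyramid with high-pass modulation (MTF_GLP_HPM,
  `FUSᵢ = MSᵢ · PAN / PAN_low`), and the weighted wavelet *à trous*
  method driven by fractal dimension maps (WAT⊗FRAC,
  `FUSᵢ = MSᵢ + αᵢ(x,y) · Σ W_PAN` with `αᵢ` a per-pixel differential
  box-counting dimension rescaled from [2,3] to [0,1]).
- **Six quality indices** — spectral: SAM (mean spectral angle, degrees)
  and spectral ERGAS `100 (h/l) √(mean((rmseᵢ/mean MSᵢ)²))`; spatial:
  spatial ERGAS against the PAN, FC (correlation of blockwise-DCT AC
  coefficients) and the Zhou index (correlation of Laplacian high-pass
  planes); global: the universal image quality index Q averaged over
  bands (Q8), per band subset (`all`, `in_pan` = bands 2–6,
  `out_pan` = bands 1, 7, 8) and as block quality maps.
- **Borda-count ranking** — per-index points (best of N items gets N,
  worst 1; explicit tie policies), summed over spectral, spatial and
  global index groupings to pick a per-scene winner.
- **A seeded synthetic scene generator** — shrubland, coastal and mixed
  archetypes painted at the PAN grid and degraded Wald-style (MTF blur,
  4:1 decimation, noise) so a true high-resolution reference exists and
  the whole pipeline is testable without commercial satellite data.

## Worked example

```r
library(fuseval)

scn   <- simulate_scene(scene_config("shrubland", ms_size = 64, seed = 1))
ms_up <- upsample_ms(scn$ms, ratio = 4)
fused <- fuse_wat_frac(ms_up, scn$pan, window = 7)
evaluate_fusion(scn$ms, scn$pan, fused) |>
  dplyr::select(subset, n_bands, sam_deg, ergas_spectral, fc, zhou, q)
#> # A tibble: 3 × 7
#>   subset  n_bands sam_deg ergas_spectral    fc  zhou     q
#>   <chr>     <int>   <dbl>          <dbl> <dbl> <dbl> <dbl>
#> 1 all           8   0.698          0.948 0.613 0.334 0.988
#> 2 in_pan        5   0.694          1.08  0.836 0.349 0.990
#> 3 out_pan       3   0.274          0.678 0.241 0.311 0.986
```

The report reads: the fused product deviates from the (upsampled)
original MS by a mean spectral angle of 0.7°, its relative global error
(ERGAS) is about 1, and its band-wise Q is 0.99 — near-perfect spectral
fidelity. The spatial indices show the in-PAN bands (2–6) inherit much
more PAN structure (FC 0.84) than the out-of-PAN bands (FC 0.24), the
expected pattern when the PAN physically covers only bands 2–6.

The full pipeline fuses with all four algorithms, evaluates all three
subsets, writes every artifact to a run directory and ranks the
algorithms:

```r
res <- run_pipeline(run_config(scene_config("shrubland", ms_size = 64), seed = 1))
res$ranks[res$ranks$grouping == "global", ]
#> # A tibble: 4 × 5
#>   grouping  rank algorithm   score tied
#>   <chr>    <int> <chr>       <dbl> <lgl>
#> 1 global       1 fihs           16 TRUE
#> 2 global       1 mtf_glp_hpm    16 TRUE
#> 3 global       3 hcs            15 FALSE
#> 4 global       4 wat_frac       13 FALSE
```

`autoplot()` methods exist for quality reports, Borda results and block
quality maps; `plot_ms_rgb()` renders band triplets. A thin command-line
wrapper with `simulate`, `fuse`, `evaluate`, `rank` and `run`
subcommands is installed under `inst/cli/fuseval.R`.

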