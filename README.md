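# spectac

Tools for studying how low-dose CT acquisition parameters — tube voltage (kVp)
and quality-reference mAs (QRM) — propagate into quantitative ¹⁷⁷Lu SPECT/CT
imaging. The package is aimed at medical physicists who want to evaluate
CT-based attenuation correction (CT-AC) without scanner time: every input is a
digital phantom, and every stage of the chain is an inspectable R function.

## The analysis chain

CT-AC converts a CT scan (Hounsfield units) into a map of linear attenuation
coefficients at the 208.4 keV ¹⁷⁷Lu γ emission. `spectac` implements and
connects:

* **Theoretical attenuation** — μ = ρ · Σᵢ wᵢ (μ/ρ)ᵢ(E) from packaged
  elemental mass-attenuation tables (log–log interpolated) and ICRU-44-style
  tissue compositions.
* **Digital phantoms** — a voxelised electron-density phantom (17
  tissue-equivalent inserts in an elliptical plastic-water body, 19 segments
  with air) and a NEMA-style quantification phantom with 1-mL/10-mL syringe
  sources inside four plastic attenuators.
* **CT emulation** — per-material ideal HU at an effective beam energy plus a
  setting-dependent noise model (voxel noise, per-acquisition HU drift,
  in-plane smoothing) and a CTDI_vol lookup.
* **Bilinear HU→μ conversion** — breakpoint at HU = 0, per-kVp bone slopes
  calibrated in-repo, trilinear resampling to the SPECT grid.
* **First-order Chang ACF** — per voxel,
  ACF = [ (1/M) Σₘ exp(−∫μ dl) ]⁻¹ over M in-plane rays, and the activity
  change ΔA[%] = (ACF_theoretical/ACF_measured − 1)·100.
* **Quantitative SPECT emulator** — attenuated parallel-beam projector,
  matched OSEM reconstruction (6 iterations × 6 subsets default), image
  calibration factor, and extended-VOI activity recovery.
* **μ-map noise chain** — eight 1000-voxel VOIs, per-repetition means, and
  COV = σ/μ over ten repetitions.

Results come back as tibbles with provenance columns (kVp, QRM, seed, config
hash); `tidy()`/`glance()` methods and `plot_*()`/`autoplot()` helpers cover
the common summaries.

## Worked example

```r
library(spectac)

theoretical_mu_table(material_registry()[c("water", "plastic_water",
                                           "lung_inhale", "adipose",
                                           "muscle", "ptfe")])
#> # A tibble: 6 × 3
#>   material      density_g_cm3 mu_cm1
#>   <chr>                 <dbl>  <dbl>
#> 1 water                 1     0.135
#> 2 plastic_water         1.04  0.137
#> 3 lung_inhale           0.204 0.0273
#> 4 adipose               0.96  0.129
#> 5 muscle                1.06  0.142
#> 6 ptfe                  2.18  0.255
```

The `mu_cm1` column is the theoretical linear attenuation coefficient at
208.4 keV: water sits at 0.135 cm⁻¹, the low-density lung-inhale insert at
0.027 cm⁻¹ (which is why small absolute μ errors turn into large relative ones
there), and PTFE — the bone surrogate — at 0.255 cm⁻¹.

```r
res <- run_experiment(experiment_config("noise_cov", seed = 1))
dplyr::select(res$noise, kvp, qrm, mu_mean, cov, ctdi_mgy)
#> # A tibble: 7 × 5
#>     kvp   qrm mu_mean     cov ctdi_mgy
#>   <int> <int>   <dbl>   <dbl>    <dbl>
#> 1    80    20   0.136 0.00319      0.9
#> 2    80    35   0.135 0.00529      1.6
#> 3    80    50   0.135 0.00371      2.3
#> 4   110    20   0.135 0.00244      1.5
#> 5   110    35   0.136 0.00321      2.6
#> 6   130    20   0.136 0.00260      2
#> 7   130    35   0.136 0.00295      3.6
```

Each row is one (kVp, QRM) combination: `mu_mean` is the grand mean of the
plastic-water μ-map over ten emulated repetitions (theoretical value
0.137 cm⁻¹ for the packaged surrogate), `cov` the coefficient of variation of
the repetition means (a single ten-repetition draw scatters around the
per-setting calibration anchors of 2.9–3.9 × 10⁻³), and `ctdi_mgy` the dose
fixture — dose rises almost fourfold from 80 kVp/20 mAs to 130 kVp/35 mAs
while the μ-map noise barely moves, which is the core trade-off the analysis
quantifies. `plot_noise_tradeoff(res$noise)` draws it.

See `vignettes/attenuation-correction-methods.Rmd` for the model assumptions,
numerical choices and limitations.

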