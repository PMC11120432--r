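# qmixture

Desk-scale simulation and evaluation of **combined morphologic +
quantitative knee MRI** based on interleaved, magnetization-prepared turbo
spin-echo (TSE) acquisitions. Interleaving TSE blocks with different T2 or
spin-lock (T1ρ) preparations inside one repetition time yields
co-registered clinical image contrasts *and* voxel-wise relaxation maps
from a single scan; this package lets methods researchers study that
design — contrast behavior, map accuracy, fat-saturation failure modes,
and the reader-study statistics used to evaluate it — without a scanner.

It provides, as composable tidyverse-style functions:

* **Digital knee phantoms** (`build_knee_phantom()`): femoral/tibial
  cartilage with depth-dependent T2/T1ρ (zonal stratification, surface >
  deep), synovial fluid, infrapatellar fat, bone marrow, menisci, muscle;
  label-derived circular ROI placement (`roi_from_label()`).
* **Signal simulation** (`simulate_stack()`): per-block steady-state
  two-compartment signals
  `S = (1-f)·S_w + f·κ·S_fat`, with
  `S_c = PD·(1-e^(-TR/T1))·e^(-TE_equiv/T2)·P_c` and preparation factor
  `P_c = e^(-τ/T2)` (T2-prep) or `e^(-TSL/T1ρ)` (spin-lock), plus Rician
  noise (`add_rician_noise()`). Presets ship for the two interleaved
  variants — MIX1 (TR 1200 ms, prep TE 0/50 ms) and MIX2 (TR 600 ms,
  TSL 0/25/50 ms at 500 Hz) — and four 2D/3D TSE references.
* **Relaxometry** (`reconstruct_map()`): two-point closed-form
  `t = τ/ln(s1/s2)` or log-linear least-squares mono-exponential fits,
  with diagnostics-based validity masking that reproduces the
  "maps are not meaningful in fatty tissue" behavior, and segmented
  region summaries (`summarize_region()`).
* **Image-quality metrics** (`compare_sequences()`): Weber contrast
  `(SI_t - SI_r)/SI_r`, signed CNR `(SI_a - SI_b)/√(σ_a² + σ_b²)`, and
  CV `σ/SI` on standardized label-derived ROIs (2.11 / 3.76 mm²).
* **Reader-study statistics**: paired sample-size estimation
  (`min_sample_size()`), ordinal 1–5 score simulation
  (`simulate_likert()`), a from-scratch **cumulative link mixed model**
  fitted by the Laplace approximation (`fit_clmm()`) with latent-scale
  estimated marginal means and Monte-Carlo Tukey-adjusted contrasts
  (`emm_and_tukey()`), and repeated-measures ANOVA with Tukey–Kramer
  post hoc tests (`rm_anova_tukey()`). `tidy()`/`glance()` methods and
  `autoplot()`/`plot_metrics()` cover the result types.

## Worked example

```r
library(qmixture)

ph    <- build_knee_phantom(phantom_config(), seed = 1)
stack <- simulate_stack(ph, "MIX1", noise_sigma = 0.005, seed = 1)
t2map <- reconstruct_map(stack, "T2")
summarize_region(t2map, ph, c("femoral_cartilage", "tibial_cartilage"))
#> # A tibble: 2 × 4
#>   region            mean_ms sd_ms n_voxels
#>   <chr>               <dbl> <dbl>    <int>
#> 1 femoral_cartilage    42.2  8.39     5679
#> 2 tibial_cartilage     41.0  8.05     4526
```

The fitted means recover the configured zonal truth (55→25 ms surface→deep,
mean ≈ 42 ms) from the noisy two-point reconstruction; the SD mostly
reflects the depth gradient, not noise.

```r
pd <- c("MIX1", "2D TSE PD-w FS", "3D TSE PD-w FS")
stacks <- lapply(pd, function(nm) simulate_stack(ph, nm, noise_sigma = 0.005, seed = 31))
compare_sequences(stacks, ph, "PD-w FS")[, 1:5]
#> # A tibble: 3 × 5
#>   sequence       weighting  weber   cnr     cv
#> 1 MIX1           PD-w FS   -0.662 -14.7 0.0205
#> 2 2D TSE PD-w FS PD-w FS   -0.695 -21.4 0.0102
#> 3 3D TSE PD-w FS PD-w FS   -0.655 -14.0 0.0220
```

Cartilage is darker than fluid on every PD-w FS image (negative Weber
contrast), and the long-TR 2D TSE reference shows the most negative value
— the longer TR recovers the long-T1 synovial fluid more completely.

```r
scores <- simulate_likert(seed = 8)       # 10 specimens x 3 readers x 22 structures
fit <- fit_clmm(scores)                   # random intercepts: structure, reader, specimen
emm_and_tukey(fit)$contrasts
#> # A tibble: 3 × 6
#>   contrast         estimate     se     z       p_raw     p_tukey
#> 1 MIXTURE - 2D TSE    0.506 0.100   5.05 0.000000453 0.000000453
#> 2 3D TSE - 2D TSE     0.287 0.0995  2.88 0.00393     0.0111
#> 3 3D TSE - MIXTURE   -0.219 0.0997 -2.19 0.0284      0.0733

min_sample_size(0.5, 0.4, 0.8, 0.01)
#> [1] 8
```

The simulated latent effects (0.5 and 0.25 on the logit scale) are
recovered within one standard error, and the paired sample-size formula
returns the study-design value of 8 specimens.

`run_pipeline(out_dir)` chains phantom → stacks → maps → metrics and
writes NIfTI/CSV/JSON artifacts with a hash manifest; reruns with the same
seed are bit-identical. A command-line wrapper with `phantom`, `simulate`,
`map`, `metrics`, `run`, `reader-sim` and `presets` subcommands lives at
`inst/cli/qmixture.R`.

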