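---
title: "Models and methods behind qmixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qmixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmixture)
```

`qmixture` is a desk-scale simulation and evaluation toolkit for combined
morphologic and quantitative knee MRI built on interleaved,
magnetization-prepared turbo spin-echo (TSE) acquisitions. Two or more TSE
blocks with different preparation modules are interleaved within one
repetition time, yielding intrinsically co-registered image contrasts from
which voxel-wise T2 or T1ρ maps are reconstructed by mono-exponential
fitting. This vignette documents the models, the tunable parameters, the
numerical conventions, and what the synthetic experiments can and cannot
show.

## The signal model

The simulator does not model k-space acquisition or echo-train dynamics.
Each voxel's steady-state magnitude in one block is the two-compartment
saturation-recovery surrogate

$$
S \;=\; (1-f)\,S_w \;+\; f\,\kappa\,S_{fat},
\qquad
S_c = \mathrm{PD}\,\bigl(1-e^{-\mathrm{TR}/T_{1,c}}\bigr)\,
      e^{-\mathrm{TE_{equiv}}/T_{2,c}}\,P_c ,
$$

where $f$ is the tissue's fat fraction, $\kappa$ the residual fat signal
under fat saturation (default 0.05; 1 without saturation), and the
preparation factor $P_c$ is $1$ for an unprepared block,
$e^{-\tau/T_{2,c}}$ for a T2-preparation of duration $\tau$, and
$e^{-\mathrm{TSL}/T_{1\rho,c}}$ for a spin-lock preparation. Key
simplifications, chosen deliberately:

* **Full-TR saturation recovery** instead of an echo-train-resolved
  recovery. Vendor refocusing-flip-angle trains are summarized by the
  scalar equivalent echo time `te_equiv_ms` of each preset (for the 2D TSE
  references, their single TE). Because all blocks of a sequence share TR,
  TE~equiv~ and proton density, these factors cancel exactly in the
  prepared/unprepared signal ratio — the property the map reconstruction
  relies on — so the surrogate is sufficient for contrast-level and
  relaxometry-level conclusions. A corollary: residual T1-weighting
  artifacts that arise from complex refocusing patterns (e.g., in menisci)
  are *not* representable in this model.
* **Fat saturation as a multiplicative residual** $\kappa$ on the fat
  compartment, with no spectral modeling. The fat compartment relaxes with
  fixed adipose constants (`fat_compartment_params()`: T1 380 ms,
  T2 = T1ρ 130 ms); the water compartment uses the per-voxel ground-truth
  T2/T1ρ so that the depth-dependent cartilage modulation propagates into
  the images.
* **Rician noise**: independent zero-mean Gaussian noise of SD `sigma` on
  the real and imaginary channels, then the magnitude. The default
  `noise_sigma = 0.005` (signal units in which proton density is ≤ 1)
  puts cartilage at a morphologic SNR of roughly 30–50, a realistic
  clinical regime. Noise is spatially white and independent between
  blocks; per-block RNG substreams are derived deterministically from the
  master seed.

## The phantom

`build_knee_phantom()` draws a sagittal knee-like slab (default 160 × 160
voxels × 7 slices at 0.875 × 0.875 × 3 mm) from simple parametric shapes:
a circular femoral condyle with an articular cartilage band, a flat tibial
plateau with its cartilage band, a synovial fluid pool, wedge menisci, an
anterior infrapatellar fat pad, bone marrow and posterior muscle. Anatomic
fidelity is irrelevant for the quantities under test; what matters is that
every tissue class exists with enough voxels for ROI placement and that
cartilage has a well-defined depth coordinate. Voxel indices are 1-based
(the R convention); the NIfTI affine is identity rotation scaled by the
voxel spacing.

Cartilage ground truth is depth-modulated by the linear profile
`cartilage_zonal_profile()`, from 55 ms (articular surface) to 25 ms
(bone interface) for T2 and 60→30 ms for T1ρ. This reproduces the
qualitative zonal stratification of cartilage — superficial values exceed
deep values monotonically. The remaining defaults (fluid T1 3600 / T2 800
ms, fat and marrow T1 380 / T2 130 ms with fat fraction 0.9, meniscus T2
12 ms, muscle T2 32 ms) are plausible 3 T values; none is load-bearing,
since every test compares against whatever the configuration states.
With the shared zonal endpoints, segmented cartilage means come out near
42 ms (T2) and 45 ms (T1ρ); the femoral annulus weights the superficial
zone slightly because outer-radius shells contain more voxels.

ROIs are derived from the label map only, never from intensities, so
placement is identical across sequences. A nominal area in mm² maps to
`round(area / in-plane voxel area)` voxels (minimum 1): with the package's
0.875 mm in-plane spacing the standard 2.11 mm² pair ROI is 3 voxels; at
0.5 mm spacing it is 8, and the 3.76 mm² homogeneity ROI 15. The ROI is
the set of that many tissue voxels nearest the tissue's in-slice centroid
(nearest tissue voxel to the centroid when the centroid falls outside a
curved band), giving a connected, approximately disc-shaped region. The
placement rule is our convention; only "circular, fixed area, fixed
anatomic site" is prescribed by the study design the package emulates.

## Map reconstruction

With two usable blocks the relaxation time is the closed form
$t = \tau / \ln(s_1/s_2)$; with three or more it is ordinary least squares
of $\ln s$ on preparation time, $t = -1/\mathrm{slope}$. The two
estimators coincide exactly on two points. Log-domain least squares is
deterministic, matches the two-point form, and is adequate at the 2–3
samples per voxel the sequences provide; no nonlinear or
magnitude-bias-corrected fit is attempted, and the log-domain
$R^2$ is reported per voxel (1 by convention for two-point fits).

Validity masking ("diagnostics mode", the default) marks a voxel invalid
when

1. any used signal is at or below the floor (default $3\sigma$),
2. the signal does not decay (non-negative slope, or $s_1 \le s_2$ for
   two-point fits), or
3. for fits with ≥ 3 points, the largest absolute log-domain residual
   exceeds `resid_tol` (default 0.15, i.e. roughly 15% deviation from a
   single exponential).

The first two rules reproduce the "no meaningful values in fat" behavior
for the T2 variant directly: fat is saturated in the unprepared block but
not in the prepared one, so the fat-pad signal *rises* and the two-point
fit is rejected. For the spin-lock variant the geometry is reversed (the
unprepared block is unsuppressed), and the fat pad decays steeply between
blocks 1 and 2 and then flatly between 2 and 3 — a pattern no single
exponential fits. The floor alone cannot catch this: with the default
parameters the suppressed fat-pad signal is numerically almost identical
to the late-spin-lock cartilage signal, so any floor that removes fat also
removes cartilage. The residual bound is the discriminating diagnostic: it
trips deterministically on the fat pad (residual ≈ 0.3) while leaving
water tissues valid, including synovial fluid, whose near-flat decay has
small residuals even though its $R^2$ would be poor — which is why the
criterion is an absolute residual bound and not an $R^2$ threshold.
Alternatively, `fat_mask_from_phantom()` imposes ground-truth masking
(fat fraction > 0.5). Fitted times are clamped to (0, 2000] ms so fluid
voxels stay finite under noise; display ranges default to the conventional
0–100 ms (T2) and 0–70 ms (T1ρ) windows.

## Image-quality metrics

For each sequence, `compare_sequences()` evaluates on the designated
morphologic block (the fat-saturated zero-preparation block for the
PD-weighted family, the unsaturated zero-preparation block for the
T1-weighted family):

* Weber contrast $(SI_t - SI_r)/SI_r$ between femoral cartilage and
  synovial fluid (PD-w FS) or the infrapatellar fat pad (T1-w),
* CNR $(SI_a - SI_b)/\sqrt{\sigma_a^2 + \sigma_b^2}$, signed as defined,
* CV $\sigma/SI$ in the homogeneous reference ROI (3.76 mm²).

ROI statistics use the population (n) SD; the choice is a fixed convention
so that exact tests are well defined. On the default phantom the
cartilage–fluid Weber contrast is negative for every PD-w FS sequence
(fluid is brighter than cartilage) and strictly more negative for the
long-TR 2D TSE reference than for the TR 1200 ms interleaved variant: the
longer TR recovers the long-T1 fluid more completely, brightening the
reference tissue. This sign ordering is a property of the signal model and
is asserted, not tuned.

## Reader-study statistics

`min_sample_size()` implements the two-sided normal-approximation paired
design, $n = \lceil ((z_{1-\alpha/2} + z_{\text{power}})\,
\mathrm{SD}/|\Delta|)^2 \rceil$; with $\Delta = 0.5$, SD 0.4, power 0.8
and $\alpha = 0.01$ it returns 8. The sidedness is our choice — the
one-sided variant would give 7 — and the two-sided form is adopted and
documented because it reproduces the published determination exactly.

`simulate_likert()` draws 5-point ordinal scores from a cumulative-logit
model with crossed Gaussian random intercepts for structure, reader and
specimen: $P(Y \le s) = \mathrm{logit}^{-1}(\theta_s - \eta)$ with
$\eta = \beta_{\text{sequence}} + u_{\text{structure}} + u_{\text{reader}}
+ u_{\text{specimen}}$. The default design (10 specimens × 3 readers × 22
structures per sequence, reference level "2D TSE") mirrors a realistic
multi-reader evaluability study; the generator emulates proportional odds
and independent random intercepts exactly, so model-recovery tests verify
the fitter, not the realism of reader behavior — real reader data may
violate proportional odds, show reader-by-sequence interactions, or have
informative missingness, none of which the generator produces.

`fit_clmm()` maximizes the Laplace-approximated marginal likelihood:

* **inner loop** — Newton maximization of the penalized log-likelihood
  over the stacked random-effect vector $u$ (analytic gradient and
  Hessian $Z^\top W Z + D$; step halving; gradient tolerance $10^{-8}$),
* **outer loop** — box-constrained quasi-Newton (`nlminb`, relative
  tolerance $10^{-6}$) over thresholds (parametrized as first threshold
  plus log-differences to keep them ordered), fixed effects, and
  log random-effect SDs (bounded in $[-8, 4]$),
* the Laplace objective
  $\ell(\hat u) - \sum_g m_g \log\sigma_g - \tfrac12 \log\det H(\hat u)$,
  warm-starting $\hat u$ between outer evaluations.

With no random terms the model reduces to the fixed-effects
proportional-odds ML, fitted with an analytic gradient to a tighter
tolerance; this exact special case is also used as the starting point of
the mixed fit and is validated against an independent implementation
(`MASS::polr`) in the tests. Standard errors come from the observed
information of the Laplace objective in the natural parametrization;
log-SD parameters that end on the lower boundary (variance → 0) are held
fixed in that computation.

Latent-scale estimated marginal means are
$\mathrm{EMM}_j = \beta_j - \bar\theta$ (reference level $\beta = 0$):
latent EMMs are identified only up to threshold location, and centering by
the mean threshold is the documented convention. Pairwise contrasts reduce
to fixed-effect differences; their multiplicity adjustment is the
equicoordinate multivariate-normal bound over the whole contrast set,
evaluated by seeded Monte Carlo (2 × 10⁵ draws by default) on the contrast
correlation matrix, and floored at the unadjusted p-value. The classical
studentized-range adjustment is reserved for the repeated-measures ANOVA,
mirroring common practice in mixed-model versus classical ANOVA settings.

`rm_anova_tukey()` decomposes a complete specimen × sequence table into
block and sequence sums of squares, tests
$F = \mathrm{MS}_{\text{seq}}/\mathrm{MS}_{\text{res}}$ on
$(k-1, (k-1)(n-1))$ degrees of freedom, and adjusts all pairwise
comparisons with the studentized-range distribution (Tukey–Kramer). A
degenerate table with zero between-sequence variance returns $F = 0$ with
all adjusted p-values 1.

## Numerical conventions and degenerate inputs

* Relaxation fits: signals at or below the floor, non-decaying signals,
  and single-category score vectors are rejected or flagged, never
  silently clamped; the only clamp is the (0, 2000] ms ceiling on fitted
  times.
* Probabilities in the ordinal likelihood are floored at $10^{-300}$
  before logging; the threshold log-difference parametrization keeps
  cutpoints strictly ordered at machine precision.
* All stochastic functions take explicit integer seeds, restore the
  caller's RNG state, and derive per-block / per-stage substreams with an
  integer hash kept inside exact double arithmetic, so every artifact is
  bit-reproducible from configuration plus seed.
* Ties in ROI voxel selection are broken by voxel index order, making ROI
  placement deterministic.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the full-size default phantom
(160 × 160 × 7) for round-trip and masking checks, 10⁴ voxel repetitions
for noisy-recovery bias, 10⁶ draws for the Rayleigh/Rice moments, 100
random instances for the fit-oracle comparison, 200 replicates of the
10 × 3 × 22 two-sequence design for Wald-interval coverage, and 2000 null
simulations for the ANOVA type-I error. Unit tests use a 48 × 48 × 3
phantom, which preserves every tissue with ≥ 20 voxels.

## Known limitations

* No k-space sampling, parallel-imaging noise amplification, B0/B1
  effects, or echo-train ordering; scan-time fields in the presets are
  metadata only.
* The meniscal artifact mechanism attributed to residual T1 contrast
  from complex refocusing patterns cannot arise in a ratio-cancelling
  steady-state model; representing it would require an echo-train-resolved
  (EPG-style) simulator.
* Mono-exponential relaxometry only — no multi-component or stretched
  exponentials, and no B1-corrected spin-lock model.
* The Likert generator cannot stand in for human readers; statistics on
  simulated scores validate the estimation machinery, not diagnostic
  claims about sequences.
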