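# mcdmri

Multi-compartment modelling of diffusion MRI in breast cancer tissue.

Conventional ADC and diffusion-tensor analyses assume a single Gaussian
water pool per voxel. In tumour tissue, intracellular water is restricted by
cell membranes and the stroma is anisotropic, so those models confound cell
volume fraction, cell size and matrix organisation. `mcdmri` implements the
richer analysis used in ex vivo breast microstructure studies:

* **Compartment signal models.** Ball (free isotropic), Zeppelin
  (cylindrically symmetric tensor), Tensor (full anisotropic), and Sphere —
  restricted diffusion in an impermeable sphere of radius *R* via the
  Gaussian-phase-distribution (Murday–Cotts) series. Nine composite models
  (`Ball` … `Tensor-Sphere`) combine an extracellular shape with an
  intracellular Ball or Sphere weighted by the volume fraction *f_I*, with
  S0 and T2 fitted jointly:
  `S = S0 · exp(−TE/T2) · (f_E·E_ext + f_I·E_int)`.
* **Acquisition schemes.** The 42-combination pulsed-gradient spin-echo
  protocol (four Δ/TE blocks, δ ∈ {3, 10} ms, G up to 400 mT/m, b up to
  ~22 000 s/mm², with the published NEX pattern) and 42-direction DTI
  shells, as tidy tibbles with Stejskal–Tanner b-values
  `b = γ²G²δ²(Δ − δ/3)`.
* **Rician maximum-likelihood voxel fitting** with background-based noise
  estimation, NEX-aware likelihood, and structured multi-start search;
  **AIC/BIC model selection** (`AIC = −2lnL + 2k`, `BIC = −2lnL + k·ln n`)
  with per-voxel winner maps and relative-criterion boxplot summaries.
* **Metropolis–Hastings posterior sampling** around the ML estimate
  (burn-in 5000, thinning 400, 500 retained samples).
* **NNLS T2-spectrum screening** that excludes voxels whose main spectral
  peak holds < 90% of the area (non-mono-exponential T2, e.g. necrosis).
* **Derived maps**: ADC, *f_I*, *R*, Zeppelin FA and colour FA, plus
  block-average downsampling to emulate coarser acquisitions.
* **A structured synthetic phantom** (cellular tumour, aligned stroma,
  mucinous, necrotic, fat) with ground truth, Rician noise, multi-echo T2
  simulation, and a compiled Monte-Carlo random-walk oracle for the
  restricted-sphere signal.

## Worked example

```r
library(mcdmri)

scheme <- build_study_protocol()
round(b_value(400, 3, 10))   # strongest gradient, shortest-timing block
#> [1] 928

phantom <- make_phantom(seed = 1)
dwi <- simulate_signals(phantom, scheme, sigma = 0.01, seed = 2)  # SNR 100

# one cellular-tumour voxel, ground truth f_I = 0.50, R = 8.87 um, D_I = 0.85
vox <- dplyr::filter(phantom$truth, region == "tumour-cellular")[100, ]
obs <- dwi[vox$i, vox$j, vox$k_idx, ]
fit <- fit_voxel(obs, scheme, "Zeppelin-Sphere", noise = 0.01,
                 n_starts = 12, seed = 3)
glance(fit)
#> # A tibble: 1 x 7
#>   model             lnL     k     n   AIC   BIC converged
#>   <chr>           <dbl> <int> <int> <dbl> <dbl> <lgl>
#> 1 Zeppelin-Sphere  451.     9   130 -883. -857. TRUE
round(unlist(fit$params[c("f_I", "R", "D_I")]), 2)
#>  f_I    R  D_I
#> 0.43 8.94 1.08
```

`f_I` is the intracellular signal fraction, `R` the fitted cell radius in
micrometres, `D_I` the intracellular diffusivity in 10⁻³ mm²/s; the fit
recovers the generating values (0.50, 8.87, 0.85) to within the
single-voxel uncertainty at this SNR — medians across voxels are tighter
(see the phantom-recovery tests). Model comparison and maps follow the same
tidy verbs
(`fit_volume()` → `select_models()` → `best_model_map()` / `colour_fa()`),
and `run_pipeline()` drives the whole chain with a config list or YAML file.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mcdmri", load_package = "installed")'
```

The suite covers the closed-form signal identities (nesting degeneracies to
1e-12), the printed protocol b-values, Monte-Carlo vs series agreement for
the restricted sphere, parameter recovery and model selection on the
phantom at SNR 50, T2 screening, MCMC correctness against a Laplace oracle,
and the pipeline smoke test.

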