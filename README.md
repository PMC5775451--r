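# cftnoise

Analytic and simulation toolkit for the **chemical fluctuation theorem**
(CFT) of gene expression: the exact relation between fluctuations of the
transcription rate, the mRNA lifetime distribution, and cell-to-cell
variability in mRNA copy number.

## The problem

Gene expression noise is usually analyzed with kinetic network models
(constant-rate transcription, or the two-state telegraph gene). Real
transcription rates are coupled to hidden cell-state variables — polymerase
levels, promoter DNA conformation, nutrients — that no explicit network
captures. The CFT sidesteps this: for *any* transcription process and any
renewal degradation process, the copy-number variance is

```
σ_n²(t) = ⟨n(t)⟩ + ∫₀ᵗ∫₀ᵗ S(t−τ₁) S(t−τ₂) ⟨δR(τ₁) δR(τ₂)⟩ dτ₁ dτ₂
```

where `S(t)` is the mRNA survival probability and `⟨δR δR⟩` the
autocovariance of the transcription rate. Hidden variables enter only
through the time-correlation function (TCF) of the rate. In the stationary
state, for a factorized rate `R = ξ·κ(Γ)` (gene state × environment-coupled
active-gene rate), the relative variance decomposes additively:

```
η_n² = 1/⟨n⟩₁ + χ_nκ η_κ² + χ_nξ η_ξ² + χ_n(κ,ξ) η_κ² η_ξ²
χ_nq = τ_m⁻² ∫∫ S(t₁) S(t₂) φ_q(|t₁−t₂|) dt₁ dt₂
```

Each rate factor contributes its noise magnitude `η²` weighted by a
susceptibility `χ ∈ [0, 1]` set by its TCF `φ` against the lifetime
distribution: slow fluctuations transmit fully, fast ones are filtered out.

The package is for quantitative/systems biologists and biophysicists who
want to (i) predict mRNA noise for arbitrary lifetime distributions and
rate TCFs, (ii) verify such predictions against exact event-driven
simulation, and (iii) fit telegraph-type models to noise-versus-mean curves
to extract hidden-TCF parameters.

## What's in the box

- **Lifetimes** (`make_degradation_model`, `lifetime_phase_type`): all
  degradation schemes as phase-type distributions (sub-Poisson
  Michaelis–Menten chains, Poisson, two-state super-Poisson bi-exponential),
  plus deterministic lifetimes; closed-form moments, survival, randomness
  `R_d`, exact chain sampling.
- **TCFs** (`switching_tcf`, `parametric_env_tcf`, `renewal_rate_tcf`):
  telegraph switching, exponential and damped-cosine environment TCFs, and
  renewal-process rate TCFs from a renewal-equation solver (promoter
  occlusion model: exponential binding ⊛ gamma initiation).
- **CFT core** (`steady_state_noise`, `variance_trajectory`,
  `susceptibility`): exact resolvent-algebra susceptibilities, transient
  mean/variance trajectories, the full additive noise decomposition.
- **Copy number & polymerase sharing** (`population_noise`,
  `rnap_sharing_correlation`, `constitutive_noise`): gene copy-number
  variation, inter-copy correlation `C_n` from shared RNAP levels,
  constitutive-promoter occupancy models with dichotomous binding affinity.
- **Heterogeneity** (`heterogeneous_noise`, `delta_measure`,
  `noise_surface`): mixture law for cell-to-cell heterogeneity and the
  `Δ(x)` measure separating within-cell non-Poisson decay from between-cell
  rate heterogeneity.
- **Simulator** (`simulate_doubly_stochastic`, `simulate_mechanistic`,
  `estimate_rate_tcf`): event-driven, non-Markovian, per-molecule decay,
  seeded per cell; the brute-force oracle for every analytic claim.
- **Fitting** (`fit_noise_curve`, `forward_curve`): weighted least squares
  with Latin-hypercube multi-start, bootstrap intervals, nested-model
  comparison; classic S3 modelling interface (`coef`, `predict`, `summary`,
  `residuals`, `plot`).
- **CLI** (`inst/cli/cft.R`): `predict | scan | simulate | surface | fit |
  validate` over JSON/YAML configs; every run writes its resolved config
  next to the outputs.

## Worked example

Telegraph gene (`k_on = k_off = 0.01` Hz) whose active-state rate carries
hidden-environment noise `η_κ² = 30` with exponential TCF decaying at
`306 γ`, mRNA decaying at `γ = 1/120` Hz:

```r
library(cftnoise)
d <- make_degradation_model("exponential", gamma = 1/120)
m <- transcription_model("model_III", kappa_mean = 1/12,
                         k_on = 0.01, k_off = 0.01,
                         kappa_tcf = parametric_env_tcf("exponential",
                                                        eta2 = 30,
                                                        decay = 306/120))
steady_state_noise(m, d)
#> Steady-state mRNA noise decomposition
#>   mean <n>        5
#>   Poisson term    0.2
#>   gene switching  0.294118 (chi = 0.2941)
#>   rate factor     0.0977199 (chi = 0.003257)
#>   bilinear        0.0969619 (chi = 0.003232)
#>   eta2_n = 0.688799, Fano = 3.444, Q/<n> = 0.488799
```

Reading: of the total relative variance 0.689, 0.2 is unavoidable Poisson
noise at a mean of 5 copies; gene switching contributes 0.294 (its slow
TCF passes `χ ≈ 0.29` of `η_ξ² = 1`); the fast hidden rate factor passes
only `χ ≈ 1/307` of its large `η_κ² = 30`; and the bilinear coupling of the
two factors contributes as much again — the non-Poisson noise
`Q/⟨n⟩ = 0.489` would be misread by any model ignoring that coupling.

Fitting a synthetic 12-point noise-versus-mean sweep with 2% noise recovers
the hidden parameters:

```r
fx <- generate_noise_fixture(seed = 7)       # λ/γ = 306, η_κ² = 30 truth
fit <- fit_noise_curve(fx, "model_III", seed = 7)
fit
#> Noise-curve fit: model_III (12 rows, RSS 11.82)
#>         k_on lambda_ratio   eta2_kappa       offset
#>     0.010282   319.484026    33.252764     0.204156
```

## Command-line use

```sh
Rscript inst/cli/cft.R predict config.yaml --out results
Rscript inst/cli/cft.R scan config.yaml --seed 3 --out results
Rscript inst/cli/cft.R validate config.yaml
```

See `vignettes/cft-methods.Rmd` for the model, conventions (TCF
normalization, the `Δ(x)` abscissa), numerical choices, and limitations.
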