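---
title: "Methods: the chemical fluctuation theorem for mRNA copy-number noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the chemical fluctuation theorem for mRNA copy-number noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftnoise)
```

## The model

Transcription produces mRNA at a stochastic rate $R(t)$ that is coupled to
hidden cell-state variables: polymerase levels, promoter conformation, gene
state, nutrients. Each mRNA molecule, once made, survives for a random
lifetime with survival probability $S(t)$ and mean $\tau_m = \int_0^\infty
S(t)\,dt$. The central relation this package evaluates connects the variance
of the copy number $n$ at time $t$ to the autocovariance of the
transcription rate:

$$
\sigma_n^2(t) \;=\; \langle n(t)\rangle \;+\;
\int_0^t\!\!\int_0^t S(t-\tau_1)\,S(t-\tau_2)\,
\langle \delta R(\tau_1)\,\delta R(\tau_2)\rangle \,d\tau_1\,d\tau_2 ,
\qquad
\langle n(t)\rangle = \int_0^t \langle R(\tau)\rangle S(t-\tau)\, d\tau .
$$

It holds exactly for any lifetime distribution as long as degradation is a
renewal process independent of transcription — the two standing assumptions
of everything below. Two consequences organize the package:

* if $R$ is constant (Poisson transcription), the double integral vanishes
  and $\sigma_n^2 = \langle n\rangle$ *regardless of the lifetime
  distribution*;
* in the stationary state, for a factorized rate $R = \xi\,\kappa(\Gamma)$
  with independent factors (gene state $\xi \in \{0,1\}$, environment-coupled
  active-gene rate $\kappa$), the relative variance decomposes additively:

$$
\eta_{n}^2 = \frac{1}{\langle n\rangle_1}
 + \chi_{n\kappa}\,\eta_\kappa^2
 + \chi_{n\xi}\,\eta_\xi^2
 + \chi_{n(\kappa,\xi)}\,\eta_\kappa^2\eta_\xi^2 ,
\qquad
\chi_{nq} = \frac{1}{\tau_m^2}\int_0^\infty\!\!\int_0^\infty
  S(t_1)S(t_2)\,\phi_q(|t_1-t_2|)\,dt_1 dt_2 ,
$$

with $\langle n\rangle_1 = \langle\xi\rangle\langle\kappa\rangle\tau_m$.
Each rate factor enters only through its noise magnitude $\eta_q^2$
(relative variance) and normalized time-correlation function (TCF)
$\phi_q$, with $\phi_q(0)=1$. The susceptibility $\chi$ is a
lifetime-weighted average of $\phi$, so $0 \le |\chi| \le 1$: slow factors
($\phi \equiv 1$) transmit their noise fully, fast factors
($\phi \to 0$) not at all. The bilinear term means the two contributions are
*not* an intrinsic/extrinsic split.

The statistic we report throughout is the non-Poisson noise
$Q_n/\langle n\rangle = \eta_n^2 - 1/\langle n\rangle$: zero for any Poisson
process, and far more discriminating between transcription mechanisms than
the Fano factor.

## Lifetimes as phase-type distributions

All degradation schemes are represented uniformly as phase-type
distributions — absorption times of a small continuous-time Markov chain
with sub-generator $T$ and initial distribution $\alpha$ — plus a dedicated
`delta` kind for deterministic lifetimes, which no finite chain represents
exactly. One representation gives one code path for moments
($E[X^k] = k!\,\alpha(-T)^{-k}\mathbf 1$), survival
($S(t) = \alpha e^{Tt}\mathbf 1$), exact sampling (stochastic simulation of
the chain, never inverse-CDF), and the susceptibility integrals.

The three named models:

* `exponential`: one state, rate $\gamma$; the default $\gamma = 1/120$ Hz
  is a measured bacterial *lacZ* mRNA decay rate. Randomness
  $R_d \equiv \mathrm{Var}/\mathrm{mean}^2 - 1 = 0$.
* `michaelis_menten`: substrate binding then catalysis (optionally
  reversible). Sub-Poisson, $R_d < 0$; the default equal-rate irreversible
  two-stage chain has $R_d = -1/2$.
* `two_state_super`: two interconverting mRNA states with distinct decay
  rates, degradation starting from state 1. Super-Poisson ($R_d > 0$) with a
  bi-exponential lifetime density, the standard model for bacterial
  transcripts with observed bi-exponential decay. By default the
  state-1-to-state-2 conversion rate is solved (by `uniroot` on the analytic
  phase-type mean) so that the mean lifetime is exactly 25.8 s, a measured
  mean lifetime for such a transcript; the remaining rates
  ($\gamma_1 = 0.2$, $\gamma_2 = 1/48$, $k_{21} = 0.01$ Hz) are package
  defaults chosen to give a clearly super-Poisson, strongly bi-exponential
  shape at that mean.

Construction fails loudly when a requested model class cannot have the sign
of $R_d$ its name promises, reporting the computed value.

## TCF families and the renewal rate TCF

Closed-form TCFs (exponential decay; exponentially damped cosine) are stored
as sums of complex exponentials $\phi(u) = \mathrm{Re}\sum_k c_k
e^{-z_k u}$. This makes two operations exact rather than numeric: pointwise
products (term-by-term outer products, used for the bilinear susceptibility)
and the susceptibility integral itself, which reduces to resolvent solves,
$\int_0^\infty e^{-z u} e^{Tu}\mathbf 1\,du = (zI - T)^{-1}\mathbf 1$, after
the lag substitution

$$
\int_0^\infty\!\!\int_0^\infty S S \phi
 = 2\int_0^\infty \phi(u)\, A(u)\,du,
\qquad A(u) = \int_0^\infty S(t)S(t+u)\,dt,
$$

with $A(u)$ available in closed form through a Kronecker-sum identity. An
independent adaptive-quadrature route (`method = "quadrature"`) exists
purely as a cross-check and agrees to $10^{-8}$ on random models.

The transcription rate of an *active* gene following the three-step
mechanism — exponential polymerase binding (mean $\tau_1$), gamma-distributed
initiation (mean $\tau_2$, dispersion $b$), deterministic elongation delay
$\tau_3$, with promoter occlusion so waiting times are the convolution of
steps 1 and 2 — is a renewal process. Its stationary rate autocovariance is
$\mathrm{cov}(u) = r\,(h(u) - r)$ for $u > 0$, where $r$ is the event rate
and $h$ the renewal density, with the same-event delta excluded (that delta
*is* the Poisson term of the variance relation; excluding it is what makes
the relation hold exactly by construction for doubly stochastic rates). We
return this as $(\eta^2, \phi)$ with $\phi(0^+) = 1$; for sub-Poisson
streams the covariance is negative, so $\eta^2$ carries the sign. For
small-CV waiting times the covariance oscillates with period equal to the
mean waiting time $\tau_1 + \tau_2$; peak positions are therefore measured
on the covariance, where the oscillation has sharp maxima.

$h$ solves the renewal integral equation $h = \psi + \psi * h$. We
discretize by the trapezoid rule on a uniform grid and refine with two-grid
Richardson extrapolation (default step: mean/400), which brings the solver
to $\sim 10^{-8}$ of the Erlang-2 closed form
$\mathrm{cov}(u) = -(\mu^2/4)e^{-2\mu u}$ — plain trapezoid at a practical
step cannot reach the tolerance we test at.

## Copy number, polymerase sharing, heterogeneity

For $g$ identical gene copies (static per cell) the population non-Poisson
noise is

$$
\frac{Q_n}{\langle n\rangle} =
 \frac{1}{\langle g\rangle}\frac{Q_{n,1}}{\langle n\rangle_1}
 + \eta_g^2
 + \frac{\langle g(g-1)\rangle}{\langle g\rangle^2}\,C_n ,
$$

where $C_n$ is the mean-scaled correlation between copies induced by shared
environment. The last two terms are independent of the single-copy mean, a
property asserted by test along control sweeps. The copy-number
distribution is a user-supplied discrete distribution (static replication
picture); we do not reconstruct the replication model behind any particular
copy-number Fano factor — it enters as an input (default offset 0.21 in the
sweep family).

For constitutive promoters the rate is
$R_1 = [K N_{Rp}/(1 + K N_{Rp})]\,k_{TX}(\Gamma)$. $N_{Rp}$ is treated as
static per cell (slow on the transcription timescale) and enters as a
mixture over cells; a dichotomous affinity $K \in \{0, K_0\}$ (promoter DNA
conformational dynamics, switching at 100 Hz-scale rates) maps onto the
gene-switching factor of the decomposition. Shared static $N_{Rp}$ gives
$C_n = \mathrm{Var}(\theta)/\langle\theta\rangle^2$ with
$\theta = K N_{Rp}/(1+K N_{Rp})$, computed both exactly over the discrete
support and in the quadratic approximation
$\eta^2_{N_{Rp}}/(1+\bar K \bar N_{Rp})^2$; both are reported. When the
mixture is degenerate and the affinity does not fluctuate, the constitutive
model reduces exactly to the environment-coupled single-gene model — a
structural identity the tests assert.

Cell-to-cell heterogeneity (e.g. in degradation rate) makes the pooled
process non-renewal; the generalized treatment is the law-of-total-variance
mixture over cell groups: $\langle n\rangle = \sum_c w_c \langle n\rangle_c$,
$\sigma^2 = \sum_c w_c \sigma_c^2 + \sum_c w_c(\langle n\rangle_c -
\langle n\rangle)^2$. Continuous heterogeneity is approximated by quadrature
nodes (a finite mixture).

### The $\Delta(x)$ measure

$\Delta(x)$ is the change of single-copy non-Poisson noise as the lifetime
relative variance $x$ leaves the exponential reference $x = 1$, at fixed
$\tau_m$ and fixed transcription model. We take $x$ to be the relative
variance of the lifetime ($x = R_d + 1$), so the reference point is the
exponential distribution; this mapping is a documented convention of the
package. Both families realize the *same* bi-exponential pooled lifetime
density, built by the standard balanced-means two-phase fit of
$(\tau_m, x)$:

* homogeneous: every cell has the hyperexponential (super-Poisson) lifetime
  — noise decreases with $x$;
* heterogeneous: two cell groups, each with exponential decay at its own
  rate — noise increases with $x$.

The opposite signs make $\Delta(x)$ a probe of whether non-exponential decay
in pooled data reflects within-cell kinetics or between-cell heterogeneity.

## The simulator

Two engines, deliberately separate:

* **Doubly stochastic**: transcription events are generated from a
  piecewise-constant stochastic intensity $g\,\xi(t)\,\kappa(t)$ — a
  telegraph gene switch times a finite-state Markov rate modulator. A
  two-state modulator with rates $(0, \kappa_{\mathrm{mean}}(1+\eta^2))$
  realizes any exponential TCF with any $\eta^2 > 0$ in closed form. This
  engine realizes exactly the stochastic-intensity object the variance
  relation integrates, so it verifies the analytics cleanly. Events within a
  constant-intensity segment are Poisson-thinned exactly (Poisson count,
  uniform times).
* **Mechanistic**: promoter cycles drawn as $t_1 + t_2$ (exponential
  $\circledast$ gamma) with the mRNA appearing $\tau_3$ later; elongation is
  non-blocking, the gene always active. Gene-state gating exists only in
  the doubly stochastic engine: the factorized decomposition assumes
  independent $\xi$ and $\kappa$, which a gated renewal process does not
  guarantee, so we do not offer that combination rather than silently
  produce data the analytics do not describe.

Every mRNA gets an independent lifetime sampled by exact simulation of the
degradation chain at birth; a molecule is counted at the horizon if its
death time exceeds it. Per-cell random streams are derived from
`(seed, cell index)`, so enlarging a population never reshuffles existing
cells, and identical seeds give bit-identical event logs.

The rate-TCF estimator uses the pair-lag histogram — algebraically the
binned-count autocovariance with same-bin shot noise removed, but linear in
the number of event pairs — with an edge correction $(1 - u/L)$ for sources
near the end of the observation window, and bootstrap-over-cells standard
errors.

## Fitting noise-versus-mean curves

The forward model maps a control sweep (repressor unbinding rate $k_{off}$)
to $(\langle n\rangle_1,\ Q_n/\langle n\rangle_1)$ pairs; fitting is
weighted least squares (weights $1/\mathrm{SE}^2$ when provided) with
multi-start L-BFGS-B from a seeded Latin hypercube over log-scaled bounds.
Free parameters: the offset for the constant-rate family; plus $k_{on}$ for
the telegraph family; plus $(\lambda/\gamma, \eta_\kappa^2)$ of the
exponential hidden-rate TCF for the environment-coupled family. Freeing
$k_{on}$ is what lets the richer families *collapse* onto flat data (fast
switching suppresses switching noise), preserving the nested-model
structure. For the constant-rate family the control still sets the mean
(through the induction level); the model's content is that the noise stays
flat. Identifiability is flagged (not silently ignored) when the mean range
spans less than a decade or the weighted Jacobian normal matrix has
condition number above $10^6$. Bootstrap-over-rows 90% intervals are
reported. Synthetic fixtures apply seeded, mean-preserving lognormal noise.

At the package's default sweep family ($\lambda/\gamma = 306$,
$\eta_\kappa^2 = 30$, offset 0.21, $k_{on} = 0.01$ Hz,
$\langle\kappa\rangle = 1/12$ Hz, $\gamma = 1/120$ Hz; 12 $k_{off}$ values
spanning means $\sim 0.05$–$10$ copies), 2% noise leaves both TCF
parameters recoverable with median relative error well under 20% over 20
seeded replicates, and the environment-coupled family beats the plain
telegraph on RSS in every replicate.

## Numerical and design choices

* Units: seconds and Hz throughout; config files may use `"min"`/`"h"`
  suffixes, converted at load.
* Susceptibilities: exact resolvent algebra for closed-form TCFs; trapezoid
  on the lag grid for tabulated (renewal) TCFs, which vanish beyond their
  grid; for delta lifetimes, closed forms on the finite support.
* Transient variance: direct 2-D trapezoid on $[0,t]^2$ (201 nodes per axis
  by default), with a symmetry check of the supplied covariance on probe
  points.
* Steady state: integrals truncated where both the survival and the TCF
  envelope are negligible; the spectral decomposition of $T$ is cached per
  lifetime object, with a matrix-exponential fallback when the eigenbasis is
  ill-conditioned.
* Hidden-environment defaults used in the lifetime-randomness studies:
  exponential $\phi_\kappa$ with $\lambda = 306\gamma = 2.55$ Hz (the
  fitted slow-growth value), $\eta_\kappa^2 = 30$, symmetric switching
  $k_{on} = k_{off} = 0.01$ Hz (active fraction 1/2, switching well inside
  the sub-2 Hz regime of repressor dynamics), $\langle\kappa\rangle = 0.2$
  Hz. The magnitude and switching rates are package choices — the underlying
  experimental optimum is not printed in any source we ship — selected once
  to give expression means of a few copies and clearly resolvable noise
  terms, and not revisited.
* Problem sizes: simulation-backed checks use $10^4$ cells for Fano-factor
  closures and 4000–8000 cells per point for decomposition closures, with
  horizons of 10–20 mean lifetimes after stationary modulator
  initialization; these sizes put bootstrap standard errors comfortably
  below the effects being measured.

## What the synthetic data do and do not show

The generators emulate the study conditions: control sweeps over switching
rates, polymerase-level mixtures, bi-exponential lifetime scenarios, and
renewal transcription with promoter occlusion. They are stationary, ignore
cell division and lineage correlations, treat gene copies as identical and
statically counted, and assume degradation independent of transcription.
Passing tests therefore demonstrate the internal correctness of the
analytics and simulator under the stated model assumptions — not that any
particular organism satisfies those assumptions. The one behavior we know
real populations show but a homogeneous renewal model cannot reproduce is a
progressively lengthening oscillation period in the rate TCF; in this
package that arises only from explicit heterogeneity mixtures
(dispersed mean waiting times), which is exactly the diagnostic use the
$\Delta(x)$ machinery supports.

## Worked example

```{r example}
d <- make_degradation_model("exponential", gamma = 1/120)
m <- transcription_model("model_III", kappa_mean = 1/12,
                         k_on = 0.01, k_off = 0.01,
                         kappa_tcf = parametric_env_tcf("exponential",
                                                        eta2 = 30,
                                                        decay = 306/120))
steady_state_noise(m, d)
```

## Known limitations

* No protein layer, no feedback regulation, no non-stationary TCFs.
* Renewal TCFs are tabulated: products with other tabulated TCFs are
  interpolated, not exact.
* The gated (repressed) gene with renewal active-phase transcription is not
  simulated (clock semantics across off-periods is ambiguous; see above).
* Continuous parameter heterogeneity is approximated by finite mixtures.
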