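---
title: "Generative and phenomenological models of sinusoidal saccade adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative and phenomenological models of sinusoidal saccade adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(sinadapt)
```

## The paradigm and its coordinates

Saccades are too fast for in-flight visual correction, so saccadic gain is
calibrated across trials from post-movement error. In the sinusoidal
double-step paradigm the target first steps by `preTP` (held at 8 dva
here), and then — while the eye is in flight — by an intra-saccadic step
(ISS) whose size follows a sine of the trial number,
`ISS(n) = P sin(2πf n/N)` with `P = 2` dva, i.e. up to ±25% of the first
step. Everything in the package works on dimensionless gains:

- stimulus gain `s(n)`, the ISS normalized to its maximum: a
  unit-amplitude sinusoid on adaptation trials, zero elsewhere;
- target gain `t(n) = 1 + p·s(n)` with `p = P/preTP = 0.25`;
- adaptation gain `g(n) = (SA(n) − preTP)/P`, the residual of the saccade
  with respect to perfect landing in ISS units (0 = perfect saccade).

`session_design()` encodes a session as blocks; `freq_design()` builds the
extended-frequency session (eleven alternating blocks: six 75-trial
non-adaptation blocks interleaved with five 384-trial adaptation blocks at
1, 3, 6, 12 and 24 cycles per block — 2370 trials), and `orig_design()`
the original single-frequency layout used at 3, 4 and 6 cpb. Because the
original design's block composition per session is not fixed by the
protocol description, the package treats block structure as free
configuration and builds each original-design condition as its own
pre + adaptation session. Each adaptation block restarts the sinusoid at
phase zero and contains a whole number of cycles, so the stimulus averages
to zero over every block; frequencies are therefore restricted to positive
integers. The slight trial-to-trial variation of `preTP` present in real
recordings is not modeled: `p` is a session constant.

```{r session}
trials <- build_session(freq_design())
dplyr::count(trials, block, block_type, frequency_cpb)[1:4, ]
```

## The generative model family

The learner updates a hidden adaptation-gain state by a modified delta
rule with retention, drift, and a second, *distal* error term:

$$x(n+1) = A\,x(n) + K\,(s(n) - x(n)) + m + D\,(s(n-1) - x(n-1))$$

| parameter | meaning | units | fixed value when absent |
|---|---|---|---|
| `K` | learning rate on the last error | fraction/trial | always free |
| `A` | persistence (retention) rate | fraction/trial | 1 |
| `m` | non-error drift (bias) | gain/trial | 0 |
| `D` | distal learning rate (next-to-last error) | fraction/trial | 0 |
| `G` | initial state `x(1)` | gain | mean of first five gains |

Crossing the four optional parameters yields the sixteen models of
`model_specs()`, grouped by the presence of `m` and `D` (I: neither, II:
`m` only, III: `D` only, IV: both). Only models with `m` can produce the
non-zero baseline asymptote seen in sinusoidal adaptation data, which is
why groups II and IV matter in practice.

Two start-up conventions had to be decided because a second-order
recursion needs two initial values:

- the state is seeded as `x(1) = G` directly in adaptation-gain
  coordinates (the saccade-gain formulation would seed `z(1) = G·t(1)`;
  the two differ by the near-unity factor `t(1)`, and the package fits in
  `x`-coordinates throughout, so the simpler convention is used and the
  observation map is the identity);
- the distal term at the first update uses `s(0) = 0` and `x(0) = x(1)`,
  which makes the first step identical to the single-error model; the
  influence of this choice decays within a few trials.

`simulate_state()` (an Rcpp kernel, since it sits inside the least-squares
loop) reports divergence (`|x| > 1e6`) through an `"unstable"` attribute
instead of raising, so optimizers can walk back from unstable proposals.
Stability is exactly the condition that both roots of
`r² − (A−K)r + D = 0` lie inside the unit circle (`is_stable()`).

## Closed-form phenomenology

Under a stable parameterization and sinusoidal drive the steady state is a
lagged sinusoid; with zero stimulus the baseline relaxes exponentially.
`periodic_response()`, `asymptote()` and `decay_timescales()` implement
the closed forms; `predict_phenom_params()` bundles them. Three
conventions are worth spelling out:

- The printed forms "a=KR" / "a=QR" of the amplitude are implemented as
  the ratios `K/R` and `Q/R`: that is the unique reading consistent with
  the transfer function of the recursion,
  `H(e^{iω}) = (K + D e^{-iω}) / (e^{iω} − (A−K) + D e^{-iω})`,
  whose modulus is `Q/R` and whose phase is `−(φ + φ′)`. The
  simulation-oracle tests pin this down numerically.
- With `D < 0` the subtraction mode of the baseline is negative and
  small: it alternates in sign and decays fast. The dominant timescale is
  reported as `−log` of the largest-magnitude root; when both roots are
  real and positive the larger one is the slow (dominant) mode. When the
  discriminant is negative the roots are complex; the modulus is used and
  an `oscillatory` flag is set rather than an error, since the underlying
  theory only discusses the real case.
- Lags are reported in radians and in trials (`lag/ω`), since empirical
  lag plots use trials.

A consequence tested explicitly: at matched `A − K`, a negative `D`
*raises* the dominant root and therefore *lowers* the decay rate λ — the
integration window of the learner widens when a second error is sampled.

The exact two-learner rewriting (`two_learner_view()`) decomposes the
double-error learner into a slow channel with rate `κ = K + D` driven by
the half-sum of the last two stimulus samples and a fast channel with rate
`η = K − D` driven by the half-difference (a discrete stimulus
derivative). With the fitted-scale anchor values `K = 0.15, D = −0.13`,
`κ = 0.02` and `η = 0.28`: an order of magnitude apart.

```{r analytic}
predict_phenom_params(K = 0.15, A = 0.99, m = -0.004, D = -0.13, f = 6)
```

## Fitting the phenomenological model

The descriptive model is
`g(n) = a·sin(ωn − φ) + B·e^(−λn) + B0`, `ω = 2πν/N`, with the sinusoid
active from the first adaptation trial (its argument counts trials from
adaptation onset) while the exponential and asymptote span the whole
fitted segment including the pre-adaptation block. `fit_phenom()` adopts a
Gaussian likelihood whose noise scale is a nuisance parameter integrated
out under a Jeffreys (1/σ) prior, leaving a posterior kernel
`RSS(θ)^(−n/2)` over the six parameters inside uniform box priors.

The integration scheme and prior ranges are package decisions (the
procedure they approximate does not state them):

- priors default to `a ∈ [0, 2]`, `ν ∈ [0.5, 30]` cpb, `φ ∈ [−π, π]`,
  `B ∈ [−2, 2]`, `λ ∈ [0, 0.5]` per trial, `B0 ∈ [−2, 2]`; all
  configurable via `phenom_priors()`. The lag is reported wrapped to
  `[−π, π)` with `a ≥ 0`.
- the posterior in `ν` is multimodal, so the mode is located by a dense
  grid over `(ν, λ)` — the model is linear in the remaining coefficients,
  solved per grid point — then polished by Levenberg–Marquardt;
- moments and the log marginal likelihood come from a Laplace
  approximation at the mode. Near-unidentified directions (e.g. `λ` when
  `B ≈ 0`) would inflate the Laplace volume, so Hessian eigenvalues are
  floored such that no direction contributes more than the widest prior
  width. Exactly noise-free data (RSS numerically zero) yields a
  degenerate posterior: zero variances and infinite evidence, reported as
  such.

Evidence between the nested models — full, drift-only (`a = 0`),
noise-only (constant mean, making the chain exactly nested) — is
`10·log10` of the marginal-likelihood odds, with 3 db as the conventional
significance anchor; the full-vs-noise value is constructed as the sum of
the two chain segments, so the stacked-bar decomposition is exact by
construction. Population pooling of per-participant posterior means
"weighted by their standard deviations" is implemented as inverse-variance
weighting (`1/sd²`): the literal reading (weights ∝ sd) would up-weight
the noisiest participants, which cannot be the intent.

## Fitting the generative family

`fit_state_model()` minimizes the residual between the observed gains and
the *pure forward simulation* (no teacher forcing) with
Levenberg–Marquardt least squares. Multimodality is real when `D` is free,
so the optimizer uses one deterministic center start plus Latin-hypercube
starts (8 by default) sampled over `K ∈ [0.001, 0.3]`, `A ∈ [0.9, 1]`,
`m ∈ [−0.02, 0.02]`, `D ∈ [−0.3, 0.05]`, `G ∈ ĝ ± 0.5`; the best-RSS
solution is kept and re-polished. No bounds are imposed at the solution —
fitted `A` may land above 1 — only on start sampling. Confidence intervals
are Jacobian-linearization intervals at the optimum; rank-deficient
Jacobians mark parameters unidentifiable rather than failing.

AIC bookkeeping: `AIC = n·ln(RSS/n) + 2k` with `k` = free parameters + 1
for the Gaussian noise scale (a constant across models that cancels in
Δ-AIC but keeps the values interpretable); `G` counts only when free. The
small-sample correction (AICc) is available behind a flag but plain AIC is
the default, matching common practice. Akaike weights are
`exp(−Δᵢ/2)/Σ exp(−Δⱼ/2)` per participant; condition-level tables average
the weights element-wise across participants, and best-model ties break
toward fewer free parameters, then lexicographic name.

## The synthetic cohort generator

No human data accompany this modeling framework, so validation runs on
synthetic observers: a latent trajectory from a chosen truth model plus
i.i.d. Gaussian observation noise, `g(n) = x(n) + ε(n)`. The generator
emulates the session designs, the condition structure (Two-way vs Global
adaptation differ only through learning-rate ranges and noise level), and
cohort sizes (13 participants for the extended-frequency design, 10 for
the original one — jointly 95 two-way condition runs).

Defaults, chosen once as the study conditions:

- σ = 0.08 (Two-way) and σ = 0.15 (Global), reflecting the higher
  measurement noise of random-direction adaptation; the underlying
  reports give no per-trial noise magnitude, so these values are
  calibrated only to make recovery non-trivial, not to match human
  variability;
- single-error truth models draw `K` from 0.01–0.035 (Two-way) or
  0.005–0.015 (Global); double-error truths use `K` 0.12–0.18 with
  `D` −0.16 to −0.10 (Two-way; scaled down for Global so `K + D` stays
  positive), `A` 0.985–1, `m` −0.008 to −0.003, `G` −0.15 to 0.05 —
  asymptotes of a few tenths of the ISS amplitude, as observed;
- unstable draws are rejected and redrawn; observers whose truth is
  unstable are refused at generation.

Seeding: a master seed spawns per-observer child seeds as
`(master·1000003 + replicate·1000 + participant) mod (2³¹−1)`, so extending
a cohort never reshuffles existing observers and every run is byte-identical
under the same configuration.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: motor noise propagating into the state
(the latent learner is exactly noise-free), temporally correlated or
signal-dependent measurement error, saccade kinematics and amplitudes in
dva, direction-specific adaptation fields, pacing and fatigue. Recovery
results certify the estimation machinery, not the biological model.

## Validation problem sizes

The shipped tests and the acceptance script validate, at sizes chosen to
exercise the asymptotics while staying light: closed forms against
regression on 6000-trial noise-free simulations and 10 000-trial
zero-stimulus runs over a ~65-point stable parameter grid (worst relative
error observed ≈ 3×10⁻⁶, asserted < 10⁻⁴); exact recovery at σ = 0;
bias and CI coverage over 20 seeded cohorts of 13 observers at σ = 0.1;
model-group selection over 20 cohort replicates per truth; and evidence
behavior over 100 seeded replicates of a single 384-trial block with
periodic amplitude 0.3 at σ = 0.1.

```{r recovery, eval = FALSE}
rec <- recovery_experiment(single_block_design(6), "KAm",
                           truth = list(K = 0.02, A = 0.99, m = -0.004),
                           sigma = 0.1, n_participants = 13,
                           n_replicates = 20, seed = 1)
rec$summary
autoplot(rec)
```

## Known limitations

- The exponential's trial argument starts at the first fitted trial, so
  fitted `B` is comparable across segments only with equal pre-block
  lengths; the decay amplitude `B` is deliberately not predicted from
  generative parameters (it is dominated by the initial condition).
- Laplace evidence is an approximation; with very weak signals the floor
  on Hessian eigenvalues makes the Occam factor conservative rather than
  exact. MCMC is out of scope.
- The model family is noise-free by construction; Kalman-filter/LDS
  variants with process noise are intentionally not implemented.
- Lag comparisons across frequencies are reported but no monotonic
  lag-frequency relation is asserted: empirically the 1 cpb condition
  behaves more like a slow ramp than a periodic stimulus, and the
  closed-form lag is known to mismatch there.
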