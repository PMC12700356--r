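---
title: "Cyclic causal discovery from longitudinal panels: model, identification, and sampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic causal discovery from longitudinal panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgiv)
```

## The model

`dcgiv` learns causal structure among `Q` continuous longitudinal
outcomes measured at discrete visits, allowing *instantaneous* causal
effects — including feedback loops — alongside *time-lagged* effects and
exogenous covariates.  The generative model is linear with non-Gaussian
errors:

$$Y_j \;=\; \mu + \sum_{\ell=0}^{L_y} B_\ell\, Y_{j-\ell}
          + \sum_{\ell=0}^{L_x} A_\ell\, X_{j-\ell} + E_j,
  \qquad e_{jq} \sim \mathrm{Laplace}(0,\, 2\sigma_q).$$

`B0` holds the instantaneous effects with the target-row convention
(entry `(q, p)` is the effect of `Y_p` on `Y_q`), zero diagonal (no
self-loops), and spectral radius strictly below one.  Stability makes
`I - B0` invertible, so each visit has a unique equilibrium
`Y = (I - B0)^{-1} C` given the non-cyclic component `C`; the likelihood
of one visit is the error density of the structural residuals times the
change-of-variables Jacobian `|det(I - B0)|`.

The assumptions carried by the identification theory are (i) causal
sufficiency among the outcomes (no unmeasured confounders; covariates are
conditioned on, not modelled) and (ii) jointly independent, continuous,
*non-Gaussian* errors.  Non-Gaussianity is essential: it lets the
instantaneous mixing be identified by independent component analysis up
to row permutation and scaling of the unmixing matrix `W = I - B0`.

## ICA equivalence classes and instruments

Because ICA pins `W` down only up to admissible row permutations (those
leaving every diagonal entry nonzero) and row scaling, several directed
graphs — generally with different cyclic structure — explain the same
observational distribution.  The package makes this equivalence class an
explicit, computable object:

* `enumerate_class()` checks all row permutations (factorial cost, capped
  at nine vertices), keeps the admissible ones, normalizes rows, and
  deduplicates graphs by edge support;
* `reverse_cycle_surgery()` produces members constructively: reversing a
  set of vertex-disjoint cycles and re-targeting each out-of-cycle parent
  edge of a cycle vertex to that vertex's in-cycle parent.  Reversed
  cycle edges carry reciprocal weights and re-targeted edges are rescaled
  by the in-cycle coefficient, because the operation is a row permutation
  of `W` followed by normalization.  Both routes are implemented and
  must agree; the test suite checks their exact equivalence on random
  graphs, which is the executable form of the class characterization.

A directed acyclic graph is alone in its class; graphs whose cycles are
pairwise disjoint have exactly one *stable* member.  Joint cycles break
this: several stable members can coexist, and observational data cannot
separate them.  The package's answer is the instrumental-variable
certificate: an instrument is a vertex outside the instantaneous graph
whose only edge into it points at its designated target.  Reversing a
cycle through an instrumented vertex necessarily re-targets the
instrument edge, so instruments distinguish class members.
`certify_identifiability()` reports both the sufficient condition (every
cycle contains an instrumented vertex) and the constructive count of
class members compatible with the declared instruments; uniqueness holds
exactly when one member survives.  In longitudinal data the natural
instruments are covariates and, importantly, lagged copies of the
outcomes themselves, which is what makes panel data more identifiable
than cross-sectional data.

### Reading of "cycle" under chords

A cycle is taken to be a vertex sequence together with exactly its loop
edges; additional edges of the host graph among the same vertices
(chords) do not suppress it.  This reading is required for the
re-targeting step of the surgery to be well defined (a chord is then an
out-of-cycle parent edge, even between two cycle vertices).  Because the
opposite reading is defensible for cycle *counting*, `find_cycles()`
exposes `chordless_only = TRUE` as a strictness flag; nothing else in the
package depends on it.

## Priors and the sampler

Each coefficient carries a spike-and-slab prior: slab `N(0, ν)` with
`ν ~ Inverse-Gamma(a_ν, b_ν)`, inclusion probability
`ρ ~ Beta(a_ρ, b_ρ)` shared across coefficients, intercepts
`N(0, σ_μ²)`, and `σ_q² ~ Inverse-Gamma(a_σ, b_σ)`.  The Laplace errors
are handled by data augmentation: `e | τ ~ N(0, σ²/τ)` with
`τ ~ Inverse-Gamma(1, 1/8)` has exactly the Laplace marginal with
variance `8σ²` (the suite verifies the mixture integral against the
closed form to `1e-6`), and the full conditional of `τ` is
inverse-Gaussian with mean `σ/(2|e|)` and shape `1/4`.

The update scheme, re-derived from the stated priors:

* `τ`: per-observation inverse-Gaussian draws;
* lagged-outcome, covariate and intercept coefficients: collapsed
  conjugate updates — the inclusion indicator is drawn from the exact
  two-point marginal with the coefficient integrated out, then the
  coefficient from its Gaussian full conditional;
* instantaneous entries of `B0`: the Jacobian term
  `n log|det(I - B0)|` breaks conjugacy, so each entry is updated by
  birth/death moves (proposing from the no-Jacobian Gaussian conditional,
  Metropolis-corrected with the exact Jacobian) plus a random-walk
  refinement with scale adapted during burn-in toward a 35% acceptance
  rate; any proposal with spectral radius at or above one is rejected,
  so every retained draw of `B0` is stable;
* `ν`, `ρ`, `σ_q²`: conjugate draws.

**Spike semantics.**  The nominal spike is a normal of variance
`ν₀ ν` with `ν₀ ≪ 1`; a spike coefficient is "negligible and treated as
zero".  We take that statement literally in the likelihood: spike-state
coefficients contribute nothing to the mean (the sampler is the
pseudo-prior / variable-exclusion construction, which targets the
point-mass version of the mixture).  The alternative — letting the
spike-state coefficient keep its tiny-variance prior *inside* the
likelihood — was implemented first and rejected: with the documented
hyper-parameters (`ν₀` of order `1e-4`, slab variance around 10) the
spike component has standard deviation near 0.06, large enough that at
the benchmark sample sizes the spike explains moderate effects (|β| of
0.05–0.1) almost as well as the slab and the prior odds then keep them
excluded; the documented detection rates for exactly those small edges
(0.98 at the benchmark `n = 5000`, 0.70 at effect 0.05) are unreachable
in that reading, and are reproduced under the point-mass reading.
Indicator draws are still reported on the `{ν₀, 1}` scale
(`gamma_draws()`).

**Constrained variant** (`constrained = TRUE`, used for cohort analyses
with prior clinical structure): a lagged effect of `Y_p` on `Y_q`
(`p ≠ q`) may only be included when the instantaneous effect is, and all
lags of a pair share the instantaneous sign, realized as half-normal
slab magnitudes times a shared sign; the same hierarchy ties lagged
covariate effects to their lag-0 column.  Because instantaneous
self-effects are structurally zero, the hierarchy is not applied to
lagged *self*-effects (`p = q`) — taking the constraint literally there
would forbid the autoregressive terms that longitudinal outcomes plainly
have.  The exact functional form of this constrained prior is a design
choice of this package; it reduces to the unconstrained prior when the
flag is off.

**Initial visits.**  The likelihood conditions on each individual's
first `max(Ly, Lx)` visits rather than modelling their marginal law —
the standard conditional-likelihood treatment for autoregressions.

## Graph selection and lag choice

`select_graph()` applies the median-probability rule: an edge enters the
selected graph iff its posterior inclusion probability strictly exceeds
0.5 (ties at exactly 0.5 are excluded, matching the strict inequality of
the rule); coefficients are posterior means over slab draws.
`select_lags()` fits once at a maximal lag and inspects the decay of the
largest absolute posterior-mean coefficient per lag matrix: lag `ℓ ≥ 1`
is retained while `m_ℓ / m_0 > 0.1`.  The 0.1 ratio is a package choice
("significant decrease" is not otherwise quantified); it is scale-free,
so inflating all active lags by a common factor cannot change the
selection, and it reproduces the documented choice `(Ly, Lx) = (1, 0)`
on the cohort-style generator across seeds.  When `m_0` is numerically
zero the largest lag magnitude is used as the reference instead.

`posthoc_validate()` closes the loop: since identifiability is a
property of the *learned* graph, the selected instantaneous graph is
certified against the declared instruments, and when uniqueness fails
the output is the set of stable members of its equivalence class rather
than a silently arbitrary representative.

## What the generators emulate

`scenario_one()` is the identifiability stress case: four outcomes, two
joint 3-cycles sharing two vertices, one strong equivalence-class rival
that is also stable, and a single instrument for the shared vertex
(either a standard-normal covariate or the lag-1 copy of the outcome,
with coefficient 0.5).  Intercepts are zero, `σ² = 1/8` makes the
Laplace errors unit-variance, five visits per individual.

`scenario_two()` mimics a clinical cohort: three outcomes with one
instantaneous 3-cycle and first-order lags, one Bernoulli(0.6) and two
standard-normal covariates drawn i.i.d. across visits, intercepts
`(1, -1, 0)`, and an effect-size dial `η` (0.5–1 spans weak to strong
effects; `η = 0` is rejected as degenerate).  The reference cohort's
per-individual visit counts are not public, so the default counts are a
frozen synthetic draw — 200 integers from a right-skewed negative
binomial, clipped to the documented range `[3, 46]` and adjusted to the
documented total of 3684.  This matches the range and total but *not*
the unknown empirical shape; conclusions that depend on the exact
visit-count distribution are outside what a green test establishes.

Initial lagged values are handled by a 50-visit burn-in per individual
so retained visits are approximately stationary (`init = "zero"` is
available for exactness tests).  The simulators are seed-reproducible,
return the exogenous errors so the structural identity can be checked
exactly, and what a green recovery test establishes is internal
consistency of generator + sampler — not performance on real cohorts
with missingness, irregular visit times, or model misspecification, none
of which are modelled.

## Numerical choices

* Edge existence: `|weight| > 1e-8` (configurable per graph).  Class
  membership is compared by edge support only; weights are kept for
  reporting.
* Stability margin `1e-9`: spectral radius exactly 1 classifies as
  unstable ("strictly less than one").
* Enumeration cap: nine vertices (`9! ≈ 3.6e5` admissibility checks);
  raiseable explicitly.
* Permutation semantics: row `r` of `W` moves to row `φ(r)`.  The
  transpose convention fails to reproduce the worked coefficients
  (`0.95 = 1/1.05`, `-1.05 = -1/0.95`) and is therefore ruled out by
  tests.
* Adaptive random-walk scales are frozen after burn-in; adaptation uses
  batch acceptance rates over 100 iterations.
* `τ` draws guard against zero residuals by falling back to the exact
  limiting inverse-gamma conditional.
* Default MCMC budget: 5000 iterations, burn-in 2500, thinning 5, one
  chain, hyper-parameters `a_ν = 5`, `b_ν = 50`, `a_ρ = b_ρ = 0.5`,
  `σ_μ² = 100`, `a_σ = b_σ = 1`; `ν₀` is `2.5e-4` for the
  identifiability scenario and `5e-5·η` for the cohort scenario.

## Limitations

Beyond the scope notes above: no missing-data mechanism; visits are
discrete indices; no latent-confounder (overcomplete-ICA) extension; no
Markov-equivalence machinery (the method identifies within ICA classes,
which are finer); enumeration is factorial and intended for the small
instantaneous graphs (`Q ≤ 9`) the method targets; a single chain is run
by default, so users wanting formal convergence diagnostics should run
multiple seeds and compare selected graphs, which is what
`run_replicated_experiment()` automates.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- scenario_two(eta = 1)
sel <- select_lags(sim$panel, L_max = 2, priors = prior_config(nu0 = 5e-5),
                   seed = 2)
c(sel$Ly, sel$Lx)                       # 1, 0
fit <- fit_dcg(sim$panel, Ly = 1, Lx = 0,
               priors = prior_config(nu0 = 5e-5), seed = 3)
summ <- select_graph(fit)
summ$edges                              # the recovered structure
posthoc_validate(summ, sim$instruments) # uniqueness certificate
```
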