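# dcgiv

Bayesian discovery of **time-lagged and instantaneous — possibly cyclic —
causal structure** from longitudinal panel data, using instrumental
variables for unique identification.

## Who this is for

Biostatisticians and epidemiologists with repeated measurements of
several continuous outcomes per individual (e.g. semi-annual clinical
visits recording viral load, depression scores, kidney function) who
want *causal* structure rather than correlation, and whose system may
contain feedback loops that unfold faster than the visit spacing.
Acyclic methods cannot represent such loops; vector autoregressions miss
within-visit causation entirely.

## The model

For outcomes `Y_j ∈ R^Q` at visit `j` and covariates `X_j ∈ R^S`:

    Y_j = μ + Σ_{ℓ=0..Ly} B_ℓ Y_{j−ℓ} + Σ_{ℓ=0..Lx} A_ℓ X_{j−ℓ} + E_j,
    e_jq ~ Laplace(0, 2σ_q)   (independent, non-Gaussian)

`B0` carries the instantaneous effects (zero diagonal, spectral radius
< 1, cycles allowed); its graph is identified from the unmixing matrix
`W = I − B0`, which non-Gaussianity (ICA) pins down up to admissible row
permutation and scaling.  The resulting **ICA equivalence class** of
graphs is computed exactly by the package (exhaustive enumeration and
constructive cycle-reversal surgery), and **instrumental variables** —
covariates or lagged copies of the outcomes, each with a single declared
child — select the true member: uniqueness is certified when every
directed cycle contains an instrumented vertex.  Structural learning is
fully Bayesian with spike-and-slab priors, Laplace errors handled by a
normal/inverse-gamma scale mixture, an exact `|det(I − B0)|` Jacobian,
and stability enforced on every retained draw; the selected graph is the
median-probability model (edges with posterior inclusion probability
> 0.5).

## Worked example

Simulate the built-in cohort-like scenario (Q = 3 outcomes, one
instantaneous 3-cycle, first-order lags, 200 individuals, 3,684
visits), choose the lag orders from the data, fit, and certify:

```r
library(dcgiv)
set.seed(1)
sim <- scenario_two(eta = 1)
sel <- select_lags(sim$panel, L_max = 2, priors = prior_config(nu0 = 5e-5),
                   seed = 2)
c(sel$Ly, sel$Lx)
#> [1] 1 0
fit <- fit_dcg(sim$panel, Ly = 1, Lx = 0, priors = prior_config(nu0 = 5e-5),
               seed = 3)
select_graph(fit)
#> <dcg_summary> selected edges (threshold 0.5):
#>     from to lag      weight prob
#>       Y1 Y3   0  0.09368573    1
#>       Y2 Y1   0  0.51145332    1
#>       Y3 Y2   0  0.26999663    1
#>  lag1_Y1 Y1   1  0.48742172    1
#>  lag1_Y2 Y1   1  0.24844762    1
#>  lag1_Y2 Y2   1  0.48275177    1
#>  lag1_Y3 Y2   1  0.12345552    1
#>  lag1_Y3 Y3   1  0.50523424    1
#>       X1 Y1   0  0.78714012    1
#>       X2 Y2   0 -0.50337990    1
#>       X3 Y3   0  0.26147096    1
posthoc_validate(select_graph(fit), sim$instruments)
#> <identifiability_certificate>
#>   unique:          TRUE
#>   sufficient cond: TRUE
#>   class size:      1
#>   surviving:       1 member(s)
```

Every edge of the generative model — the instantaneous cycle
`Y1 → Y3 → Y2 → Y1`, the five lagged effects, the three covariate
effects — is recovered with inclusion probability 1 and coefficients
within a few hundredths of their generative values (e.g. `Y2 → Y1`:
0.511 vs 0.5; `X1 → Y1`: 0.787 vs 0.75), the lag orders are identified
as `(Ly, Lx) = (1, 0)`, and the certificate confirms the learned graph
is unique in its stable equivalence class given the declared
instruments.

The equivalence-class machinery is usable standalone:

```r
g   <- scenario_one(10)$truth            # 4 outcomes, two joint 3-cycles
cls <- enumerate_class(g)                # 3 members, 2 of them stable
certify_identifiability(g, instrument_spec("Y1"))$unique
#> [1] TRUE
```

A command-line driver with `simulate`, `fit`, `select-lags`, `identify`,
`enumerate`, and `replicate` subcommands is installed at
`inst/cli/dcgiv`.

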