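# survembed

Non-parametric estimation of **counterfactual survival curves** from
right-censored observational data, using kernel mean embeddings of
conditional survival distributions with inverse-probability-of-censoring
weighting (IPCW).

## The problem

In an observational two-arm study we record, for each subject, an observed
time `T* = min(T, C)` (event time `T` or censoring time `C`, whichever comes
first), an event indicator `Δ = 1{T ≤ C}`, a treatment indicator
`Z ∈ {0, 1}` and covariates `X`. Because treatment was not randomized, the
two Kaplan–Meier curves `S_{T|Z=1}` and `S_{T|Z=0}` confound two things:
the effect of the treatment and the difference in who received it. Writing
`S⟨z|z'⟩` for the survival law of arm `z`'s response structure applied to
arm `z'`'s covariate distribution (a *counterfactual distribution*), the
observational gap decomposes as

    S11(t) − S00(t) = [S01(t) − S00(t)] + [S11(t) − S01(t)]
                    =        A(t)       +        B(t)

where `A` is the **composition effect** (covariate shift between arms) and
`B` the **treatment effect on the treated**. Under conditional exogeneity
(no hidden confounding) the **counterfactual survival gain**

    d(t) = P(T̃1 > t) − P(T̃0 > t)
         = [S10(t) − S00(t)]·P(Z=0) + [S11(t) − S01(t)]·P(Z=1)

is identified, where `T̃0, T̃1` are the potential survival times.

## The estimator

The cross curves `S01` and `S10` are the hard part: they need the
conditional law of the outcome in one arm averaged over the covariates of
the other. `survembed` estimates them in three steps (for `S01`; `S10` is
symmetric):

1. **IPCW weights.** On the control arm, estimate the censoring survival
   `G(t) = P(C > t)` with the reverse Kaplan–Meier estimator and set
   `W_i = Δ_i / G(T*_i−)`. Weighting the uncensored subjects by `1/G` undoes
   the selection bias censoring induces.
2. **Censored conditional mean embedding.** Embed the conditional
   distribution of `T` given `X` into the RKHS of a Gaussian time kernel `l`
   by a weighted vector-valued kernel ridge regression with covariate kernel
   `k`. Averaging the fitted embedding over the treated covariate sample
   gives the counterfactual mean embedding in closed form,

       μ̂⟨0|1⟩(·) = Σ_i a_i · l(T*_i, ·),   a = W (K W + n ε I)⁻¹ K̃ 1_m,

   with `K_ij = k(X_i, X_j)` on the control sample, `K̃_ij = k(X_i, X¹_j)`
   against the treated covariates, `W = diag(W_i)` and ridge parameter `ε`.
   Censored subjects get coefficient exactly zero.
3. **Reconstruction.** Read the coefficients `a` as distribution weights on
   the observed times and convert them to a survival curve (`plugin`
   method, with an antitonic projection to guarantee monotonicity), or
   project the embedding onto embeddings of probability measures via a
   small simplex-constrained quadratic program (`simplex` method).

Defaults: Gaussian kernels with median-heuristic bandwidths,
`ε = 0.1 n^(−1/3)`.

Two standard comparators are included: the **Naive** embedding estimator
(weights `W_i = Δ_i`, i.e. censored subjects simply discarded) and the
**AKME**, an inverse-probability-of-treatment weighted Kaplan–Meier with
linear-logistic propensity scores. (Causal survival forests target the same
estimand through `d(t) = E[τ_t(X)]` but are an external ensemble method and
are not reimplemented here.)

## Worked example

```r
library(survembed)

sim <- simulate_dataset(sim_config(n_control = 400, n_treated = 320, seed = 7))
sim$observed
#> survival_dataset: 720 subjects (400 control / 320 treated), 3 covariate(s), 19.7% events

ec <- estimate_effect_curves(sim$observed)
ec
#> effect curves on 50 grid points in [0, 1.366] (ipcw weights, plugin reconstruction)
#>   max |composition effect A| = 0.1967, max |treatment effect B| = 0.6161
#>   counterfactual gain range: [-0.0298, 0.3940]

round(as.data.frame(ec)[c(1, 20, 40, 50), ], 3)
#>  grid   S00   S11   S01   S10      A     B  gain
#> 0.000 1.000 1.000 1.000 1.000  0.000 0.000 0.000
#> 0.530 0.725 0.864 0.692 0.669 -0.033 0.172 0.045
#> 1.087 0.476 0.838 0.326 0.646 -0.150 0.513 0.322
#> 1.366 0.397 0.788 0.200 0.613 -0.197 0.588 0.381
```

Reading the last row: at `t = 1.37` the treated arm's observational survival
exceeds the control arm's by `0.788 − 0.397 = 0.391`. A small negative part
(`A = −0.197`) is compositional — the treated arm's covariates are actually
less favorable — while the response-structure part is large
(`B = 0.588`), and the estimated counterfactual gain for the whole
population is `d̂ = 0.381`: treating everyone would raise survival
probability at that horizon by about 38 percentage points over treating no
one. (This synthetic scenario has a strong true effect: event times are
drawn with twice the conditional mean survival under treatment.)

A shell interface covers the same pipeline for user CSV files
(`exec/survembed fit --data my.csv --out curves`), data simulation
(`simulate`) and benchmarking (`benchmark`).

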