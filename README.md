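# bdltt

Birth–death models of cladogenesis for lineage-through-time (LTT) data:
likelihoods, congruence, inference, and simulation.

## The problem

Reconstructed phylogenies of extant species — ultrametric time trees with
extinct side branches pruned away — are routinely used to infer past
speciation and extinction rates. Under birth–death models whose rates are
shared across contemporaneous lineages, the tree topology carries no
information: the rank-ordered speciation ages `t1 > t2 > … > t(n−1)` (the
LTT data) are a sufficient statistic. `bdltt` implements the probability
theory of this setting for biologists and methodologists who want to

* evaluate transition probabilities and tree likelihoods under the Yule
  process, the constant-rate birth–death process (BDP) with incomplete
  sampling, and the generalized birth–death process (GBDP) with
  time-varying rates λ(t), μ(t) and sampling fraction ρ;
* construct, for any GBDP, the congruent generalized Yule process with the
  *pulled speciation rate* λp(t) = λ(t)[1 − p0(t)] — demonstrating
  numerically that time-varying-rate BDPs are **not identifiable** from LTT
  data;
* fit the identifiable piecewise-constant (two-epoch) Yule model with
  closed-form maximum-likelihood estimates and Fisher information, and a
  mass-extinction epoch model with numerical MLEs, likelihood surfaces and
  profile intervals;
* simulate reconstructed trees exactly, either forward in time (with
  extinction, mass extinction, and ρ-sampling, pruned to the survivors) or
  conditionally on the tip count via the order-statistics representation.

## The core quantities

All formulas use **ages**: the present is 0 and `t` increases into the
past. With `R(t) = ∫₀ᵗ [λ(s) − μ(s)] ds` and `A(t) = ∫₀ᵗ λ(s) e^{R(s)} ds`,
the probabilities that a lineage alive at age `t` leaves zero or exactly
one sampled descendant today are

    p0(t) = 1 − ρ e^{R(t)} / (1 + ρ A(t)),
    p1(t) = ρ e^{R(t)} / (1 + ρ A(t))²,

solving the backward ODEs with initial conditions `p0(0) = 1 − ρ`,
`p1(0) = ρ`. The GBDP likelihood of LTT data with stem age `t0` is
`(n−1)! p1(t0)/[1 − p0(t0)] ∏ λ(tᵢ) p1(tᵢ)`, identical for every model
sharing the pulled rate `λp(t)`, whose cumulative integral is exactly
`Λp(t) = log(1 + ρ A(t))`.

For the two-epoch Yule model (rate λ0 above the change point `T`, λ1 below,
`I` and `J` events per epoch) the MLEs are closed-form:

    λ̂0 = I / (Σ tᵢ⁰ − I·T),    λ̂1 = J / (Σ tⱼ¹ + I·T),

with Fisher information `diag(I/λ0², J/λ1²)`. Adding an instantaneous mass
extinction at `T` with per-lineage survival probability `p` replaces the
old-epoch survival terms by
`p1*(t) = p e^{λ0(t−T)} e^{−λ1 T} / [p e^{λ0(t−T)} + 1 − p]²`.

## Worked example: a K-Pg-style mass extinction

Simulate a clade that starts 170 Ma with one speciation per 40 Myr, loses
75% of its species at 66 Ma, then speciates at 0.125/Myr, and ask what the
reconstructed tree says about the two rates:

```r
library(bdltt)

me  <- two_epoch_model(0.025, 0.125, T = 66, t0 = 170, survival_p = 0.25)
sim <- simulate_forward_conditional(me, seed = 1, accept = function(s) {
  !s$extinct && attr(partition_ltt(ltt_from_tree(s), 66), "I") >= 1
})
d   <- partition_ltt(ltt_from_tree(sim), T = 66)
fit <- fit_massext(d, T = 66, t0 = 170, survival_p = 0.25,
                   lower = 1e-6, upper = 5)
tidy(fit)
#> # A tibble: 2 × 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 lambda0   0.0359  0.0103
#> 2 lambda1   0.125   0.000766
```

This realization kept only `I = 5` pre-extinction divergences against
`J = 26551` post-extinction ones. The young rate is recovered essentially
exactly (0.125 ± 0.0008 vs truth 0.125); the ancient rate is pinned by
five events only, and its profile interval is an order of magnitude wider
in relative terms:

```r
obj <- function(par) massext_loglik(d, two_epoch_model(par[1], par[2],
                      T = 66, t0 = 170, survival_p = 0.25))
profile_interval(obj, fit, "lambda0", lower = 1e-6, upper = 5)
#>   term    estimate  lower  upper open_lower open_upper
#> 1 lambda0   0.0359 0.0185 0.0598 FALSE      FALSE
profile_interval(obj, fit, "lambda1", lower = 1e-6, upper = 5)
#>   term    estimate lower upper open_lower open_upper
#> 1 lambda1    0.125 0.123 0.126 FALSE      FALSE
```

Even a 21 000-tip tree barely constrains the speciation rate before a hard
bottleneck — identifiable is not the same as informative.

The non-identifiability side is one call:

```r
m <- make_constant_model(1, 0.5, 1)     # constant birth-death process
max(congruence_deviation(m, seq(0, 10, 0.1))$deviation)
#> [1] 1.110223e-16
```

the constant-rate BDP and the pure-birth process with its pulled rate give
identical LTT likelihoods to machine precision.

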