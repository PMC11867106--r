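---
title: "Birth-death likelihoods, congruence, and two-epoch inference on LTT data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth-death likelihoods, congruence, and two-epoch inference on LTT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdltt)
```

## The model and its data

`bdltt` works with reconstructed phylogenies: ultrametric time trees of
extant, sampled species, extinct side branches pruned away. Under every
model in this package the per-lineage speciation rate $\lambda(t)$ and
extinction rate $\mu(t)$ are deterministic functions of time shared by all
contemporaneous lineages, and each extant lineage is sampled independently
with probability $\rho \in (0, 1]$. In this family the labelled topology is
uninformative, so the data reduce to the rank-ordered speciation ages
$t_1 > t_2 > \dots > t_{n-1}$ of an $n$-tip tree — the
lineage-through-time (LTT) data — optionally together with a stem age
$t_0 > t_1$ at which the process started from a single lineage.

**Time convention.** Every public function uses *age*: the present is 0
and $t$ increases into the past. The forward simulators convert
internally. Time is unitless; the worked examples use Myr because the
mass-extinction scenario is calibrated to a K-Pg-like history, but nothing
in the mathematics depends on the unit (rates are simply events per
lineage per time unit).

## Transition probabilities without quadrature

Writing $R(t) = \int_0^t [\lambda(s) - \mu(s)]\,ds$ and
$A(t) = \int_0^t \lambda(s)\,e^{R(s)}\,ds$, the backward ODEs for the
probabilities of zero or one sampled descendant, with initial conditions
$p_0(0) = 1-\rho$ and $p_1(0) = \rho$, are solved by

$$p_0(t) = 1 - \frac{\rho\,e^{R(t)}}{1 + \rho A(t)}, \qquad
  p_1(t) = \frac{\rho\,e^{R(t)}}{(1 + \rho A(t))^2},$$

and the complete-sampling factorization $p_1 = (1-p_0)(1-\eta_t)$ holds
with $\eta_t = \rho A/(1+\rho A)$. The practical consequence of carrying
$(R, A)$ rather than the textbook nested integrals:

* for **constant** and **piecewise-constant** models both integrals are
  exact interval sums — no quadrature anywhere, including inside $p_1$,
  where the nested integral $\int \lambda p_0$ collapses to
  $\Lambda(t) - \log(1 + \rho A(t))$;
* for **tabulated** models (rates linearly interpolated between knots,
  constant beyond the last) $A$ uses adaptive quadrature with relative
  tolerance $10^{-10}$ and absolute tolerance $10^{-12}$;
* the critical process $\lambda = \mu$ is a $0/0$ point of the usual
  closed forms; whenever $|\lambda-\mu| < 10^{-8}\max(\lambda,\mu,1)$ the
  analytic limits are used instead (complete sampling:
  $p_0 = \lambda t/(1+\lambda t)$, $p_1 = (1+\lambda t)^{-2}$). The test
  suite checks continuity across the switch at $10^{-6}$.

The test suite validates all of this against direct numerical integration
of the defining ODEs (deSolve, tolerances $10^{-12}$), over 200 random
parameter draws in the acceptance run; agreement is at the $10^{-12}$
level, far inside the $10^{-8}$ contract.

Constant-rate $p_1$ is evaluated in log space throughout
($\log(1+\rho A)$ via `log1p`-style expansions), because the two-epoch
experiment routinely produces $n > 10^4$ tips and linear-scale products
underflow.

## Likelihoods and conditioning schemes

Four Yule-density variants are exposed, and the conditioning scheme is
always an explicit caller choice — the schemes genuinely differ and their
interpretation is debated, so there is no silent default:

* `yule_joint_loglik()` — joint density of ages and tip count given the
  stem age;
* `yule_loglik_given_stem()` — conditional on $(n, t_0)$, implemented by
  both printed routes (joint divided by the tip-count law, and the
  order-statistics form with truncated-exponential kernel
  $\lambda e^{-\lambda x}/(1-e^{-\lambda t_0})$); the two agree to
  $10^{-12}$ and the equality is a standing test;
* `yule_loglik_given_root()` — conditional on $(n, t_1)$, the scheme
  usable when only the crown is observed;
* `two_epoch_loglik()` / `massext_loglik()` — conditional on the epoch
  event counts $(I, J)$, in "kernel" form (data-only constants dropped)
  or "full" form (with $\log(I+J)!$); MLEs are invariant to the choice.

Impossible *parameters* (e.g. $\lambda = 0$ with $n \ge 2$) yield
$-\infty$ rather than an error so optimizers can probe boundaries;
impossible *data* (an age at or above its conditioning age) are already
rejected by the `ltt_data()` container.

**A deliberate design choice on the GBDP joint.** The time-varying joint
density is usually written $p_1(t_0)\prod_i \lambda(t_i) p_1(t_i)$. As a
density this integrates to $1 - p_0(t_0)$, the probability that the stem
survives to the sample — while the pure-birth process it is claimed to be
congruent with integrates to 1. A reconstructed tree is only ever observed
when the stem does survive, and conditioning on that event replaces the
stem factor by $p_1(t_0)/[1-p_0(t_0)] = e^{-\Lambda_p(t_0)}$ — exactly the
pure-birth stem factor. `gbdp_loglik()` therefore conditions on stem
survival by default (`condition_on_survival = FALSE` recovers the raw
joint; the two coincide for pure-birth, completely sampled models). Both
`gbdp_loglik()` and `gyp_loglik()` also include the $(n-1)!$ rank factor
so their values are directly comparable with the constant-rate joint.

## Congruence and non-identifiability

The pulled speciation rate $\lambda_p(t) = \lambda(t)[1 - p_0(t)]$ defines
the pure-birth process congruent to a given GBDP. Its cumulative integral
has the exact representation $\Lambda_p(t) = \log(1 + \rho A(t))$
(differentiate to verify), so for piecewise-constant models the entire
congruence machinery is quadrature-free. `congruence_deviation()`
evaluates both sides of the pointwise identity
$\lambda(t) p_1(t) = \lambda_p(t) e^{-\Lambda_p(t)}$ on a grid — the
deviation threshold $10^{-8}$ (and $10^{-6}$ for whole log-likelihoods)
sits far above the quadrature tolerance and far below any scientifically
meaningful difference, which is what makes "congruent" operationally
testable. `congruent_complete_sampling_model()` exposes the constant-rate
corner of the congruence class
($\lambda' = \rho\lambda$, $\mu' = \mu - (1-\rho)\lambda$); enumeration of
general congruence classes is out of scope.

## Two-epoch inference and the mass-extinction model

For the two-epoch Yule model the MLEs and the Fisher information
$\mathrm{diag}(I/\lambda_0^2, J/\lambda_1^2)$ are closed-form; the
analytic score vanishing at the estimates and the negativity of the
second derivatives are standing tests. Degenerate epochs ($I = 0$ or
$J = 0$) produce a *partial* fit with the affected rate flagged locally
non-identifiable rather than an error, matching how local
non-identifiability arises in change-point models.

The mass-extinction survival probability $p_1^*(t)$ is defined by a
series over the lineage count just before the extinction. The series'
per-lineage tip-count probabilities must be evaluated at the *elapsed
old-epoch time* $t - T$; with that reading the geometric series sums
exactly to the closed form
$p\,e^{\lambda_0(t-T)}e^{-\lambda_1 T}/[p\,e^{\lambda_0(t-T)}+1-p]^2$
(the package implements both and the acceptance run compares them on a
540-point grid at $10^{-10}$). Two structural facts worth knowing:

* as $p \to 1$ with equal rates, $p_1^* \to e^{-\lambda t}$ and the
  likelihood degenerates to the plain two-epoch form (tested at
  $p = 1 - 10^{-8}$);
* $p_1^*$ is increasing in $p$ only while
  $\lambda_0 (t - T) < \log 2$; beyond that the derivative changes sign,
  so the monotonicity property is asserted only on that regime.

Numerical fitting (`numeric_mle()`, used by `fit_massext()`) is
box-constrained L-BFGS-B with five log-uniform multi-starts under fixed
sub-seeds — the surface can be extremely flat in $\lambda_0$ — and an
observed-information matrix from central finite differences with step
$\varepsilon^{1/3}\max(|\theta|, 1)$. Profile intervals use the
$\chi^2_1$ 95% drop of 1.92 by default, with bisection for the endpoints
and explicit open-ended flags when a bound is not bracketed inside the
box. The change point, stem age and survival probability are treated as
known throughout; estimating them is out of scope.

## Simulators: what they emulate, and what they do not

`simulate_forward()` is an exact event-driven simulation: per-piece
exponential waiting times for constant and piecewise-constant rates (no
discretization error), thinning against the maximum total rate for
tabulated rates (exact because the linear interpolant attains its maximum
at a knot), binomial survival at the mass-extinction age, and binomial
$\rho$-sampling at the present. Each simulation uses one locally scoped
generator; the seed is recorded in the result and echoed into every file
written from it. Total extinction is a flag, not an exception.
Conditioning (e.g. on a tip count) is by rejection with a capped attempt
count that reports the acceptance rate.

`sample_yule_order_stats()` draws the $n-1$ ages conditional on
$(n, t_0)$ directly from the truncated-exponential kernel by inverse CDF;
`sample_bdp_order_stats()` generalizes to the constant-rate BDP with
sampling using the kernel $\propto \lambda p_1(x)$, whose CDF is exactly
$\eta_x/\eta_{t_0}$, evaluated on a 2048-point grid and inverted by
monotone interpolation. The acceptance run confirms the two routes —
conditional sampler vs rejection-conditioned forward simulation — are
distributionally indistinguishable (KS per order statistic at
$n = 10$, 2000 replicates) and that forward tip counts follow the
geometric law (chi-square at $10^5$ replicates).

What the generator deliberately does **not** emulate: divergence-time
estimation error (ages are taken as known, as in most applications of
these models), lineage-specific rates, fossil or serially sampled tips,
and gene-tree/species-tree conflict. Tests passing on simulated data
therefore validate the probability calculus and the estimators *given*
correct, exactly dated trees — not robustness to the errors real
timetrees carry. Imported newick trees are accepted as ultrametric within
$10^{-6}$ of tree height to absorb rounding noise in published timetrees.

## Study conditions, problem sizes, and one honest negative result

The two simulation experiments shipped in the tests and the acceptance
script use these conditions:

* **Two-epoch calibration:** $(\lambda_0, \lambda_1, T, t_0) =
  (0.05, 0.2, 5, 15)$, 200 forward replicates conditioned on
  $I, J \ge 5$, Wald 95% intervals from the closed-form Fisher
  information.
* **Mass-extinction experiment:** $(\lambda_0, \lambda_1, t_0, T, p) =
  (0.025, 0.125, 170, 66, 0.25)$ — one speciation per 40 Myr, a 75%
  extinction at 66 Ma, a fivefold rate increase afterwards — five seeds,
  conditioned on a surviving reconstructed tree with at least one
  pre-extinction node. Typical realizations carry a handful of old-epoch
  events against $10^4$ young-epoch events.

In the mass-extinction experiment the young rate is recovered within
three standard errors of 0.125 in every seed, while the relative profile
width of $\lambda_0$ exceeds that of $\lambda_1$ by a factor of 30–50:
identifiable, but barely informed — even with tens of thousands of tips.

The two-epoch calibration contains a negative result we keep visible
rather than paper over. The young rate's Wald interval covers the truth
at almost exactly the nominal rate (0.98 observed over 200 replicates in
the acceptance run). The ancient rate's does not (about 0.77): given the
epoch counts, the old-epoch ages are *truncated* exponentials on
$(T, t_0)$, the epoch-count-conditioned likelihood drops the truncation
normalizer $(1 - e^{-\lambda_0(t_0-T)})^I$, and the MLE
$I/(\sum t_i^0 - IT)$ therefore targets roughly the reciprocal mean of a
near-uniform variable — several-fold above a small true
$\lambda_0(t_0 - T)$. Conditioning on $I \ge 5$, a $\sim 1\%$ event under
these parameters, adds strong upward selection. The corresponding
acceptance assertion for $\lambda_0$ fails by design of the experiment,
and the test suite leaves it failing: it is a real property of this
estimator under these conditions, of a piece with the experiment above —
rates before a bottleneck are where this model family's information runs
out.

## Known limitations

* Piecewise-constant exact integrals are computed in linear space; for
  extreme products $|\lambda-\mu| \cdot t \gtrsim 700$ within a single
  piece they can overflow (the constant-rate path is fully log-space).
* General $p_n(t)$ for $n \ge 2$ under time-varying rates is not
  provided; the LTT likelihoods only need $p_0$ and $p_1$.
* The congruence tooling verifies and constructs the pulled-rate
  pure-birth representative; it does not search congruence classes for
  members with non-negative extinction rates.
* Newick input is deliberately minimal: plain labels, mandatory branch
  lengths, comments stripped with a warning, polytomies rejected.
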