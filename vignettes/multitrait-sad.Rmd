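---
title: "Multiple-trait structured antedependence mixed models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-trait structured antedependence mixed models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

sadmix analyses several traits recorded repeatedly over a common time grid —
the motivating case is litter size (LS) and average birth weight (ABW) of a
sow or doe over up to five successive parities.  The phenotype of animal
$i$ at time $t_j$ decomposes as

$$ y_i(t_j) = \mu_i(t_j) + u_i(t_j) + p_i(t_j), $$

with fixed effects $\mu_i$, an additive genetic effect $u_i$ and a
*pseudo-permanent* animal effect $p_i$.  There is deliberately **no separate
residual term**: the permanent effect absorbs residual variation.  This
avoids the identifiability tug-of-war between a structured permanent
covariance and an unstructured residual and helps convergence; the price is
that the permanent covariance must be read as "permanent environment +
residual", which is how its heritability denominator is used throughout.

Both random effects follow a structured antedependence (SAD) process over
the trait-by-time grid.  For one trait, an order-$\alpha$ SAD writes the
effect at time $t_j$ as a regression on its own past values plus an
independent innovation:

$$ p(t_j) = \sum_{s=1}^{\alpha} \theta_{sj}\, p(t_{j-s}) + e(t_j), \qquad
   e(t_j) \sim N(0, \sigma^2(t_j)). $$

Parsimony comes from modelling the coefficients as polynomials in the raw
time value, $\theta_{sj} = \sum_q a_{sq} t_j^q$, and the innovation variance
on the log scale, $\sigma^2(t_j) = \exp(\sum_q b_q t_j^q)$, which keeps it
positive for every finite parameter value.  A structure is labelled
`SAD` $\alpha\beta_1\ldots\beta_\alpha\gamma$ by its order and polynomial
degrees; `SAD 111` has one lag with a linear-in-time coefficient and a
log-linear innovation variance.

The multiple-trait extension adds *cross-antedependence*: trait 2's effect
at $t_j$ may also load on trait 1's effect at lags $c', \ldots, \eta'$, with
lag 0 (a same-time, recursive dependence) allowed.  Identifiability mirrors
the structural-equation-model results for recursive systems: innovations of
different traits are independent, except that a correlation $\rho$ between
the two traits' innovations at the first time point may be estimated when
*neither* direction carries a lag-0 cross.  Lag-0 dependences must form an
acyclic graph (no simultaneous feedback); the validator enforces both rules.

## Covariance construction

Stacking the trait-time cells time-major (all traits at $t_1$, then $t_2$,
...), the inverse covariance of one random effect factorizes as

$$ P^{-1} = L' D^{-1} L, $$

where $L$ is unit lower triangular holding the *negated* (cross-)
antedependence coefficients and $-\rho$, and $D$ is the diagonal of
innovation variances.  The covariance itself is computed by triangular
solves, never by a general inverse, and is positive definite for every
finite parameter vector.  Two conventions needed fixing:

* **Early times.**  The defining recursion only applies once full history
  is available; for earlier rows the sums simply truncate to the lags that
  exist.  This keeps $L$ triangular and reproduces the standard printed
  example in which the $t_2$ rows of a three-time, order-1 system carry
  only lag-1 terms.  A lag-0 cross is retained at $t_1$, where the model
  reduces to a classical recursive two-trait model.
* **Within-slice trait order.**  With a lag-0 cross the "from" trait must
  precede the "to" trait inside a time slice for $L$ to stay triangular;
  slices are ordered by a topological sort of the lag-0 graph (stable with
  respect to the declared trait order), and results are returned in
  declared order.
* **Initial correlation.**  $\rho$ is encoded exactly as in the Cholesky
  convention: a regression coefficient of the second trait's first-time
  cell on the first trait's.  It is optimized on the $\mathrm{atanh}$
  scale and reported on $(-1, 1)$.

Time is *not* rescaled: polynomials are evaluated at the raw parity values
1..T.  Rescaling would change coefficient values but not the implied
covariance family; raw values match the field's reporting habits.

## REML estimation

The genetic effects of all animals have covariance $A \otimes U$ with $A$
the pedigree numerator relationship matrix (tabular method with inbreeding;
its sparse inverse by Henderson's rules is provided and tested against
dense inversion).  Permanent effects are independent across animals with
covariance $P$ per animal.  Because the model has no residual, the
phenotype covariance restricted to the records of one *family block*
(a connected component of $A$ among recorded animals) is

$$ V_b[r, s] = A[i_r, i_s]\, U[c_r, c_s] + [i_r = i_s]\, P[c_r, c_s], $$

and blocks are independent.  The REML criterion is evaluated block-wise in
compiled code; an optional shared random intercept (contemporary group,
constant over parities, independent per-trait variances) couples the blocks
and is handled by a Woodbury correction.

The criterion is the density of an **orthonormal basis of error
contrasts**,

$$ \ell = -\tfrac12\left[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X|
   - \log|X'X| + y'Qy\right], $$

chosen over the bare Henderson form because it is invariant to nonsingular
reparameterizations of the fixed design — a property the test suite checks
and that makes log-likelihoods comparable across equivalent codings.  Only
likelihood *differences* are ever interpreted.

**Optimization.**  All parameters live on an unconstrained scale
(coefficients as-is, $\rho$ via $\mathrm{atanh}$, variances via logs), so a
quasi-Newton method (L-BFGS-B, Nelder–Mead fallback) runs without bounds.
Two details matter in practice:

* a coefficient multiplying $t^q$ moves the likelihood roughly
  $\bar t^{\,q}$ times as fast as a constant; per-parameter `parscale`
  preconditioning derived from the layout names removes this imbalance;
* the gradient uses exact *score kernels*: with
  $K = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1} - (Qy)(Qy)'$, the
  derivative of $-2\ell$ with respect to any covariance parameter is
  $\langle K, \partial V\rangle$, which reduces to inner products of the
  small $d \times d$ derivatives of $U$ and $P$ with cell-aggregated
  kernels computed once per gradient.  The $d \times d$ derivatives are
  taken by forward differences on the (cheap) covariance builder.  With a
  group effect present the gradient falls back to plain forward
  differences.

Default initialization sets every (cross-)antedependence coefficient to 0
and splits the per-trait sample variance evenly between the random parts;
a small number of jittered multi-starts (default 3, fixed seed) guards
against local optima.  Non-convergence is reported, never silent.

AIC is $-2\ell + 2k$ with $k$ the number of **covariance parameters only**;
fixed effects are identical across every comparison the package performs,
so their count cancels.  This convention is stated here prominently because
reported AIC values are only comparable within it.

## Model selection

The published two-step procedure is implemented literally:

1. **Within-trait ladder** (single-trait model, per random effect): start
   at `SAD 100`; test raising the innovation-variance degree ($\gamma$),
   then each antedependence degree ($\beta_s$), repeating the cycle while
   any step is accepted by a likelihood-ratio test at $\alpha = 0.05$
   (the reference is $\chi^2$ with the parameter-count difference as
   degrees of freedom); once a full cycle stalls, test an order increase
   with a constant new coefficient — after an accepted `SAD 121` the next
   candidate is `SAD 2201` — and resume the degree cycle.  Caps on order
   and degree guarantee termination.  The genetic ladder is completed
   first with the permanent structure held fixed, then the permanent one;
   every candidate and test is recorded in a trace.
2. **Cross-dependence selection** (two-trait model): with the within-trait
   structures frozen, start from a recursive lag-0 cross of degree 0 in a
   *user-chosen* direction — biology, not statistics, decides that litter
   size drives birth weight — and raise the polynomial degree while the
   LRT accepts.  An optional initial-correlation candidate is validated
   first and rejected without fitting when a lag-0 cross is present.

All degree/order extensions tested are interior parameters (coefficients
may be negative), so the usual boundary conservatism of variance-component
LRTs does not apply to the ladder; the significance level 0.05 is a
package default, stated since the procedure's source does not fix one.

The random-regression (RR) baseline uses normalized Legendre polynomials
with the argument standardized over [first time, last time] (a convention
that had to be chosen; it is documented because coefficient covariances
depend on it).  Unlike the SAD model the RR model carries an explicit
residual, independent across parities with an estimable within-parity
cross-trait covariance — with degree-1 genetic and constant permanent
coefficients for two traits this accounts for $10 + 3 + 3 = 16$ covariance
parameters, matching the SAD count at which the two families are compared.
Coefficient covariance matrices are optimized through log-Cholesky factors.
At degree $T-1$ with a free coefficient covariance the RR family reproduces
any covariance over the grid exactly (the saturation check in the tests).

## The synthetic-data generator

No real pig or rabbit records are available, so the generator *is* the
package's data: it emulates the design of the motivating datasets, and all
empirical claims in the tests are claims about data of this design.

* **Pedigree:** discrete generations, nested random mating (each dam to
  one sire), configurable sires, dams per sire and offspring per dam
  (fixed or Poisson); recorded animals are the final-generation females.
  Nested mating makes paternal families independent, which both mirrors
  hierarchical livestock designs and gives the block structure the
  estimator exploits.
* **Phenotypes:** genetic values for the whole pedigree are drawn via the
  Kronecker identity $\mathrm{chol}(A\otimes U) = \mathrm{chol}(A)\otimes
  \mathrm{chol}(U)$ (dense; the reference method at the target scale of a
  few thousand animals — the per-animal forward recursion is the noted
  alternative for larger pedigrees), permanent effects per recorded
  animal, plus parity means, an optional standard-normal covariate with
  per-trait coefficients and an optional contemporary-group intercept.
* **Attrition and missingness:** attrition is monotone (a female missing
  parity $j$ has no later litters) with per-parity continuation
  probabilities; per-trait, per-parity observation probabilities are
  applied afterwards.  The rabbit-like preset reproduces the hallmark
  pattern that birth weight is observed for only a small minority
  (about 6%) of first-parity litters and a fraction of later ones, while
  litter size is always recorded; the pig-like preset reproduces the
  steep decline in litter counts across parities and includes a
  60-level contemporary-group effect.

Preset true parameters were fixed once, by construction from the implied
$U$ and $P$, so that heritabilities rise over parities from roughly 0.08
to 0.28 (LS) and 0.22 to 0.39 (ABW) in the rabbit-like design, within-trait
genetic correlations decay with parity distance (LS parities 1–5 about
0.66), cross-trait genetic correlations are negative and strengthen with
parity (about $-0.07$ to $-0.57$), and permanent correlations are near zero
across parities but strongly negative (about $-0.6$) between traits at the
same parity.  The pig-like preset does the analogue with flatter
heritabilities and a very high ABW genetic correlation across parities.

What the generator does **not** emulate: selection (non-random mating),
maternal or dominance effects, non-Gaussian litter-size distributions,
heterogeneous variance between contemporary groups, and real pedigree
depth.  Passing recovery tests therefore show the estimator is correct and
unbiased *for data of this structure*; they cannot certify behaviour under
model misspecification on real data.

## Study sizes used by the test suite

These are the package's chosen simulation conditions (they keep the whole
suite within a practical runtime while leaving enough replication for
3-standard-error bias checks):

* parameter recovery: the rabbit-like design at 1000 recorded does
  (50 sires × 4 dams × 5 does), 20 replicates, single-start fits;
* selection-procedure behaviour under a `SAD 100` truth: 160 does over
  5 parities, 50 replicates; null LRT calibration: 144 does over
  3 parities, 200 replicates;
* SAD-vs-RR AIC comparison: 300 does, 20 replicates;
* Monte-Carlo covariance oracles: 200 000 forward-recursion draws per
  case, 20 random small structures.

## Numerical choices and degenerate inputs

* Innovation-variance exponents (and group log-variances) are capped at
  ±50 before exponentiation; an optimizer step into an overflow region
  returns a large finite penalty instead of NaN.
* A matrix is accepted as positive definite exactly when its Cholesky
  succeeds; there is no silent jitter or regularization anywhere.
* Rank-deficient fixed-effect columns are dropped (pivoted QR) and
  recorded on the assembled model; factor covariates are coded by first
  appearance within each trait's records.
* Duplicate (animal, time, trait) records, times off the grid, undeclared
  traits, animals missing from the pedigree, pedigree cycles and unknown
  parent ids are all hard errors with the offending item named.
* `T = 1` grids, order-0 structures (independence across times) and
  effects with zero variance are all legal; lags reaching before the
  first time point truncate.

## Known limitations

* Dense $A$ and per-family dense blocks target a few thousand animals;
  there is no sparse mixed-model-equation path for very large pedigrees.
* Standard errors of heritabilities and correlations are not computed
  (no delta method); inference is by LRT/AIC between models.
* The group-intercept variance is included in the heritability denominator
  by default (switchable) — a convention choice, since either is found in
  practice.
* No continuous-time (per-animal irregular grid) support: the grid is
  shared, as in parity data.
* Eigen summaries are of the discrete genetic covariance only; no
  eigenfunction (continuous) decomposition is attempted, since the SAD
  covariance is not built from a low-rank function basis.
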