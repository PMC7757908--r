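---
title: "Random regression models for genetic trajectories over repeated harvests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression models for genetic trajectories over repeated harvests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtraj)
```

## The model

Perennial crops are measured repeatedly on the same individuals across
harvests. Treating each harvest as a separate trait ignores that an
individual's genetic merit is a smooth function of time; treating all
harvests as one trait ignores that the genetic make-up of early and late
yield differs. Random regression models (RRM) resolve this by letting each
random effect be a polynomial function of time with unit-specific random
coefficients.

Harvest years are first rescaled to the Legendre domain,

$$t_x = -1 + 2\,\frac{h_x - h_{\min}}{h_{\max} - h_{\min}},$$

and the basis is the *normalized* Legendre system
$\phi_m(x) = \sqrt{(2m+1)/2}\,P_m(x)$, orthonormal on $[-1, 1]$. The
observation on individual $i$ (of family $f$) in replication $k$, plot $l$,
at harvest $j$ is modelled as

$$y_{ijkl} = F_{jk}
  + \sum_{m=0}^{M_g} g_{fm}\,\phi_m(t_j)
  + \sum_{m=0}^{M_p} p_{im}\,\phi_m(t_j)
  + \sum_{m=0}^{M_s} s_{lm}\,\phi_m(t_j)
  + \varepsilon_{ijkl},$$

with fixed harvest-by-replication cell means $F_{jk}$, random genetic
(family), permanent-environment (individual) and plot coefficient vectors

$$g \sim N(0, K_g \otimes I), \quad
  p \sim N(0, K_p \otimes I), \quad
  s \sim N(0, K_s \otimes I), \quad
  e \sim N(0, R).$$

The coefficient covariances $K_g, K_p, K_s$ are unstructured symmetric
matrices of order $M+1$; three residual structures are supported:
homogeneous ($R = \sigma^2 I$), diagonal (one variance per harvest) and
unstructured (a full harvest covariance applied within individual).

The covariance *function* $\sigma^2_x(t) = \phi(t) K_x \phi(t)'$ turns each
$K$ into per-harvest variance components, from which phenotypic variance,
heritability $h^2_g(t) = \sigma^2_g(t) / \sigma^2_{phen}(t)$, genetic
correlations between harvests, eigenfunctions of $K_g$, and
area-under-trajectory selection indices follow.

### Fixed-effect layout

The scalar model (replication effects plus a common fixed Legendre
regression of degree $J-1$) is nested inside the harvest-by-replication
cell means whenever the common regression is saturated, so cell means are
the default (`fixed_layout = "cells"`); the scalar layout is retained as an
option for cross-checks. Cell means also keep the fixed design full rank
without explicit estimability handling.

### Genetic units

Genetic coefficients attach to half-sib *families* by default: families are
independent units under $K_g \otimes I$, and the resulting "genetic
variance" is the between-family variance (one quarter of the additive
variance under the half-sib model; the heritability reported is the printed
ratio $\sigma^2_g/\sigma^2_{phen}$ without the factor 4, matching how such
tables are usually printed for family evaluation). Individual-level genetic
coefficients are available (`genetic_unit = "individual"`) but are
near-confounded with the permanent-environment effect without a
relationship matrix, which is out of scope (the design leaves a hook:
units are exchangeable under $K \otimes I$).

## Estimation

Variance components are estimated by REML. The restricted log-likelihood is
evaluated through the mixed-model-equations identity

$$-2\,\ell = \log|R| + \log|G| + \log|C| + y'Py + (n - r_X)\log 2\pi,$$

where $C$ is the Henderson coefficient matrix. The $2\pi$ constant is
included so values are comparable across residual structures on the same
data. A second, independent code path (`reml_loglik_direct`) forms the full
$n \times n$ covariance $V$ and evaluates
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py + (n-r_X)\log 2\pi]$ directly;
the two routes agree to near machine precision on small instances and serve
as mutual oracles in the test suite.

The optimizer is average-information (AI) REML with step-halving,
safeguarded by EM:

* two EM warm-up iterations stabilize the starting values
  (total phenotypic variance split equally over the four effects,
  diagonal coefficient covariances);
* each AI proposal is accepted only if the restricted likelihood does not
  decrease, halving the step up to 8 times otherwise;
* when an AI step fails — which is typical near the boundary of the
  positive-semidefinite cone, e.g. when a fitted polynomial order exceeds
  the rank of the underlying variation — the fallback is an EM step with
  squared extrapolation (SQUAREM-style): two EM sub-steps plus an
  extrapolated candidate, taking whichever has the higher likelihood. Plain
  EM approaches boundaries geometrically (ratios near 1), and the
  extrapolation collapses that crawl by an order of magnitude in iteration
  count. After a failed AI step, AI is rested for three iterations.

Numerical choices:

* **PSD enforcement.** After every update each $K$ is symmetrized and its
  eigenvalues floored at $10^{-10}\times$ its trace (with a tiny absolute
  fallback scaled to the data variance), keeping $K^{-1}$ computable;
  boundary hits set the `boundary` flag rather than aborting.
* **Convergence.** Relative parameter change and absolute log-likelihood
  change both below `tol` ($10^{-8}$ by default), at most 200 iterations.
  If neither AI nor the accelerated EM fallback can improve the likelihood
  by more than $10^{-10}$, the point is declared stationary (`stall` in
  the trace) — this happens only at boundaries, where the likelihood is
  flat in the floored directions.
* **Observation ordering.** Records are grouped by individual and ordered
  by harvest, so the unstructured residual is block diagonal with one
  harvest-pattern submatrix per individual (patterns are cached). With
  missing records the unstructured EM update divides by pairwise
  observation counts and is therefore only approximately monotone; it is
  accepted as a fallback only when it does not decrease the likelihood.
* **Degenerate inputs.** All-equal harvest years, duplicated
  individual-harvest records, individuals in two plots or families, and
  degrees exceeding $J-1$ are rejected with specific errors. Ties in the
  area ranking break lexicographically on the unit identifier.

BLUEs, BLUPs and per-unit prediction error variance (PEV) blocks come from
the same factorization at the optimum; PEV blocks are the genetic diagonal
blocks of $C^{-1}$, and satisfy $0 \preceq PEV \preceq K_g$. Mean selective
accuracy at harvest $j$ is
$\overline{r}_j = \mathrm{mean}_u\,\sqrt{1 - \phi_j PEV_u \phi_j' /
\sigma^2_g(j)}$, clipped to $[0,1]$; the square root is the standard
definition of accuracy (some renderings print the formula without the
radical).

## Model selection

Candidate models differ in the three polynomial orders and the residual
structure. Each converged fit is scored by
$BIC = -2\,\mathrm{LogL} + p\,\ln(n - r_X)$ (natural logarithm), where $p$
counts only covariance parameters: $(M+1)(M+2)/2$ per random effect plus 1,
$J$ or $J(J+1)/2$ residual parameters. Whole effects are tested by
likelihood-ratio tests against reduced models with the effect's incidence
removed, on $\chi^2$ with the number of removed covariance parameters as
degrees of freedom — a deliberately plain reference that ignores the
boundary constraint and is therefore conservative. The statistic is the
conventional non-negative $2(\mathrm{LogL} - \mathrm{LogL}_R)$; software
that prints $-2(\mathrm{LogL} - \mathrm{LogL}_R)$ reports the same
magnitude with the opposite sign.

## The synthetic trial generator

`simulate_trial()` emulates the motivating field experiment: 73 half-sib
families in randomized complete blocks with 2 replications and 5 plants per
plot — 730 individuals on 146 plots — harvested annually in 2010–2015.
Default generating parameters (see `default_truth()`) are degree-1
coefficient covariances whose implied variance trajectories rise across
harvests with the magnitudes reported for half-sib yield trials of this
crop: genetic variance from 0.0034 to 0.3232, plot variance from about
0.004 to 0.217, and heterogeneous per-harvest residual variances from 0.002
to 0.215 (kg² per plant²); harvest-by-replication cell means are the
published per-harvest means ± 0.05 kg/plant. The permanent-environment
endpoints printed for the motivating trial (0.0035 to 0.1064) are not
attainable by any PSD degree-1 coefficient covariance, so the generator
uses the closest PSD-feasible choice (0.006 rising to 0.1064). The genetic
covariance is nearly rank 1, consistent with a first eigenfunction that
carries almost all genetic variance.

Missingness is missing-completely-at-random (`missing_prob`), reflecting
only that real trials lose records, without a dropout mechanism. Each
effect draws from its own RNG stream split from the master seed, so adding
or removing one effect leaves the others' draws unchanged, and identical
seeds give byte-identical tables.

What the generator deliberately does *not* emulate: spatial field trend
beyond the plot effect, genotype-by-environment structure beyond the time
dimension, pedigree depth beyond half-sib families, selection or informative
dropout, and non-Gaussian trait distributions. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to violations of it.

## Problem sizes used in validation

The test suite validates the likelihood on random instances of up to ~50
observations against the dense-matrix oracle; parameter recovery uses 30
replicates of the full study-sized layout (73 families × 10 progeny × 6
harvests, 4380 records) under a degree-1/0/0 truth, checking that the mean
estimated genetic variance trajectory is within three Monte-Carlo standard
errors of the generating one; BIC degree recovery uses 20 strong-signal
replicates of a 40-family, 4-harvest layout. The bundled analysis scripts
fit a degrees 0:2/0:1/0:1 grid on the default 4380-record trial plus
homogeneous and unstructured residual comparisons at the selected degrees;
warm starts from nested fits keep the whole grid around a minute. A single
saturated fit (genetic 2, plot 5, permanent environment 1 — a ~2600-column
coefficient matrix) converges in roughly 30 iterations, about two minutes
on one core, dominated by the dense factorization of the mixed-model
equations.

## Known limitations

* No pedigree or genomic relationship matrix; genetic units are
  exchangeable.
* The AI matrix is not returned for EM-only runs, so standard errors
  (`param_se`) are available only when at least one AI step was evaluated.
* Absolute log-likelihoods depend on the constant convention; only
  differences between models on the same data are meaningful, and published
  information criteria computed under other conventions need not be
  numerically reproducible from printed likelihoods.
* The unstructured residual with heavy missingness relies on an
  approximately monotone EM fallback; convergence there is to a stationary
  point certified by the failure of both AI and EM to improve the
  likelihood.
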