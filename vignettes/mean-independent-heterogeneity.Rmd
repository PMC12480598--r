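---
title: "Mean-independent heterogeneity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-independent heterogeneity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltadisp)
library(dplyr)
```

## The problem

Ecologists, economists and epidemiologists routinely summarise the
"heterogeneity" of a continuous variable — the spatial spread of elevation
inside a grid cell, the inequality of incomes, the dispersion of cover
percentages — with the variance, standard deviation, coefficient of
variation (CV), Gini coefficient, entropy, or a quantile range. All of
these are **mean-dependent when the variable is bounded**. A variable with
a lower bound (elevation above sea level, biomass, counts per area) must
concentrate against that bound as its mean approaches it; a double-bounded
variable (a cover percentage in $[0, 100]$) must concentrate against
whichever bound the mean drifts towards. Because the measure moves with the
mean even when the underlying dispersion is constant, any regression of an
outcome on such a measure inherits the outcome's *mean* relationship — and
that entanglement can fabricate relationships that are not there.

`deltadisp` implements a dispersion measure that removes this entanglement.
For a variable $V$ with lower bound $L$ and/or upper bound $U$,

$$\delta \;=\; \frac{\sigma^2}{(\mu - L)^{\mathbf 1(L)}\,(U - \mu)^{\mathbf 1(U)}},$$

where each indicator exponent is 1 when that bound exists and 0 otherwise.
The four cases are: $\delta_2 = \sigma^2 / [(\mu-L)(U-\mu)]$ for
double-bounded variables, $\delta_L = \sigma^2/(\mu - L)$ for
lower-bounded, $\delta_U = \sigma^2/(U - \mu)$ for upper-bounded, and
$\delta_0 = \sigma^2$ for unbounded variables.

## Why these denominators

The normalisations are not ad hoc; each retrieves the *dispersion
parameter* of the natural model family for that boundedness class.

**Double-bounded → beta.** Writing the beta density with shapes $p, q$, the
mean is $\mu = p/(p+q)$ and the variance
$\sigma^2 = pq/[(p+q)^2(1+p+q)]$. Define $\delta_2 = 1/(1+p+q)$: then
$\sigma^2/[\mu(1-\mu)] = \delta_2$ exactly, and $(\mu, \delta_2)$
parameterise every beta distribution through
$p = \mu(1/\delta_2 - 1)$, $q = (1-\mu)(1/\delta_2 - 1)$. $\delta_2$ is
the inverse of the usual beta "precision" and is constrained to $(0, 1)$.

**Single-bounded → gamma.** With shape $k$ and scale $\delta_L$, the gamma
has $\mu = k\delta_L$ and $\sigma^2 = \mu\,\delta_L$, so
$\sigma^2/\mu = \delta_L$: the variance is linear in the mean at fixed
dispersion, and dividing by the mean recovers the scale parameter exactly.
Upper-bounded variables use the same machinery on the flipped variable
$U - V$.

Because $\delta$ is a parameter of the distribution rather than a
functional entangled with $\mu$, it is mean-independent *by construction*
for (approximately) beta- or gamma-distributed variables. Note that
$\delta$ is **not scale-invariant** for single-bounded variables (it
carries the variable's units), so comparisons require common units;
$\delta_2$ is dimensionless.

By contrast, each common measure has a closed form that moves with the
mean: the gamma CV is $1/\sqrt k$ and equals half the skewness
($\mathrm{Skew} = 2/\sqrt k$) — it measures shape, not spread; the gamma
Gini $\Gamma(k + 1/2)/[\sqrt\pi\,\Gamma(k+1)]$ likewise depends on $k$
alone; the beta Gini is $2B(2p,2q)/[p\,B(p,q)^2]$; differential entropies
are digamma expressions in the shapes. `bias_curve()` traces all of these
against the mean at fixed $\delta$:

```{r}
bias_curve(bounds(lower = 0), delta = 2,
           means = c(50, 100, 200, 400),
           measures = c("variance", "cv", "delta")) |>
  tidyr::pivot_wider(names_from = measure, values_from = value)
```

The variance doubles with the mean, the CV falls, and $\delta$ stays put.

## Estimators

`heterogeneity_profile()` computes, per group of observations: the sample
mean and variance, sd, CV, Gini (on the standardized scale), a
k-nearest-neighbour differential entropy, a range, and $\hat\delta$
(sample variance over the mean's distance(s) to the bound(s)).

Conventions that had to be pinned, and their defaults:

* **Variance denominator** $n-1$ (`ddof = 1`), configurable to $n$. At the
  default tile size of 400 the difference is below 0.3%, but it must be
  fixed for reproducibility.
* **Empirical quantiles** use linear interpolation between order statistics
  (R's type 7), and the "range" of a sample is exposed in two conventions:
  the 0.95 quantile range (0.025–0.975 extent, the default) and min–max,
  which some older elevation-range analyses used. Both are available in
  `qrange_hat()`.
* **Gini** is computed on the standardized variable, because a location
  shift changes the *relative* mean absolute difference; the closed forms
  for the standard families are only meaningful there. The fast
  sorted-cumulative formulation is tested against the brute-force pair sum.
* **Entropy** uses the Kozachenko–Leonenko estimator with $k = 3$;
  exact-zero neighbour distances (heavy ties) are floored at machine
  epsilon times the data range before the logarithm. A banded Shannon
  entropy (`band_shannon_hat()`) is provided for comparisons with
  height-band style analyses, but band choice biases it, which is why the
  band-free estimator is preferred.
* **Means on a bound** leave $\delta$ undefined (a zero denominator); means
  within $10^{-12}$ of a bound (relative to the support width) are rejected
  rather than clamped. A constant sample strictly inside the bounds has
  $\delta = 0$.
* **Entropy of general double-bounded variables** adds $\ln(U-L)$ to the
  standard-beta entropy — the change-of-variables term; location shifts add
  nothing.

## The quantile-range solver

The 0.95 quantile range of a parametric distribution is solved from its
CDF by Newton's method, seeded at the mode, with tolerance $10^{-12}$.
Safeguards: at most 100 iterations; any step leaving the open support is
replaced by a step halfway to the violated edge; non-converged points fall
back to bisection bracketed by the support. Beta distributions without an
interior mode ($p \le 1$ or $q \le 1$) seed at the nearer support edge
nudged inward by $10^{-9}$ of the support width (U-shaped symmetric cases
seed at the centre). The solver is vectorised across parameter vectors so a
$500 \times 500$ grid evaluates in seconds, and it is tested against
`qbeta`/`qgamma` and an independent bisection to $10^{-9}$.

## Testing mean-(in)dependence empirically

Given per-tile profiles, the package follows a three-step inferential
design:

1. **Mean-balanced resampling** (`mean_balanced_sample()`): tiles are
   binned by mean into uniform strata and resampled per stratum (with
   replacement when a stratum is short), so the mean axis is evenly
   covered. Filters (a mean cap; a minimum per-tile valid-data fraction,
   default 0.75) mirror common raster hygiene and run before
   stratification.
2. **Analytic vs null prediction** (`bias_model_comparison()`): each
   measure is predicted from the tile means with the across-tile average
   dispersion held fixed — $s^2 = \bar\delta(\bar x - L)$ for
   lower-bounded, $s^2 = \bar\delta(\bar x - L)(U - \bar x)$ for
   double-bounded, with sd and CV as the corresponding square-root forms —
   against a null that predicts the across-tile average of the measure
   everywhere. The CV prediction uses the *median* $\tilde\delta$ because
   $\hat\delta$'s ratio form is heavy-tailed at small means. Squared errors
   are compared with a two-sided paired t-test.
3. **Equivalence (TOST)** (`delta_negligibility_test()`): mean-independence
   is a null hypothesis, so it is tested as equivalence. Both $\hat\delta$
   and a reference measure are min–max rescaled to $[0,1]$ and regressed on
   the reference measure's mean-form predictor; two one-sided tests assess
   whether the $\delta$ coefficient lies within half the magnitude of the
   reference coefficient. $\alpha = 0.05$ by default, configurable.

## The spurious-hump mechanism

`make_warp_grid()` builds a Cartesian lattice of true $(\mu, \delta)$,
evaluates a known richness surface at each point — by default

$$D = 66.395 + 3.034\times 10^{-2}\,\mu \;-\; 1.188\times 10^{-5}\,\mu^2
\;+\; 1.076\times 10^{-1}\,\delta,$$

a hump-shaped mean relationship plus a *linear, monotonically positive*
dispersion relationship — and computes every heterogeneity measure at each
point (gamma family, lower bound 0, means 64–2422, $\delta$ 0.64–144 by
default). Plotting $D$ against a mean-biased measure folds the lattice:
`fit_quadratic_hdr()` on the range-based measure returns a clearly negative
quadratic coefficient (an apparent hump), while on $\delta$ the quadratic
term is zero to machine precision. The default lattice is $500 \times 500$;
a $50 \times 50$ fast mode gives the same signs in the test suite.

`fit_model_suite()` fits the five standard regression forms used to
arbitrate these relationships in gridded surveys (#1–#2 with the range,
#3–#5 with $\delta$; #2/#4/#5 adding the quadratic mean term), with
predictors min–max rescaled **after** filtering (the order is not dictated
by the formulas; rescaling on the analysis sample keeps coefficients
comparable within that analysis). `nested_f_test()` compares nested fits by
the standard extra-sum-of-squares F with the standard degrees of freedom
(one numerator df for a single added term).

## What the generators emulate — and what they do not

`gen_tiles()` draws i.i.d. beta or gamma observations per tile at
configured $(\mu_i, \delta)$; `gen_richness_survey()` draws cells with
uniform $(\mu, \delta)$, richness from the surface above plus additive
Gaussian noise (sd 5 by default, 0 for exact-surface checks), and a
range covariate computed as the analytic 0.95 quantile range of the implied
gamma. Defaults — 400 observations per tile, 200 tiles for
mean-independence checks, 285 cells per survey, means 10–400 (tiles) or
64–2422 (surveys) — are the study conditions of the package's simulations.
Per-tile random substreams are seeded arithmetically from the global seed,
so tile 1 is identical whether 20 or 200 tiles are generated.

The generators deliberately omit: spatial autocorrelation between and
within tiles, measurement error and void-filling artifacts of real rasters,
non-beta/gamma tail behaviour, and sampling-effort gradients. Passing tests
therefore demonstrate the *statistical mechanism* — that mean-biased
measures fabricate heterogeneity relationships and $\delta$ does not — not
that any particular field dataset is free of other confounding.

## Problem sizes and numerical notes

The simulations run at desk scale by design: 200 tiles of 400 observations
for the mean-independence and model-comparison checks, 500 tiles for the
equivalence check, a $500 \times 500$ lattice for the polynomial fits, and
100 replicate surveys of 285 cells for coefficient recovery. Gini and the
gamma Gini/entropy closed forms are evaluated in log-gamma space so shapes
of order $10^6$ do not overflow. Beta densities at a support edge with
shape below 1 return `Inf` (the true limit); CDFs are unaffected.

One caveat worth stating for users of the recovery simulation: with the
model's $\mu$ and $\mu^2$ terms fit jointly over a wide mean range, the
coefficient estimates are strongly correlated, so while each coefficient's
2-SE interval covers its true value at the nominal ~95% rate, the *joint*
event that all four coefficients are simultaneously covered occurs in only
~87% of replicates. Joint-coverage expectations should be calibrated
accordingly (or a joint confidence region used instead of per-coefficient
intervals).

## Limitations

$\delta$'s mean-independence is proven within the beta/gamma/normal
families; for variables far from these shapes (strong multimodality,
discrete mass at the bounds) it is an approximation. Bounds must come from
subject-matter knowledge — estimating them from a small sample's min/max
re-introduces the entanglement the measure removes. Maximum-likelihood
fitting of the distribution parameters and multivariate extensions are out
of scope.
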