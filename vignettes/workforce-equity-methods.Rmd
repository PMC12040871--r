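---
title: "Measuring health-workforce equity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health-workforce equity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwequity)
```

## The problem

A health system's workforce can be counted nationally and still be badly
misallocated: the same number of workers can be spread evenly over the
population, concentrated in economically strong units, or piled into a
small fraction of the territory. `hwequity` quantifies this with the
standard three-measure toolkit — Gini coefficient, Theil T, Theil L —
computed over a panel of administrative units, each carrying a worker
count $h_i$ and three candidate denominators $p_i$: population, GDP and
land area. The unit of analysis is the administrative unit (province in
the bundled China setting); all indices are computed per year from that
year's cross-section.

## Density and the trend test

Workforce density is $x_i = h_i / p_i \times 10{,}000$ for the
population dimension (workers per 10,000 persons); for GDP and area the
scaling constant is 1 (workers per currency unit, per km²). Scaling
never affects any inequality index below — they are all scale-free — it
only sets interpretable units.

Temporal trends on short annual series use ordinary least squares of the
value on calendar year, with the two-sided $t$ test on the slope at
$n - 2$ degrees of freedom. Two numerical choices matter:

- **Two-sided p-values.** On the bundled five-point national series the
  two-sided test reproduces the published three-decimal p-values
  (0.001 for density, 0.048 for professional share), which is how the
  convention was fixed.
- **Degenerate fits.** A series lying exactly on a non-horizontal line
  has zero residual variance; the test statistic is unbounded and the
  result is returned with $p = 0$ and a `degenerate` flag rather than an
  error. An exactly constant series is reported as slope 0, $t = 0$,
  $p = 1$: no evidence of trend, nothing degenerate about it. Both
  detections use relative thresholds (residual sum of squares below
  $10^{-20}$ of the response's sum of squares) so they are unit-free.
  Year recoding is immaterial: the test is invariant to affine
  transforms of either axis, and the suite asserts this.

The regression itself is delegated to `stats::lm`; the test suite checks
it against explicit normal-equation arithmetic.

## Gini coefficient and the Lorenz curve

For a chosen dimension, each unit contributes a dimension share
$w_i = p_i / P$ and a density $x_i$. The package computes the
mean-normalized, weight-generalized Gini

$$G \;=\; \frac{\sum_i \sum_j w_i w_j \, |x_i - x_j|}{2\mu},
  \qquad \mu = \sum_i w_i x_i ,$$

equivalently one minus twice the area under the Lorenz curve (units
sorted by ascending density, cumulative dimension share on the x-axis,
cumulative resource share on the y-axis, trapezoid integration). Both
routes are implemented independently — `gini_pairwise()` and
`gini_from_lorenz()` — and the suite requires them to agree to
$10^{-12}$ on random weighted instances.

A plain unnormalized pairwise sum $\tfrac{1}{2N^2}\sum\sum|x_i - x_j|$
is sometimes quoted as "the" Gini formula, but it is not scale-free and
cannot be confined to $[0, 1]$; dividing by the mean density (and
weighting by dimension shares, so that large and small units count by
their size) restores the standard estimator, which reduces to the
classical equal-weight form when all $w_i$ are equal. No small-sample
$N/(N-1)$ correction is applied. Ties in density are broken
lexicographically by unit name; this fixes the Lorenz vertex order for
byte-reproducible output but cannot change $G$ (tie-order invariance is
asserted implicitly by the dual-route check).

The three dimensions follow the WHO convention for workforce equity:
units are *weighted* by their share of the dimension (population, total
GDP, land area) and *ranked* by workers per dimension unit. "Economy"
therefore means cumulative GDP share against cumulative worker share —
GDP is the weight, not GDP per capita.

## Theil T and Theil L

With resource shares $s_i = h_i/H$ and dimension shares $w_i = p_i/P$:

$$T = \sum_i s_i \ln\frac{s_i}{w_i}, \qquad
  L = \sum_i w_i \ln\frac{X}{x_i} = \ln X - \ln \chi ,$$

where $X = H/P$ is the overall density and
$\chi = \exp\left(\sum_i w_i \ln x_i\right)$ the weighted geometric mean
density. `theil_L()` evaluates both forms and asserts the identity
internally. The population dimension is the default (and the
conventional choice); GDP and area denominators are available through
the same share machinery.

**Zero-worker units.** The two indices behave differently at zero, and
the package treats the asymmetry as part of the contract: $T$ uses the
$x \ln x \to 0$ convention, so zero-resource units contribute nothing
and $T$ stays finite; $L$ contains $\ln x_i$, so a single zero-worker
unit collapses $\chi$ to 0 and the index diverges —
`theil_L()` raises a classed `hw_zero_worker_error` instead of returning
infinity. `inject_zero_unit()` exists precisely to exercise this path.

**Decomposition.** Grouping units into regions $g$ with totals $H_g$,
$P_g$:

- Theil T: within $= \sum_g (H_g/H)\, T_g$, between
  $= \sum_g (H_g/H) \ln\frac{H_g/H}{P_g/P}$;
- Theil L: within $= \sum_g (P_g/P)\, L_g$, between
  $= \sum_g (P_g/P) \ln\frac{P_g/P}{H_g/H}$;

with each $T_g$, $L_g$ computed from shares renormalized within the
group. Within + between equals the pooled index identically (up to
floating-point round-off; the suite requires $10^{-12}$), and percentage
attribution is computed from the *unrounded* components. When the
overall index is 0 the percentages are undefined and returned as `NA`
with a `degenerate` flag rather than as 0/0 artifacts. The regional
index columns of the report are each region's own within-group index —
the only reading under which the within column is their weighted sum.

## The synthetic generator: what it emulates and what it does not

`synthetic_config()` describes a balanced panel: units per region, a
log-scale density location per region, a within-region log-normal
dispersion, uniform ranges for population, GDP per capita and area, a
professional fraction, and a multiplicative annual density drift.
Defaults emulate the bundled China setting: 31 units split 11/8/12
across three regions, years 2019–2023, densities around 1.2–1.6 workers
per 10,000 (log locations 0.45/0.20/0.25), `sigma_within = 0.33`
(chosen so the implied Theil $\sigma^2/2 \approx 0.054$ matches the
order of published national values), professional fraction 0.74, growth
6 %/year (the published national density rose from 1.30 to 1.64 over
four year-steps, a 6 % annual rate). Populations span 3–120 million,
GDP per capita 30k–200k currency units, areas $10^4$–$1.7\times10^6$
km² — realistic provincial magnitudes.

Worker counts are rounded to integers after density × population, as in
real registries; validation tests use large populations so rounding
error is negligible. All draws flow from one explicit seed through an
isolated RNG scope (`withr::with_seed`), so a run never perturbs the
session RNG and identical seeds give identical panels byte for byte.

The generator supports closed-form validation because an equal-weight
log-normal density field has known population values: Gini
$= 2\Phi(\sigma/\sqrt 2) - 1$ and Theil (both T and L) $= \sigma^2/2$
(`lognormal_reference()`). The recovery checks run at $\sigma = 0.4$
with 2,000 equal-population units over 50 seeds — at that size the
sampling spread of the estimators sits comfortably inside the 5–10 %
recovery bands, while the whole check still runs in seconds. The
designed between/within split is likewise recovered: with two regions
whose log locations differ by $\delta$, the between-L component is a
closed function of the group mean densities, and a 500-unit-per-region
panel reproduces the designed within-percentage to a few points.

What the generator does **not** emulate: correlation between density
and wealth (population, GDP and area are drawn independently of
density), spatial autocorrelation, unbalanced panels, and any
calibration to actual provincial values. Passing recovery tests
therefore show the estimators are correct on log-normal fields, not
that real administrative data are log-normal.

## Published-table inputs

The package bundles the small published national aggregates for China's
CDC system, 2019–2023: annual totals with density and professional
share, composition percentages (gender, age, tenure) and regional Theil
decomposition rows. Two caveats are preserved as printed:

- The published tenure percentages do not close to 100 in every year
  (95.63 in 2019, 101.77 in 2023 as printed). `read_breakdown()`
  enforces the 100 ± 0.1 partition check by default, but
  `china_cdc_breakdown()` loads with the check disabled and leaves the
  cells untouched — sums over printed cells (e.g. the 46.25 % share with
  20+ years of service in 2023) are taken at printed precision.
- Some published percentage-attribution cells are internally
  inconsistent (a within/between pair summing past 100). The package
  always reports percentages computed from unrounded components and
  makes no attempt to match inconsistent printed percentages; the
  printed *index* components, which do add up, are what the tests
  check.

The provincial microdata behind the published provincial Gini/Theil
values are not public, so those exact values are out of reach; the
synthetic panels carry the estimator-level validation instead.

## Known limitations

- One grouping level (unit → region); no nested decomposition.
- No confidence intervals or bootstrap for Gini/Theil — point values
  only, as is standard in this literature.
- No joinpoint or autocorrelation-adjusted trend models; with five
  annual points, OLS on year is the defensible maximum.
- The Gini is reported without bias correction; at $N = 31$ units the
  classical estimator understates the population Gini slightly, which
  matters for cross-study comparison but not for the within-study
  contrasts the indices are used for.
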