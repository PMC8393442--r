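---
title: "Reconstructing education-specific old-age mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing education-specific old-age mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edumort)
```

## The problem

Nordic education registers do not cover the oldest cohorts: in Sweden no
educational attainment is recorded for people born before 1915, in Denmark
before 1922. In register extracts of deaths and population exposure by
5-year age group (30--34, ..., 85--89, 90+) and ISCED-based education
(low, middle, high), this shows up as an explicit "unknown" category whose
share is negligible at working ages but climbs steeply with age in the early
periods — above 50% at the oldest ages. Education-specific death rates and
life tables therefore cannot be computed directly above roughly age 75--90,
exactly where most deaths now occur.

`edumort` implements a nonparametric reconstruction of the full
education-specific mortality surface from such data plus one auxiliary
input: national all-education death rates by single year of age up to a
terminal age $\omega$ (in practice taken from the Human Mortality Database
and supplied as a local file).

## The method

Write $P_e(a)$, $D_e(a)$ for population exposure and deaths of education
group $e \in \{l, m, h\}$ at age group $a$, $P_u(a)$, $D_u(a)$ for the
unknown category, $P(a)$, $D(a)$ for totals, and $\mu(a)$ for the national
death rate. The pipeline has four stages.

**1. Last reliable age.** $a^*$ is the largest age, at least `min_age`
(default 60), such that the unknown share is at most `threshold`
(default 0.05) at that age *and at every age between `min_age` and it*. The
contiguity requirement means an isolated "good" age beyond a run of bad
ones is never selected; the scan stops at the first failure or masked cell.
The criterion share can be taken from population counts, death counts, or
(default) both — an age qualifies only if both shares are small. Below
$a^*$ the unknown pools are at most a few per cent by construction and are
folded into the known categories in proportion to the same-age known
distribution; observed rates are then $D_e(a)/P_e(a)$.

**2. Hazard-ratio extrapolation.** Above $a^*$ the ratio of each group's
hazard to the national hazard is assumed to converge linearly in age to 1,
reaching it exactly at $\omega = 110$:
$$R_e(a) \;=\; 1 + \bigl(R_e(a^*) - 1\bigr)\,\frac{\omega - a}{\omega - a^*},
\qquad
\mu_e(a) \;=\; R_e(a)\, \mu(a),$$
with anchor $R_e(a^*) = \mu_e(a^*)/\mu(a^*)$ taken against the national
rate aggregated to the $a^*$ group. Affine curves sharing the endpoint
$R_e(\omega)=1$ cannot intersect before $\omega$, so ordered anchors give
hazards that are ordered at every age — no crossovers — and every group
meets the national hazard exactly at $\omega$. Because the input is
abridged, ratios are evaluated at 5-year group midpoints (the anchor sits
at the midpoint of the $a^*$ group) and $\omega$ is a point. If a group has
no deaths in the $a^*$ group, its anchor is pooled over the last two
reliable age groups and a warning is emitted.

**3. Redistribution of unknowns.** Education composition is rigid across
adjacent old-age cohorts, so the unknown population at age $a > a^*$ is
allocated by the composition of the previous age group, scaled by a factor
$\delta$ and applied recursively up to age 90:
$$P^*_e(a) \;=\; P_e(a) + \frac{P^*_e(a-5)}{\sum_e P^*_e(a-5)}\, P_u(a)\, \delta .$$
By default the allocation shares come from the already-redistributed
population at $a-5$ (they sum to 1 even where the raw known counts are
zero); the literal raw-share variant, with the total including unknowns in
the denominator, is available as `recursion_basis = "raw"`. Implied deaths
are $D^*_e(a) = P^*_e(a)\,\mu_e(a)$, and $\delta$ is chosen so that the
residual unknown deaths
$D_u^*(a) = D(a) - \sum_e D^*_e(a)$ vanish in least squares over the ages
above $a^*$ with observed totals. One scalar $\delta$ is fitted per
(country, period, sex): the constraint couples the three education groups
through a single total, so a shared scalar is the reading under which the
constraint system is consistent. $\delta$ is searched over
[0, 2] by a compact differential-evolution optimizer followed by bounded
scalar refinement (`stats::optimize`), deterministic given the seed; a
Gauss--Newton alternative (`optimizer = "closed_form"`, exact in one step
for the raw basis where the residuals are affine in $\delta$) and a grid
search serve as independent cross-checks in the test suite. $\delta$ is not
constrained to 1; values slightly above 1 drain the unknown pool negative
and are flagged with a warning rather than clipped. Two degenerate cases
have conventions: no unknowns anywhere (flat objective) and $a^*$ equal to
the last data age (nothing to fit) both return $\delta = 1$.

**4. Life tables.** From each group's reconstructed hazard schedule on
ages 30, 35, ..., 105 plus the open interval at 110, abridged period life
tables are built with radix 100 000: $q = n m / (1 + (n/2) m)$ with
$a = n/2$ under the default mid-interval convention, or
$q = 1 - e^{-nm}$ under the constant-hazard alternative; the open interval
is closed with $L_\omega = l_\omega / m_\omega$. Any interval with
$n m \ge 1$ — only the oldest groups — always uses the constant-hazard
form, because the deaths-at-mid-interval assumption is untenable there and
would push $q$ to or past 1. Complete (single-year) tables are graduated by
piecewise-constant hazard consistent with each group's survival
probability, then constrained to reproduce the parent group's person-years
exactly, so survivorship and remaining life expectancy at every group
boundary match the abridged table to machine precision.

## Tunable parameters

| key | default | units | role |
|---|---|---|---|
| `threshold` | 0.05 | proportion | maximum unknown share for a reliable age |
| `min_age` | 60 | years | youngest admissible $a^*$ |
| `basis` | `"both"` | — | which unknown share governs the criterion |
| `omega` (grid) | 110 | years | terminal age where all hazards meet |
| `delta_bounds` | [0, 2] | — | admissible $\delta$ interval |
| `delta_tolerance` | 1e-6 | relative deaths | per-age convergence check |
| `optimizer` | `"de_refine"` | — | stochastic search + refinement vs Gauss--Newton |
| `recursion_basis` | `"redistributed"` | — | allocation shares at $a-5$ |
| `convention` | `"midpoint"` | — | within-interval life-table assumption |
| `seed` | 1 | — | seeds the stochastic $\delta$ search |

The choice of $\omega = 110$ matters: it is old enough that assuming full
convergence of group hazards there is demographically defensible (observed
convergence does not occur by age 90), and it is the terminal age to which
national rates are published. The two life-table conventions differ by
roughly 0.05--0.07 years in $e(30)$ on realistic schedules, entirely
through the oldest groups.

## The synthetic register

Since the real register extracts are restricted, the package ships a
cell-level generator (`synthetic_spec()` / `generate_register()`) that
emulates their structure and makes every stage testable:

* **Hazards.** Gompertz per education group,
  $\mu_e(x) = \alpha_e e^{\beta_e (x-30)}$, with defaults
  $\alpha = (9, 7, 5)\times 10^{-4}$ per person-year at age 30 for
  low/middle/high and slopes $\beta = (0.092, 0.095, 0.098)$ per year —
  level-ordered hazards whose relative differences narrow slowly with age,
  the compensation pattern seen in education-stratified data. Male rates
  scale the level by 1.5. These defaults put $e(30)$ in the upper-40s to
  low-50s with a low-to-high gap of 3--4 years, the ballpark of Nordic
  register studies.
* **Composition.** Education shares are cohort-driven: a linear ramp in
  birth year from (0.72, 0.20, 0.08) for cohorts born by 1900 to
  (0.20, 0.42, 0.38) for cohorts born from 1985, clamped outside. This one
  mechanism yields both the within-period age gradient and the
  cross-period educational expansion.
* **Exposure.** `population_base` persons per age group times 5 years,
  scaled by stationary survival within each education group, so older
  groups are smaller and better-educated groups survive longer — which is
  also what makes the national reference an *exposure-weighted* mixture of
  the group hazards (`reference_from_truth()`).
* **Missingness.** Everyone born before `cohort_cutoff` (default 1915, the
  Swedish analog) is masked to "unknown"; post-cutoff cohorts carry a small
  residual unknown share (1% everywhere, 3% above age 60 in the first
  period, decaying by 0.7 per period). In the first period the unknown
  share therefore rises from ~1% at adult ages to 100% at the oldest ages
  and recedes across periods as the pre-cutoff cohorts die out — the
  pattern the method targets, and one that yields $a^* = 75$ in the first
  period.
* **Deaths.** Expected deaths are exposure times the Gompertz hazard at the
  group midpoint; deterministic mode (the default) uses the expectation
  itself so that test tolerances measure the method's approximation error,
  not sampling noise; stochastic mode draws Poisson counts under the seed.

What the generator deliberately does *not* do: the generating truth does
**not** force group hazards to meet the national hazard at 110 (the
Gompertz curves simply continue), so the linear-convergence assumption is
genuinely an approximation on this data and end-to-end recovery error
measures the method's own bias. With the default scenario at
`population_base = 1e5` the reconstructed $e(30)$ per education group lands
within about 0.05 years of truth, comfortably inside the 0.3-year band the
test suite asserts. The generator also omits migration, cause-of-death
structure, sub-annual exposure detail and numerator--denominator source
discrepancies; passing tests say nothing about those features of real
registers.

## Numerical and degenerate-input choices

* Masked register cells are `NA` throughout and are never conflated with
  zeros; a masked cell at or below $a^*$ is an error, a masked total above
  $a^*$ simply drops that age from the $\delta$ fit.
* A group with zero exposure and zero deaths below $a^*$ gets a masked
  rate with a warning; zero exposure with positive deaths is an error.
* Anchor ratio exactly 1 gives a flat ratio curve; the endpoint value at
  $\omega$ is set to 1 exactly (no floating-point residue).
* The $\delta$ objective is evaluated on the same code path as the final
  redistribution, so the reported residuals are exactly the fitted ones;
  `converged` means every per-age residual is within `delta_tolerance`
  relative to that age's total deaths.
* Problem sizes in the test suite: registers at `population_base` 2e4
  (structure tests) and 1e5 (recovery), 1000-profile comparison against the
  exhaustive reliable-age scan, 401-point coarse plus 1e-5-step fine grid
  search as the $\delta$ oracle.

## Known limitations

* Linear convergence of hazard ratios to 1 at $\omega$ is an assumption,
  not an estimate; where true convergence is slower, old-age differentials
  are compressed (this is exactly what the recovery tests quantify).
* One $\delta$ per stratum cannot zero the residual unknown deaths at every
  age on real data; the per-age residuals are reported and should be
  inspected (`delta_residuals.tsv` in batch runs).
* Redistribution stops at age 90, the last data age; above it composition
  is implicitly that of the 90+ group.
* No variance estimation: outputs are point reconstructions, and death
  counts are treated as exact.
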