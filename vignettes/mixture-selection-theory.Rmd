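---
title: "Predicting responses to recurrent selection for performance in species mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting responses to recurrent selection for performance in species mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixsel)
```

## The problem

Cultivars grown in two-species mixtures (grass–legume meadows, cereal–legume
intercrops) are usually bred in pure stands, although pure-stand and mixture
performances are often only moderately correlated. `mixsel` implements the
quantitative-genetic machinery needed to compare, *before committing a decade
of field work*, three recurrent-selection strategies for improving the
performance of a mixture of two populations from different species:

* **SRMA** — reciprocal mixture-ability selection: each progeny family of
  species 1 is tested in mixture with one progeny family of species 2 and
  the best *pairs* are selected;
* **SGMA** — two parallel general-mixture-ability selections: each species'
  families are tested in mixture with a balanced bulk of all companion
  families;
* **pure-stand selection** — ordinary parallel recurrent selections whose
  effect on mixture performance is a correlative response.

## The mixture model

The m-th plot observation of the mixture of families r (species 1) and s
(species 2) is $y_{1r2sm} = x_{1rm} + x_{2sm}$, with the species-1
contribution modelled as

$$x_{1rm} = u_1 + v_{1r} + a_{2s} + (va)_{1r2s} + e_{1rm},$$

where $v_{1r}$ is the **direct effect** of the family on its own species'
contribution, $a_{2s}$ the **associate effect** of the partner family on the
species-1 contribution, $(va)_{1r2s}$ a pair-specific direct-by-associate
interaction, and $e_{1rm}$ a plot error; species 2 mirrors this. Summing the
two contributions gives the general/specific mixture-ability decomposition

$$y_{1r2sm} = u_1 + u_2 + g_{1r} + g_{2s} + d_{1r2s} + \epsilon_{1r2sm},
\qquad g = v + a,\quad d = (va)_{12} + (va)_{21}.$$

All effects are zero-mean Gaussian. The user supplies variances and
*correlations* (never covariances: `mixsel` reconstructs
$\mathrm{Cov} = \rho\,\sigma\sigma'$ and forces the covariance to zero when
either variance is zero, a degenerate case the algebra is otherwise silent
about). `derive_components()` returns the GMA/SMA variances, the genetic
variances of the two species contributions under pair mixtures
($\sigma^2_{Gx1} = \sigma^2_{v1} + \sigma^2_{a2} + \sigma^2_{(va)12}$), and
their covariance.

### Parameters and defaults

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `var_direct`, `var_associate` | variances of v and a | trait² | — |
| `rho_va` | correlation of v and a within a species | — | 0 |
| `var_va_12`, `var_va_21`, `rho_va12_va21` | interaction structure | trait², — | 0 |
| `var_plot_error_mixture` | plot error of observed mixture performance | trait² | 0 |
| `var_e1`, `var_e2`, `rho_e1_e2` | error split of observed contributions | trait², — | see below |
| `eta`, `omega` | correlation of pure-stand effect with v, with a | — | `NA` |
| `pure_design_h2` | design heritability of the pure-stand criterion | — | `NA` |
| `replicates` (design) | observations per tested family/pair, M | count | 3 |
| `selection_rate` (design) | selected fraction per species | — | 0.10 / 0.20 |
| `theta`, `phi` | sexes under selection; progeny-type coefficient | — | 1, 1 |

The negative `rho_va` region is the agronomically worrying one: competition
between the species induces compensation, so a family that raises its own
contribution tends to depress its partner's.

**Error split.** The plot error of the observed mixture performance is the
sum of the errors on the two observed species contributions,
$\epsilon = e_1 + e_2$. When only $\sigma^2_\epsilon$ is given, the split
defaults to $\sigma^2_{e1} = \sigma^2_{e2} = \sigma^2_\epsilon$ with
$\rho(e_1,e_2) = -0.5$, which recomposes to $\sigma^2_\epsilon$ exactly. The
preset grids that vary the error correlation keep $\sigma^2_\epsilon$ fixed
and use the symmetric split
$\sigma^2_{e1} = \sigma^2_{e2} = \sigma^2_\epsilon/(2+2\rho_e)$: the
recomposition identity then holds for any $\rho_e > -1$, and the default is
recovered at $\rho_e = -0.5$. Constructor validation rejects any explicit
split that fails the identity beyond 1e-9 relative.

## Expected responses

Every expectation is an instance of the truncation-selection kernel
(`response_kernel()`)

$$\Delta G = \theta\,\varphi\; \frac{i}{\sigma_I}\;
  \mathrm{Cov}(I, \text{transmitted value}),$$

with $i$ the Gaussian selection intensity ($i = \phi(z_p)/p$,
`selection_intensity()`), $\theta \in \{1,2\}$ the number of sexes under
selection and $\varphi \in \{1, 1/2\}$ the half-sib/topcross
parent–offspring coefficient. The criterion is a linear index on the
observed species contributions, $I = \alpha_1 x_1 + \alpha_2 x_2$; the plain
mixture performance is the unit-weight special case.

Key structural facts the implementation preserves (and the test suite
asserts):

* **Conservation**: the mixture response is the sum of the two
  species-contribution responses, in every scheme and flavor.
* **Interactions are not inherited** under SRMA: pairings are re-randomized
  each cycle, so $(va)$ variances inflate the criterion variance but never
  the transmitted covariance. Hence the before/after-recombination gap
  $\delta G - \Delta G = i\,\sigma^2_{d12}/\sigma_y$ at unit weights and
  $\theta\varphi = 1$.
* **Scale invariance**: responses are invariant to a joint positive
  rescaling of an index's weight pair (criterion variances are degree-2
  homogeneous).
* Pure-stand correlative responses depend on `eta`, `omega` and the design
  heritability only — never on `rho_va`, and the pure-stand genetic variance
  cancels out of the response entirely.

## Index tuning

Breeders usually need the two species' contributions to move in controlled
proportions, not merely the total to rise.

**SRMA.** The design tests each family in a single pair, so the direct and
associate components are not separately estimable and only the
*before-recombination* responses can be targeted. `solve_srma_index()`
solves the 2×2 linear system
$\{\alpha_1\sigma^2_{Gx1} + \alpha_2 C = k_1;\;
   \alpha_1 C + \alpha_2\sigma^2_{Gx2} = k_2\}$
($C$ the contribution covariance); the before-recombination ratio then
equals $k_1/k_2$ exactly, while the after-recombination ratio departs from
it through the interaction terms. The departure grows with the asymmetry of
the interaction variances; it is *reported*, never asserted equal to the
target. Negative solved weights are legitimate (penalizing one observed
contribution) and trigger a warning, not an error. A singular contribution
covariance matrix (perfectly correlated contributions) is reported as an
unsolvable target.

**SGMA.** With four weights (one pair per parallel process) and one ratio
constraint there are many solutions; `optimize_sgma_indices()` returns the
one maximizing the cumulated mixture response. The constraint is imposed in
product form $\Delta G_{x1} k_2 - \Delta G_{x2} k_1 = 0$ to stay well
behaved when a response crosses zero. Because each process's responses are
scale-invariant in its own weights, each index reduces to an angle
$t$, weights $(\cos t, \sin t)$, and both objective and constraint are sums
of a function of $t_1$ and a function of $t_2$. The optimizer does a
deterministic one-degree scan over $t_1$, solves the constraint exactly in
$t_2$ for every candidate (all sign-change brackets on the circle, refined
by `uniroot` to 1e-12), and polishes $t_1$ with a derivative-free 1-D
search around the best cell. Both halves of the circle are searched: the
optimum may accept a slightly negative companion-species response in each
process, compensated by the partner process. A dense 721×721 independent
grid oracle in the test suite is required not to beat the optimizer by more
than 1e-4. Since antipodal angles negate a process's responses, the
constraint pieces have sign-symmetric ranges and any ratio target is
feasible; the infeasibility branch is a defensive guard.

Note that meeting a cumulated ratio of 1 does **not** mean each process
meets ratio 1 — in asymmetric settings the per-process ratios deviate in
opposite directions, which the tests assert.

## Monte-Carlo oracle

`simulate_cycle()` draws candidate effects from the model's
multivariate-normal structure, averages plot errors over the M
observations, applies the index, truncates the top `rate` fraction (exact
top-k, ties broken by candidate id — a measure-zero event) and records
realized gains, replicated over independently seeded cycles (replicate r
derives its seed from the base seed and r, so results do not depend on
execution order). Transmission is represented by the $\theta\varphi$
coefficient applied to the selected parents' mean direct/associate effects:
the oracle validates the covariance algebra, which already averages over
Mendelian sampling, so meiosis is deliberately not simulated.

One exactness subtlety: the closed forms use the infinite-population
intensity $i = \phi(z)/p$, while selecting the top k of n finite candidates
realizes the slightly smaller exact expectation of the mean of the top k
Gaussian order statistics. `finite_selection_intensity(n, k)` computes that
expectation by numerical integration, and all Monte-Carlo comparisons
center their 3-standard-error bands on the analytic value rescaled by
$i_{n,k}/i_\infty$ (about 0.5% at 300 candidates, 1% at 150). This is
exact-expectation centering, not a tolerance adjustment.

The pure-stand simulator needs the *joint* distribution of
$(p, v, a)$, so it validates positive definiteness of the implied
correlation matrix and refuses non-realizable combinations. The analytic
formulas are linear in the individual covariances and are well defined on
such grids; several published-style parameter corners (e.g. `eta = 0.75`,
`omega = 0.5`, `rho_va = -0.75`) are of this non-realizable kind, which is
why the Monte-Carlo checks of the pure-stand scheme run at realizable
points only.

What the simulator emulates — and what it does not: it reproduces the
model's Gaussian effect structure, the trial design arithmetic and
truncation selection, so agreement demonstrates the internal correctness of
the closed forms. It does not probe non-Gaussian effects, epistasis,
polysomic inheritance, estimation error in the variance components, or
multi-cycle drift; passing tests therefore say nothing about those aspects
of real data.

## Numeric investigation grids

`grid_spec()` / `run_grid()` reproduce the standard comparison settings as
deterministic tables: unit direct variances, $\sigma^2_\epsilon = 2$, M = 3,
rates 10% (SRMA) / 20% (parallel schemes) — with 900 plots that is 300
vs 150 candidates tested and 30 selected per species — $\theta\varphi = 1$,
interaction variances half the companion associate variance, and a shared
`rho` for the three correlations. The `rho` axis uses 17 points from −1 to
1 (step 0.125), a resolution choice of this package; curve values read off
published plots are never asserted, only prose-stated orderings and signs.
`plot_grid()` renders the tables with ggplot2.

At the reference parameter point (`rho = -0.5`, associate variances 0.5,
interaction variances 0.25):

```{r heritability}
p <- mixture_params(species_params(1, 0.5, rho_va = -0.5),
                    species_params(1, 0.5, rho_va = -0.5),
                    var_va_12 = 0.25, var_va_21 = 0.25,
                    rho_va12_va21 = -0.5, var_plot_error_mixture = 2)
round(design_heritability(p, basic_design("srma"), "srma"), 2)
round(design_heritability(p, basic_design("sgma"), "sgma"), 2)
```

## Numerical choices and limitations

* Algebraic identities are tested at 1e-12/1e-9 relative tolerance; the
  index solver uses dense `solve()` on the 2×2 system with a determinant
  guard at 1e-12 of the squared matrix scale.
* `candidates_selected()` rounds half-up with a floor of one (the rounding
  rule linking the 10%/20% rates to exactly 30 selected is a convention of
  this package).
* Monte-Carlo tests use 500 replicate cycles (300 pairs for SRMA, 150
  candidates per process for SGMA) and 3-SE bands — about a 0.3% false-alarm
  rate per check under correct code; criterion-variance checks use 50,000
  simulated pairs. These sizes keep the default suite under a minute of
  simulation while leaving the bands a few times wider than the residual
  numerical error.
* Infinite-population selection intensity is used in all closed forms (no
  finite-sample correction), matching the published 1.75/1.40 values;
  the finite-sample expectation is available separately and used only to
  center Monte-Carlo bands.
* Out of scope: more than two species, multi-cycle responses (drift,
  inbreeding, changing variances), epistasis, non-additive polysomic cases,
  estimation of the variance components from field data, and designs
  testing one family in several pair mixtures.
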