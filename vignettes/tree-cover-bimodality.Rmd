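---
title: "Switched fire dynamics and tree-cover bimodality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switched fire dynamics and tree-cover bimodality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firetree)
```

## The model

`firetree` simulates the yearly dynamics of tree cover in moist savannas
and tropical forests as a *Markov jump linear system*. The state
$x(t) \in [0,1]^n$ holds the cover fraction of $n$ tree size classes
(class 1 the smallest), with $\sum_i x_i \le 1$. Each year a Bernoulli
fire indicator $F(t)$ selects one of two Lefkovitch stage matrices and the
state is updated in two stages — survival/transition first, recruitment
second:

$$
x' = A_{F(t)}\, x(t), \qquad
x(t+1) = x' + a\,\bigl(1 - \textstyle\sum_j x'_j\bigr)\, e_1 .
$$

$A_{nf}$ (no fire) and $A_f$ (fire) are nonnegative with column sums at
most 1; entry $(i,j)$ is the fraction of class-$j$ cover moving to class
$i$, and column-sum deficits are mortality. Fire typically kills small
stems, knocks mid-sized stems back to the smallest class (topkill), and
leaves large trees comparatively unharmed, which is why the two matrices
are kept free-form rather than parameterized.

The fire probability closes a feedback loop: more tree cover means less
grass fuel, hence less fire. We take $p(C)$ piecewise linear in the
*effective cover* $C$ (the summed cover of a configurable subset of
classes, e.g. only those tall enough to carry canopy): $p = p_{\max}$ for
$C \le \theta_1$, $p = p_{\min}$ for $C \ge \theta_2$, linear in between,
and a step function in the degenerate case $\theta_1 = \theta_2$. Defaults
$p_{\max} = 1$, $p_{\min} = 0$ anchor the curve at certain fire under
heavy fuel and no fire once fuel is sparse; both are configurable, and the
three-class demonstration deliberately uses $p_{\max} = 0.95$ (not every
dry year carries an ignition).

Because fire begets low cover and low cover begets fire, the switching
process is persistent in both directions: fire years cluster, and long
quiet spells alternate with long burning spells. The central phenomenon
the package quantifies is that this *switching between two globally
stable linear dynamics* — without any bistability — can produce a bimodal
long-run distribution of tree cover.

### Design choices in the update rule

Three decisions were genuinely open and are fixed as follows:

* **Recruitment form.** Recruitment enters additively in the smallest
  class, proportional to the free space left after the survival update:
  $b = a\,(1-\sum_j x'_j)\,e_1$. This is the simplest form that (i) keeps
  the state on the unit simplex for *any* valid stage matrices, (ii)
  respects the survival-then-recruitment order, and (iii) keeps the yearly
  map affine, so steady states have the closed form below. A constant
  variant $b = a\,e_1$ is available via
  `tree_model(..., recruitment = "constant")`; it does not guarantee
  simplex invariance, so the step errors if cover would exceed 1.
* **Fire-draw timing.** $F(t)$ is drawn from $p$ evaluated at the
  *pre-update* state $x(t)$: the fuel that carries a fire exists before
  that year's mortality.
* **Effective cover.** The feedback reads a class subset so that, e.g.,
  seedlings (which carry no canopy and suppress no grass) can be excluded,
  as in the three-class demonstration where classes 2–3 drive fire.

## Steady states and stability

Holding one dynamic fixed, the yearly map is affine,
$x \mapsto \tilde A x + a e_1$ with
$\tilde A = (I - a\,e_1 \mathbf 1^\top) A$, and has the unique fixed point

$$ x^* = (I - \tilde A)^{-1} a\,e_1 $$

whenever the spectral radius of $\tilde A$ is below one. `steady_state()`
evaluates this closed form (the *undisturbed* state for $A_{nf}$, the
*disturbed* state for $A_f$); `simulate_tree_cover(..., forced_fire =)`
converges to it geometrically, which the test suite checks to $10^{-8}$
over 2000 years for random configurations.

For the switched system, boundedness under arbitrary switching is
guaranteed when every product of update maps contracts, for which a
sufficient condition is that each $\tilde A$ has norm below one in a
submultiplicative norm. `stability_check()` reports two norms per dynamic:
the induced 1-norm (maximum absolute column sum) — the operative
criterion, natural here because column sums are survival totals — and the
maximum-element norm scaled by $n$, which upper-bounds it. The bare
maximum-element norm is not submultiplicative without the factor $n$,
which is why the scaled version is reported.

## The Ulam chain

To get the long-run cover distribution without simulation error, the
state space is discretized: each axis is cut into $k = 1/\Delta$ half-open
cells $[l, l+\Delta)$ (last cell closed), and the hypercubes whose
*center* satisfies $\sum_i c_i \le 1$ become the states of a finite Markov
chain. The center test matches how the per-cell fire probability
$p_i = p(C(\text{center}_i))$ is evaluated; an any-point acceptance test
would admit cells whose center is infeasible and leave $p_i$ undefined.

Each dynamic yields a conditional transition matrix whose entry $(i,j)$ is
the proportion of cell $i$ mapping into cell $j$:

* for $n = 1$ the affine maps are monotone, so the image of a cell is an
  interval and the row is computed **exactly** from normalized overlap
  lengths;
* for $n > 1$ a regular sub-grid of `samples_per_axis`$^n$ points per cell
  (default 5 per axis), restricted to points inside the simplex, is
  propagated and destination cells are counted. Images that float noise
  pushes just outside the accepted set are reassigned to the nearest
  accepted center.

The total-probability mixture
$T_{i\cdot} = (1-p_i)\,T^{nf}_{i\cdot} + p_i\,T^{f}_{i\cdot}$ gives the
chain, and its stationary vector $w$ ($wT = w$, $\sum w = 1$) is the
long-run occupancy of cover states. `stationary_distribution()` uses power
iteration from the uniform vector (step tolerance $10^{-13}$) with a
direct linear solve — one equation replaced by the normalization — as
fallback and cross-check; the residual $\lVert wT - w\rVert_1$ must be
below $10^{-10}$ or the solver errors. Structure is checked first via
strongly connected components (`ergodicity_check()`): with a unique closed
communicating class the solve is restricted to it (degenerate fire limits
produce exactly this), with several closed classes the stationary vector
is not unique and a convergent iterate is returned with a warning and
`unique = FALSE`.

All grids used by the package are small ($N = 100$ states at
$\Delta = 0.01$ for one class; $N = 165$ at $\Delta = 0.1$ for three
classes), so transition matrices are stored dense; the matrix-market
export in `write_results()` is the interchange format, not the working
representation.

## Statistics

**Permanence ratios.** The fractions of post-burn-in years spent under
each dynamic. The burn-in default is 100 years, excluding the transient
influenced by the initial state.

**Fire chain.** The empirical $2\times 2$ transition matrix of the fire
indicator. Its diagonal exceeding the marginal fire frequency is the
signature of fire clustering, i.e. of the feedback.

**Histograms.** All cover histograms use half-open bins $[l, l+\Delta)$
(last closed) with centers $l + \Delta/2$, the same convention as the
state grid; the standard analysis bin width is 0.1.

**Bimodality index.** $B = |\mu^* - \mu|$, where $\mu$ is the histogram
mean $\sum_k c_k f_k / \sum_k f_k$ of the full cover distribution and
$\mu^*$ the histogram mean, *with the same bins*, of the years belonging
to the more frequent dynamic. Both means use the binned estimator so that
the two are directly comparable; the raw (unbinned) trajectory mean is
reported alongside. When both dynamics are sticky, the dominant dynamic's
mode sits far from the overall mean and $B$ is large; a distribution with
$B \ge 0.1$ is classified bimodal. Exact dominance ties are broken toward
no-fire and flagged. For a chain, stationary mass replaces year counts:
the expected fire weight is $\phi = \sum_i w_i p_i$, fire dominates when
$\phi > 0.5$, and $\mu^*$ is the cover mean under $w_i p_i$ (or
$w_i(1-p_i)$) renormalized and rebinned to the same bin width as the
trajectory estimate. Whether the overall mean is taken from the chain or
from a trajectory is immaterial at the agreement level the tests enforce
(chain and trajectory $B$ agree within 0.02 for the scalar bimodal
reference).

## Reference configurations

The demographic rates behind the demonstrations are package choices,
selected once for ecological plausibility:

* `reference_model()` — retentions 0.9 (no fire) / 0.4 (fire),
  recruitment 0.1, thresholds 0.2/0.8. Its steady covers are
  $10/19 \approx 0.526$ and $0.15625$. Because the disturbed steady cover
  lies below $\theta_1$, fire recurs every year once cover drops under
  0.2: the model is a clean single-attractor baseline whose chain and
  simulation must agree exactly, and its fire-probability values at the
  steady states illustrate the feedback geometry.
* `resprouter_model()` — retentions 0.93/0.3 with recruitment 0.5,
  representing fire-adapted savanna trees that resprout vigorously.
  Fast post-fire recovery is essential for bimodality under a feedback
  anchored at $p_{\max}=1$, $p_{\min}=0$: with slow recovery (e.g. the
  reference demography) a single fire crashes cover into the fire-prone
  range faster than the system can climb out, and the fire dynamic
  dominates for *every* feasible threshold pair — the measured $B$ never
  reaches 0.1. With recovery crossing the danger zone in a couple of
  years, threshold pairs putting low fire risk at the undisturbed state
  and high risk at the disturbed one make both states sticky, and $B$
  reaches 0.10–0.15.
* `bimodal_reference_model()` — the resprouter demography with thresholds
  solved by `invert_fire_thresholds()` so that $p = 0.05$ at the
  undisturbed and $p = 0.9$ at the disturbed steady state; the canonical
  bimodal, fire-clustering configuration.
* `three_class_model()` — a synthetic three-class Lefkovitch pair (fast
  seedling-to-sapling growth without fire; heavy small-stem kill, topkill
  of mid-stems and moderate large-tree loss with fire), with the feedback
  reading classes 2–3 only and $p_{\max} = 0.95$. It alternates between a
  forest-like state (tall cover $\approx 0.87$) and an open savanna state
  (tall cover near 0), with strongly clustered fires. The rates are
  illustrative, not estimates for a particular species.

## Sensitivity sweeps

`sensitivity_demographic()` sweeps the scalar retentions over the triangle
$0 < \alpha_f \le \alpha_{nf} \le 1$ (fire cannot improve survival),
holding recruitment and the fire curve fixed; `sensitivity_fire()` sweeps
the target fire probabilities at the two steady states over the triangle
$0 < p(x^*_{nf}) < p(x^*_f) < 1$, inverting each target pair to
$(\theta_1, \theta_2)$ and skipping pairs whose thresholds escape
$[0, 1]$. Infeasible points are absent from the result, not zero-filled.
Each feasible point is scored by $B$ and mean cover from a fresh 5000-year
simulation with a counter-derived child seed, so grids are reproducible
from the master seed alone. The maps show the three regimes: fast-growing,
fire-resistant demographies collapse to a high-cover unimodal state;
slow-growing, vulnerable ones to a low-cover unimodal state; fast growth
with high vulnerability — both dynamics strongly attracting — yields
bimodality.

## Ensembles (spatial sampling)

Field tree-cover distributions pool many sites at one instant rather than
one site through time. `run_ensemble()` mimics this: each site draws its
parameters uniformly from per-parameter intervals (optionally a union of
two disjoint intervals, or several named regimes among which sites are
split evenly) and runs independently; covers and fire status are pooled at
the sampling year (default 300, safely past the 100-year burn-in) and
scored with `pooled_bimodality()`. Site $i$ uses the child seed
`child_seed(master, i)` for both its parameter draw and its fire sequence,
so ensembles are reproducible bit-for-bit and embarrassingly parallel in
principle. Two default designs ship with the package:
`ensemble_ranges_bimodal()` draws every site from the bimodal band of the
sensitivity maps, and `ensemble_regimes_high_low()` mixes a high-cover
unimodal regime with a low-cover unimodal one — pooling the latter is
bimodal even though every single site is unimodal, which is the caveat the
spatial-sampling experiment is designed to expose.

## Numerical conventions

* Simplex tolerance: results within $10^{-9}$ of the boundary are clipped;
  larger violations raise errors rather than being silently repaired.
* Bin and cell assignment: half-open intervals with the last one closed;
  boundary values are nudged by $10^{-9}$ relative slack before flooring
  so that exact boundaries land deterministically.
* Power iteration: tolerance $10^{-13}$ on the L1 step, residual gate
  $10^{-10}$, direct solve as fallback; small-chain solutions match an
  independent eigen decomposition to $10^{-12}$ in the tests.
* Problem sizes used by the tests and the acceptance script: single-site
  runs of 5000 years (the standard analysis length), one $10^6$-year run
  for the chain-versus-simulation oracle, $10^5$-year runs for rate
  comparisons, 20-value-per-axis sensitivity grids, and 1000-site
  ensembles sampled at year 300.

## What the generator does and does not emulate

The experiments generate all their own data; no field data enter the
package. The generator reproduces the structural features the analysis
targets — state-dependent disturbance switching, stage structure,
fire clustering, pooled spatial sampling — but real landscapes differ in
ways the model deliberately ignores: space is implicit (no fire spread,
no seed dispersal between sites; ensemble sites are fully independent),
grass biomass enters only through the cover-dependent fire probability
rather than as a state variable, rainfall and other environmental forcing
are absent, and demographic rates are constants rather than estimates
with uncertainty. Passing tests therefore show that the *mechanism*
behaves as claimed, not that any particular landscape follows these
parameter values.

## Known limitations

* The bimodality index compares a dominant-dynamic mean with an overall
  mean; it detects the two-mode structure produced by switching but is
  not a general multimodality test (no kernel density or dip statistics).
* Ulam discretization evaluates fire probability at cell centers; with
  very steep feedback curves and coarse grids this biases the mixture
  near the thresholds. The tests pin the error at $\Delta = 0.01$ for the
  scalar model (total variation below 0.02 against a $10^6$-year run).
* The sufficient stability condition (1-norm contraction) is conservative;
  switched systems can be stable without satisfying it.
* For $n > 1$ the transition matrices are sampled, not exact; accuracy is
  controlled by `samples_per_axis` and the defaults are adequate only for
  the coarse ($\Delta = 0.1$) grids the package uses at $n = 3$.
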