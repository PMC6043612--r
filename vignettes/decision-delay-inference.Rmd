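---
title: "Dating hidden cell-fate decisions from delayed marker onsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating hidden cell-fate decisions from delayed marker onsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaytree)
```

## The problem

In time-lapse movies of dividing cells, lineage commitment is read out by a
marker (a surface antigen, a fluorescent reporter) that turns on only long
after the decision it reports. In a single, non-dividing cell the decision
time is unidentifiable: any combination of decision time and delay that sums
to the observed onset fits equally well. Division breaks this degeneracy.
If a cell decides and then divides before the marker is detectable, both
daughters inherit the partially accumulated expression state and will cross
the detection threshold at similar times. The correlation pattern of onsets
among sisters and cousins therefore carries the delay length, and with it
the decision time. `delaytree` implements the corresponding generative
model, its tree likelihood, maximum-likelihood fitting, and the validation
machinery around it.

## The generative model

Two independent stochastic processes per lineage:

**Decision process.** An undecided cell decides with hazard
$\lambda(t) = \max(0,\, a_0 + a_1 t)$ on the absolute movie clock
($t = 0$ at movie start), independently in every cell. The event density is
$\phi(t) = \lambda(t)\, e^{-\int_0^t \lambda}$ and the cumulative
distribution $\Phi(t) = 1 - e^{-\int_0^t \lambda}$. The linear form is a
first-order approximation to an unknown, slowly varying commitment rate.
Two design choices deserve a note:

* *Clipping.* A fitted decreasing hazard ($a_1 < 0$) would go negative at
  late times; we clip it at zero, which makes $\phi$ a valid sub-density.
  The missing mass $e^{-a_0^2/(2|a_1|)}$ is the probability that a lineage
  never commits; the tree likelihood is consistent with that through its
  survival factors.
* *Absolute clock.* The hazard runs on experiment time, not cell age: the
  decision probability is assumed to depend only on non-inherited factors,
  and one global $\Phi(t)$ is fitted per fate class.

**Delay process.** From the decision onward, marker expression is a
birth–death process on copy numbers: production at rate $\alpha$ (zeroth
order), degradation at rate $\gamma x$, starting at $x_0 = 0$. The marker
becomes detectable when $x$ first reaches the threshold $x^\*$; states
$0..x^\*-1$ form a Markov chain with an absorbing boundary. The package
solves the master equation by matrix exponentials and exposes the
first-passage density $\psi_{x_0}(t)$ (the flux $\alpha
P_{x_0 \to x^\*-1}(t)$) and the sub-threshold propagator
$P_{x \to x'}(t)$. At division both daughters *copy* the mother's
sub-threshold state by default; `x` is an abstract expression state rather
than a literal molecule count, and copying is what makes sister onsets
similar. A binomial-partition mode is available behind a flag for
sensitivity analyses and is the default in the toggle-switch simulator,
where molecule counts are literal.

## The hidden-tree likelihood

An observed genealogy with onsets is compatible with many decision
scenarios ("hidden trees"): any antichain of cells such that every onset
lies at or below a decision cell; cells unrelated to any onset may or may
not carry an invisible decision whose expression never reached threshold.
The likelihood of a tree is the sum over all scenarios; each scenario
factorises into the undecided part $U$ (per-cell survival factors
$e^{-\int \lambda}$ over the lifetime) and decision-rooted subtrees $D_i$.

Within a $D_i$ the root's latent decision time $t'$ is integrated against
$\lambda(t')\,e^{-\int_{b}^{t'}\lambda}$ (conditioned on survival to the
root's birth $b$; ancestors' survival lives in $U$, so nothing is counted
twice), and the delay process is propagated down by sum–product messages:
vectors over the sub-threshold states, multiplied by the propagator within
a cell, combined at divisions (pointwise product of the daughters' messages
under copy inheritance — the daughters are conditionally independent *given*
the mother's division-time state, so the message must marginalise jointly
over that state), terminated by the first-passage flux at onset leaves and
by the remaining sub-threshold mass at censored leaves.

The scenario sum is evaluated without enumeration by a post-order dynamic
programme carrying, per cell, (a) the decided message vector and (b) the
undecided scalar that adds "decide here during this lifetime" and "do not
decide here" contributions. The same recursion with max instead of sum
gives the MAP scenario, and a k-best variant returns ranked alternatives.
Everything is scaled per cell in log space. An explicit-enumeration route
through the same exported building blocks (`enumerate_hidden_trees()`,
`likelihood_undiff()`, `likelihood_subtree()`) exists for verification and
matches the DP to machine precision on random trees.

Cells below an onset cell are pruned from the likelihood: the delay process
is absorbed at the onset, so the subtree underneath carries no further
information (and the data model forbids annotating further onsets there).

### Numerical choices

* All event times are snapped to a uniform grid (default `h = 0.25` h),
  and the propagator is precomputed on that grid as cumulative powers of
  `expm(Q h)`, so each likelihood evaluation costs one small matrix
  exponential plus dense linear algebra per cell.
* The decision-time integral uses the *exact* per-interval decision mass
  $e^{-\Lambda(b,t_j)} - e^{-\Lambda(b,t_{j+1})}$ times the trapezoid
  average of the delay factor. Quadrature of the density itself
  (e.g. a plain trapezoid of $\lambda e^{-\Lambda}$) overestimates the
  integral grossly when the hazard scale drops below the grid step and
  creates spurious likelihood optima at huge hazards; the exact-mass rule
  is stable for hazards of any magnitude. Halving `h` changes
  log-likelihoods well below optimizer tolerances; tests verify convergence
  towards continuum quadrature oracles.
* Ties in the MAP search (within 1e-12 log units) prefer the scenario with
  fewer decision cells, i.e. the earlier decision; this makes predictions
  deterministic.

## Fitting

`fit_genealogies()` maximises the summed log-likelihood over trees
(GM-fated and MegE-fated sets are fitted separately: their delay processes
differ). The optimiser is a staged multistart. A Latin-hypercube sample
over the parameter box — log-scaled for the rates `alpha` and `gamma`,
which span decades — plus a set of deterministic anchor points (a few
hazard scales crossed with delay means of hours to days at each threshold
value; the relevant `alpha` scales with `x_star`, which random box
sampling easily misses) is screened with one likelihood evaluation each on
a coarse time grid. Bounded Nelder–Mead searches (on logit-transformed
coordinates, restarted with a fresh simplex until they stop improving)
then start from the best screened point of each `x_star` value — the
likelihood's basins cluster by threshold, and taking the global top-k
starts tends to drop them all into one basin — and the best search result
is re-polished on the fine grid. The integer threshold `x_star` is
profiled on a grid. Default bounds —
$a_0 \in [0,1]$/h, $a_1 \in [-0.05, 0.05]$/h², $\alpha \in [0.01, 5]$/h,
$\gamma \in [0,1]$/h, $x^\* \in \{5,\dots,100\}$ — cover decision waiting
times of minutes to days and delays of hours to days at ~12 h cell cycles.
The fit is deterministic given `rng_seed`; per-restart traces are kept for
diagnostics. No confidence intervals are reported. Note that $\alpha$ and
$x^\*$ trade off against each other (the delay mean is approximately
$x^\*/\alpha$ for small $\gamma$), so a coarse `x_star_grid` mostly costs
resolution in the delay *shape*, not its location.

`mean_delay()` reports the mean decision-to-onset interval of the fitted
model. Its default is a Monte-Carlo estimate from the forward simulator in
which each onset is weighted by $2^{-d}$ ($d$ = divisions since the
decision): this is the delay of a single lineage followed downward from the
decision. Without the weight, long-delayed branches would dominate simply
because they have divided more often by the time they cross. Under copy
inheritance a single lineage's delay is exactly the first-passage time of
the birth–death process, so `method = "analytic"` (the mean of
$\psi_0$ from the master equation) gives the same number without
simulation noise; the two agree within Monte-Carlo error in the tests.

## The forward simulator

`simulate_trees()` draws genealogies from the model itself: gamma cell
cycles (default 12 ± 5 h, optionally longer in the first generations, as
freshly activated stem cells cycle slowly), a 120 h observation window,
decisions from the clipped linear hazard on the absolute clock, Gillespie
expression dynamics after the decision, state inheritance at division, and
right-censoring at movie end (or by an optional tracking-loss rate; "lost"
and "movie end" censor identically in the likelihood). Onsets are terminal
per branch, as in tracked movies where annotation stops at first detection.
Ground-truth decision cells and times travel along as an attribute.

What the simulator deliberately does *not* emulate about real movies:
measurement noise in onset calls, biased/partial manual tracking,
spatial effects, fate-dependent cell-cycle changes, or multi-gene delay
cascades. Passing recovery tests on these synthetic data therefore shows
the estimator is consistent under the model's own assumptions — not that
the model is true for any particular biological dataset.

One practical guard: with a hazard that decays to zero, never-deciding
lineages keep proliferating in long simulated movies; `stop_undecided_at`
drops still-undecided branches after a cutoff (ending them as "lost"),
which leaves decision and onset statistics untouched. It is used
internally for delay estimation with long horizons.

## Colony branching model

The per-generation decision probabilities
$\lambda(i) = E_{s_i, c_i}[1 - e^{-\int_{s_i}^{s_i+c_i} \lambda}]$ are
obtained by joint lineage sampling (birth times accumulated from the same
cycle draws). The pure-colony frequency follows the recursion
$f(N, i) = \lambda(i) p + (1-\lambda(i)) f(N-1, i+1)^2$ with
$F_{GM}(N) = f(N, 1)$, and the mixed frequency is the complement — which
classifies colonies with any still-undecided lineage as mixed, a modelling
convention forced by the complement definition. `N = 10` generations is
the default (a ten-day assay at ~12 h cycles is past that; the frequencies
have stabilised in `N` well before). A direct Monte-Carlo branching
simulation (`simulate_colony_assay()`) serves as the independent check and
agrees within binomial error.

## Toggle switch

The mutual-repression toggle is a stand-in with documented phenomenology
rather than a fixed literature parameterisation: production of each species
is Hill self-activation plus repression by the other
($\mathrm{act}\,X^n/(K^n+X^n) + \mathrm{rep}\,K^n/(K^n+Y^n)$), degradation
linear. The shipped defaults (`act = rep = 5`/h, `K = 10`, `n = 4`,
`deg = 0.25`/h) put the progenitor state near (20, 20) copies and the
committed states near (40, 0)/(0, 40), with noise-driven escape on the time
scale of one to a few cell cycles — slow enough that commitment is not
immediate, fast enough that most lineages commit within a 72 h movie. The
quasi-potential is estimated from an *ensemble* of runs started in the
progenitor region (committed wells are effectively absorbing, so one long
run cannot visit all basins); tristability is verified at set-up and the
basin geometry (linear separatrices through the occupancy barrier between
central and committed wells, perpendicular to the connecting segment) is
derived from it. Basin entry of a lineage's trajectory defines its marker
onset, molecules are binomially partitioned at division, and the exported
tables feed the same inference stack as the main simulator.

Two lessons from building this validation deserve a note, because both are
statements about identifiability rather than implementation:

* *Founding cells must be equilibrated.* Started exactly at the central
  fixed point, the ensemble's relaxation transient produces a burst of
  early escapes synchronised to the movie start — and the inference,
  correctly, reads this as an early shared decision at the root.
  `simulate_toggle_trees()` therefore equilibrates each founder inside the
  progenitor basin for a burn-in period (rejecting founders that commit
  during burn-in), emulating the sorting of undifferentiated progenitors
  before imaging. After equilibration, escapes are memoryless per lineage
  and scatter across generations.
* *The unrestricted delay family contains the escape process itself.* A
  birth–death delay tuned near criticality (`alpha/gamma` just below
  `x_star`) hovers under the threshold and crosses it as a rare,
  memoryless event whose propensity is inherited at division — which is
  statistically equivalent to the toggle's own basin escape. An
  unrestricted fit can therefore explain toggle genealogies as "one
  decision at the root plus escape-like delay", relocating every predicted
  decision to generation 0. For the toggle analysis the fit restricts the
  delay to the degradation-free (Erlang) regime (`gamma` bounded at
  effectively zero), which cannot mimic a memoryless escape; the predicted
  decisions then coincide with the tilt of the switch, reproducing the
  up-/down-regulation signature at relative generation 0.

## Slope statistics

`fit_cell_slopes()` fits an ordinary least-squares line to each cell's
concentration (intensity/area) over its lifetime; slopes are grouped by
generation relative to the predicted decision cell (−1 mother, 0 decision
cell, +1 daughters, plus the onset-cell group) and compared by two-sided
Wilcoxon rank-sum tests (exact where `wilcox.test` can be exact, normal
approximation with tie correction otherwise; no continuity correction so
identical samples give p = 1; no multiple-testing correction — raw
p-values are reported). Slopes are pooled across trees within a fate
class. On toggle-simulated data this pipeline shows strong up-/down-
regulation at relative generation 0; on data from the decision+delay model
with decision-independent tracks it is null — the package's positive and
negative controls.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run at desk scale: 200 random
trees of up to 15 cells for the enumeration equivalence; 200 simulated
genealogies per seed (10 seeds) for parameter recovery with a reduced
multistart (a 120-point screen, 3 local searches, `x_star` on a 7-point
grid); 10⁵-colony Monte-Carlo checks per colony parameterisation; and a
400-genealogy toggle experiment. These sizes were chosen so the
whole suite runs in tens of minutes on a single core while keeping every
statistical margin comfortable; all of them can be scaled up by arguments.

## Known limitations

* The hazard is global and time-linear; covariates (space, signalling) are
  out of scope.
* Decision-time *marginals* per cell are not exposed, only scenario-level
  MAP/k-best (the posterior mean of the decision time within a scenario is
  available for alignment plots).
* The delay is a single birth–death stage; gene cascades are represented
  only insofar as this process approximates them.
* `x_star` is fitted on an integer grid; likelihood differences between
  neighbouring thresholds are often small (the $\alpha$–$x^\*$ trade-off),
  so the reported threshold should not be over-interpreted.
* Absolute-time hazards make fits sensitive to how "movie start" is
  defined; synchronised experiment starts are assumed.
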