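# delaytree

Dating unobserved cell-fate decisions from delayed, correlated
lineage-marker onsets in single-cell genealogies.

## The problem

In time-lapse microscopy of differentiating cells (the motivating system is
hematopoietic progenitors choosing between the granulocyte–macrophage, GM,
and the megakaryocytic–erythroid, MegE, lineage), commitment is detected by
a lineage marker that turns on hours to days *after* the decision. In a
non-dividing cell the decision time is unidentifiable. But cells divide:
if a cell decides and divides before the marker reaches its detection
threshold, both daughters inherit the partially accumulated expression
state, and their onset times become correlated. Those correlations across
sisters and cousins identify the delay — and thereby the decision time.

## The model

Per lineage, two processes:

* **Decision**: a memory-less hazard, linear in absolute movie time and
  clipped at zero,

  λ(t) = max(0, a₀ + a₁ t),    ϕ(t) = λ(t) e^(−∫₀ᵗ λ),    Φ(t) = 1 − e^(−∫₀ᵗ λ).

* **Delay**: from the decision, marker expression is a birth–death process
  (production α, degradation γx) started at x₀ = 0; the marker is detected
  when the copy number first reaches x\*. The sub-threshold states form a
  Markov chain with an absorbing boundary whose master equation gives the
  first-passage density ψ(t) and the propagator P(t). At division both
  daughters copy the mother's sub-threshold state.

A genealogy with onsets is compatible with many decision scenarios
("hidden trees": antichains of decision-bearing cells covering every
onset). The tree likelihood sums over all of them,

  L(T | θ, η) = Σ_H L(H | θ, η),   L(H) = L(U | θ) · Π_i L(D_i | θ, η),

where U is the undecided part and each decision-rooted subtree D_i
integrates the latent decision time against sum–product messages over the
expression state. The sum is evaluated by a post-order dynamic programme
(C++ core); max instead of sum gives the MAP scenario and a k-best list.
Parameters θ = (a₀, a₁) and η = (α, γ, x\*) are estimated by
maximum likelihood with Latin-hypercube multistart optimisation, x\*
profiled on an integer grid.

Around the estimator the package ships the paper-style validation
machinery: a forward simulator of annotated genealogies (the ground-truth
generator for recovery experiments), a branching-process model of colony
assay frequencies driven by a generation-discretised hazard, a Gillespie
simulator of a tristable PU.1/GATA1-like toggle switch on dividing
lineages, and per-cell marker-production slope statistics with rank-sum
comparisons around the predicted decision.

## Worked example

Simulate 60 genealogies under known parameters, fit them, and predict the
decision cells:

```r
library(delaytree)
set.seed(7)

truth <- sim_config(theta = decision_params(a0 = 0.15, a1 = -0.002),
                    eta = delay_params(alpha = 0.5, gamma = 0.01, x_star = 25),
                    n_trees = 60, movie_end = 120)
trees <- simulate_trees(truth)

fit <- fit_genealogies(trees, fit_config(
  x_star_grid = c(10L, 15L, 20L, 25L, 30L, 40L, 50L),
  n_explore = 120, n_restarts = 3, maxit = 400, rng_seed = 7))
fit
#> <delaytree_fit>
#>   theta: a0 = 0.1652 /h, a1 = -0.002435 /h^2
#>   eta:   alpha = 0.4984 /h, gamma = 0.009885 /h, x* = 25
#>   log-likelihood -26665.422 over 60 trees (3 restarts)

mean_delay(fit, method = "analytic")
#> # A tibble: 1 x 2
#>   mean_delay_h n_onsets
#>          <dbl>    <int>
#> 1         67.5       NA

dec <- predict_decisions(trees, fit$theta_hat, fit$eta_hat)
predicted_decision_generation(dec)
#> # A tibble: 6 x 3
#>   generation     n fraction
#>        <int> <int>    <dbl>
#> 1          0    54   0.72
#> 2          1     8   0.107
#> 3          2     5   0.0667
#> 4          3     1   0.0133
#> 5          4     2   0.0267
#> 6          5     5   0.0667
```

The fitted parameters reproduce the generating ones (a₀ = 0.165 vs 0.15,
a₁ = −0.0024 vs −0.002, α = 0.498 vs 0.5, γ = 0.0099 vs 0.01,
x\* = 25 exactly); the mean decision-to-onset delay of the fitted model is
67.5 h, against 67.5 h for the generating model. 83% of predicted
decisions sit in generations 0–1 — generations before the first marker
onsets appear, which is the method's point.

`onset_distribution_fit(trees, fit)` compares the model-predicted and
empirical cumulative onset curves (`autoplot()` shows them), and
`map_hidden_tree(tree, fit$theta_hat, fit$eta_hat, k = 3)` ranks
alternative decision scenarios for a single genealogy.

The same stack runs from the shell via the thin CLI in `inst/cli/delaytree`
(subcommands `simulate`, `fit`, `predict`, `colony`, `toggle-sim`,
`slopes`; tab-separated cell tables as defined in `?read_genealogies`).

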