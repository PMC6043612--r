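small_fit_config <- function(seed = 1)
  fit_config(x_star_grid = c(6L, 12L), n_explore = 12, n_restarts = 2,
             maxit = 80, rng_seed = seed)

test_that("fitting is deterministic given the config seed", {
  set.seed(51)
  sim <- simulate_trees(sim_config(eta = delay_params(1, 0.02, 8),
                                   n_trees = 12, movie_end = 40))
  f1 <- fit_genealogies(sim, small_fit_config())
  f2 <- fit_genealogies(sim, small_fit_config())
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$restarts, f2$restarts)
  g <- glance(f1)
  expect_equal(g$n_trees, 12)
  expect_equal(f1$logLik, max(f1$restarts$loglik))
})

test_that("fitting without onsets warns about unidentifiable delay", {
  set.seed(52)
  sim <- simulate_trees(sim_config(theta = decision_params(0, 0),
                                   n_trees = 5, movie_end = 30))
  expect_warning(fit_genealogies(sim, small_fit_config()), "unidentifiable")
})

test_that("the optimum dominates the generating parameters", {
  set.seed(53)
  theta0 <- decision_params(0.1, 0)
  eta0 <- delay_params(1, 0.02, 8)
  sim <- simulate_trees(sim_config(theta = theta0, eta = eta0,
                                   n_trees = 40, movie_end = 50))
  cfg <- fit_config(x_star_grid = c(4L, 8L, 16L), n_explore = 80,
                    n_restarts = 6, maxit = 400, rng_seed = 2)
  fit <- fit_genealogies(sim, cfg)
  ll_truth <- sum(likelihood_tree(sim, theta0, eta0)$loglik)
  expect_gte(fit$logLik, ll_truth - 1e-6)
})

test_that("mean delay recovers the Erlang limit and grows with the threshold", {
  # gamma = 0 and no divisions: delay is Erlang(x*, alpha), mean x*/alpha
  no_div <- list(family = "gamma", mean = 1e5, sd = 1)
  set.seed(54)
  md <- mean_delay(list(theta_hat = decision_params(0.3, 0),
                        eta_hat = delay_params(0.25, 0, 20)),
                   cellcycle = no_div, n_trees = 800)
  expect_equal(md$mean_delay_h, 80, tolerance = 0.02)
  # immediate detection limit
  set.seed(55)
  md0 <- mean_delay(list(theta_hat = decision_params(5, 0),
                         eta_hat = delay_params(500, 0, 1)),
                    cellcycle = no_div, n_trees = 200)
  expect_lt(md0$mean_delay_h, 0.1)
  # monotone in x* at fixed rates (with divisions allowed)
  set.seed(56)
  md_small <- mean_delay(list(theta_hat = decision_params(0.3, 0),
                              eta_hat = delay_params(0.5, 0.01, 10)),
                         n_trees = 60)
  set.seed(56)
  md_large <- mean_delay(list(theta_hat = decision_params(0.3, 0),
                              eta_hat = delay_params(0.5, 0.01, 30)),
                         n_trees = 60)
  expect_gt(md_large$mean_delay_h, md_small$mean_delay_h)
})

test_that("onset-distribution comparison is well-formed and order-invariant", {
  set.seed(57)
  sim <- simulate_trees(sim_config(eta = delay_params(1, 0.02, 10),
                                   n_trees = 25, movie_end = 60))
  fit <- list(theta_hat = decision_params(0.15, -0.002),
              eta_hat = delay_params(1, 0.02, 10),
              inheritance_mode = "copy")
  class(fit) <- "delaytree_fit"
  set.seed(58)
  of <- onset_distribution_fit(sim, fit, n_sim_trees = 50)
  expect_true(all(of$curves$empirical >= 0 & of$curves$empirical <= 1))
  expect_true(all(diff(of$curves$empirical) >= 0))
  shuffled <- sim[sample(nrow(sim)), ]
  set.seed(58)
  of2 <- onset_distribution_fit(shuffled, fit, n_sim_trees = 50)
  expect_equal(of2$sup_distance, of$sup_distance)
})
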