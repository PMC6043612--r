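test_that("master equation conserves probability and freezes without rates", {
  eta <- delay_params(0.8, 0.1, 12)
  sol <- solve_master_equation(eta, x0 = 3, t_grid = seq(0, 40, by = 0.5))
  expect_true(all(abs(rowSums(sol$sub_threshold_prob) + sol$absorbed_mass - 1)
                  < 1e-9))
  expect_true(all(diff(sol$absorbed_mass) >= -1e-12))
  frozen <- solve_master_equation(delay_params(0, 0, 5), 2, c(0, 1, 10))
  expect_equal(frozen$sub_threshold_prob[, 3], rep(1, 3))
  expect_equal(frozen$absorbed_mass, rep(0, 3))
  # already detected at the threshold
  done <- solve_master_equation(eta, x0 = 12, t_grid = c(0, 1))
  expect_equal(done$absorbed_mass, c(1, 1))
  expect_error(solve_master_equation(eta, 13, c(0, 1)), "0..x_star")
})

test_that("pure-birth first passage is Erlang", {
  eta <- delay_params(10, 0, 20)
  grid <- seq(0, 8, by = 0.02)
  sol <- solve_master_equation(eta, 0, grid)
  # absorbed mass equals the Erlang(shape 20, rate 10) CDF
  expect_equal(sol$absorbed_mass, stats::pgamma(grid, shape = 20, rate = 10),
               tolerance = 1e-8)
  m <- first_passage_moments(eta, 0, t_max = 10, h = 0.005)
  expect_equal(m$mean_h, 2, tolerance = 1e-3)
  expect_equal(m$var_h2, 0.2, tolerance = 1e-3)
  # SSA cross-check of the first-passage CDF (KS < 0.02 at 1e4 runs)
  set.seed(42)
  cross <- replicate(1e4, sample_first_passage(eta, 0, t_max = 20)$t_cross)
  ks <- max(abs(stats::ecdf(cross)(grid) -
                  stats::pgamma(grid, shape = 20, rate = 10)))
  expect_lt(ks, 0.02)
})

test_that("first-passage density boundary and degenerate cases", {
  eta <- delay_params(0.5, 0.05, 8)
  expect_equal(first_passage_density(eta, 8, c(0, 1, 5)), c(Inf, 0, 0))
  expect_equal(first_passage_density(delay_params(0, 0.1, 8), 0, c(1, 5, 20)),
               rep(0, 3))
  psi <- first_passage_density(eta, 0, c(5, 10, 20))
  expect_true(all(psi > 0))
})

test_that("propagator satisfies identity, Chapman-Kolmogorov and flux balance", {
  eta <- delay_params(0.6, 0.08, 9)
  S <- eta$x_star
  expect_equal(delay_propagator(eta, 4, 4, 0), 1)
  expect_equal(delay_propagator(eta, 4, 5, 0), 0)
  expect_error(delay_propagator(eta, 0, 9, 1), "states")
  P <- function(t) delaytree:::bd_propagator_cpp(eta$alpha, eta$gamma, S, t)
  expect_lt(max(abs(P(3.3) %*% P(5.9) - P(9.2))), 1e-8)
  # 1 - sum_x' P_{x0 -> x'}(t) equals the integrated first-passage flux
  t_end <- 12
  grid <- seq(0, t_end, by = 0.005)
  psi <- first_passage_density(eta, 2, grid)
  n <- length(grid)                      # odd count: Simpson weights apply
  simp <- sum(psi * c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)) * 0.005 / 3
  expect_equal(1 - sum(P(t_end)[3, ]), simp, tolerance = 1e-7)
})

test_that("generator rows over the extended state space sum to zero", {
  eta <- delay_params(0.7, 0.2, 6)
  h <- 1e-6
  P <- delaytree:::bd_propagator_cpp(eta$alpha, eta$gamma, 6, h)
  Q <- (P - diag(6)) / h
  flux_out <- -rowSums(Q)            # rate into the absorbing state
  expect_equal(flux_out, c(rep(0, 5), eta$alpha), tolerance = 1e-4)
})

test_that("absorbed mass is monotone in time, alpha and the threshold", {
  grid <- seq(0, 30, by = 0.5)
  m_of <- function(alpha, xs)
    solve_master_equation(delay_params(alpha, 0.05, xs), 0, grid)$absorbed_mass
  base <- m_of(0.5, 10)
  expect_true(all(diff(base) >= -1e-12))
  expect_true(all(m_of(0.8, 10) >= base - 1e-12))
  expect_true(all(m_of(0.5, 14) <= base + 1e-12))
})
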