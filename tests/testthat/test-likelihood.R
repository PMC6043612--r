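theta_t <- decision_params(0.05, 0.001)
eta_t <- delay_params(0.6, 0.05, 6)

test_that("hidden-tree enumeration counts follow the cover recursion", {
  # single cell with onset: the decision is forced onto that cell
  one <- chain_genealogy(10, onset_last = 6)
  expect_equal(enumerate_hidden_trees(one), list("1"))
  # mother with two onset daughters: decision in mother or in both daughters
  fam <- perfect_genealogy(1, onset_leaves = TRUE)
  sc <- enumerate_hidden_trees(fam)
  expect_setequal(lapply(sc, sort), list("1", c("2", "3")))
  # depth-2 perfect tree, all four leaves onset: f(v) = 1 + f(l) f(r) = 5
  sc2 <- enumerate_hidden_trees(perfect_genealogy(2, onset_leaves = TRUE))
  expect_length(sc2, 5)
  expect_error(enumerate_hidden_trees(perfect_genealogy(5)), "enumeration")
})

test_that("undecided-part likelihood factorises and has the closed form", {
  cells <- validate_genealogies(perfect_genealogy(2))
  th <- decision_params(0.2, 0)
  # single cell with constant hazard: -lambda * lifetime
  expect_equal(likelihood_undiff(cells[1, ], th), -0.2 * 5)
  expect_equal(likelihood_undiff(cells[0, ], th), 0)
  # additivity across cells
  expect_equal(likelihood_undiff(cells, th),
               sum(vapply(seq_len(nrow(cells)),
                          function(i) likelihood_undiff(cells[i, ], th),
                          numeric(1))))
  # zero hazard: probability one
  expect_equal(likelihood_undiff(cells, decision_params(0, 0)), 0)
})

test_that("single-cell decision likelihood matches direct convolution", {
  # D = one cell [0, 12] with onset at 9: integral over the decision time of
  # decision density times first-passage density, computed independently by
  # adaptive quadrature on the continuum
  cells <- chain_genealogy(12, onset_last = 9)
  oracle <- stats::integrate(function(tp)
    decision_density(tp, theta_t) *
      first_passage_density(eta_t, 0, 9 - tp), 0, 9, rel.tol = 1e-10)$value
  fine <- likelihood_subtree(cells, "1", theta_t, eta_t, h = 0.025)
  coarse <- likelihood_subtree(cells, "1", theta_t, eta_t, h = 0.1)
  expect_equal(exp(fine), oracle, tolerance = 1e-4)
  # refinement converges towards the continuum value
  expect_lt(abs(exp(fine) - oracle), abs(exp(coarse) - oracle))
  # alpha = 0 with an onset leaf is structurally impossible
  expect_equal(likelihood_subtree(cells, "1", theta_t,
                                  delay_params(0, 0.1, 6)), -Inf)
})

test_that("three-cell message passing equals nested quadrature over the joint", {
  # mother [0,6] decides, divides at 6; both daughters onset; the daughters
  # are conditionally independent given the mother's division state, so the
  # oracle must marginalise jointly over that state
  fam <- perfect_genealogy(1, life = 6, onset_leaves = TRUE)
  fam$onset_time <- ifelse(is.na(fam$onset_time), NA,
                           c(NA, 8.5, 10.4))
  S <- eta_t$x_star
  Pm <- function(t) delaytree:::bd_propagator_cpp(eta_t$alpha, eta_t$gamma, S, t)
  oracle <- stats::integrate(Vectorize(function(tp) {
    py <- Pm(6 - tp)[1, ]                       # state distribution at division
    psi1 <- eta_t$alpha * Pm(8.5 - 6)[, S]      # per-state onset fluxes
    psi2 <- eta_t$alpha * Pm(10.4 - 6)[, S]
    decision_density(tp, theta_t) * sum(py * psi1 * psi2)
  }), 0, 6, rel.tol = 1e-10)$value
  impl <- likelihood_subtree(fam, "1", theta_t, eta_t, h = 0.025)
  expect_equal(exp(impl), oracle, tolerance = 1e-4)
  # the independence shortcut (marginalising each daughter separately) is
  # measurably different and must NOT match
  shortcut <- stats::integrate(Vectorize(function(tp) {
    py <- Pm(6 - tp)[1, ]
    psi1 <- eta_t$alpha * Pm(2.5)[, S]
    psi2 <- eta_t$alpha * Pm(4.4)[, S]
    decision_density(tp, theta_t) * sum(py * psi1) * sum(py * psi2)
  }), 0, 6, rel.tol = 1e-10)$value
  expect_gt(abs(shortcut - oracle) / oracle, 0.01)
})

test_that("DP likelihood equals explicit enumeration on random trees", {
  set.seed(1234)
  for (i in 1:50) {
    tr <- random_genealogy(max_cells = sample(3:15, 1))
    l_dp <- likelihood_tree(tr, theta_t, eta_t)$loglik
    l_en <- likelihood_tree(tr, theta_t, eta_t, method = "enumeration")$loglik
    if (is.finite(l_dp) || is.finite(l_en))
      expect_equal(l_dp, l_en, tolerance = 1e-10)
  }
  # binomial-partition inheritance agrees between the two routes as well
  set.seed(99)
  for (i in 1:10) {
    tr <- random_genealogy(max_cells = sample(5:12, 1))
    l_dp <- likelihood_tree(tr, theta_t, eta_t,
                            inheritance_mode = "binomial")$loglik
    l_en <- likelihood_tree(tr, theta_t, eta_t, inheritance_mode = "binomial",
                            method = "enumeration")$loglik
    if (is.finite(l_dp) || is.finite(l_en))
      expect_equal(l_dp, l_en, tolerance = 1e-10)
  }
})

test_that("degenerate hazards give the structural likelihood limits", {
  zero <- decision_params(0, 0)
  with_onset <- perfect_genealogy(1, life = 6, onset_leaves = FALSE)
  with_onset$onset_time[with_onset$cell_id == "2"] <- 9
  expect_equal(likelihood_tree(with_onset, zero, eta_t)$loglik, -Inf)
  no_onset <- perfect_genealogy(2)
  expect_equal(likelihood_tree(no_onset, zero, eta_t)$loglik, 0)
})

test_that("likelihood is invariant under relabeling and child swaps", {
  set.seed(5)
  tr <- random_genealogy(max_cells = 13)
  base <- likelihood_tree(tr, theta_t, eta_t)$loglik
  relab <- tr
  relab$cell_id <- paste0("x", relab$cell_id)
  relab$parent_id <- ifelse(is.na(relab$parent_id), NA,
                            paste0("x", relab$parent_id))
  expect_equal(likelihood_tree(relab, theta_t, eta_t)$loglik, base)
  swapped <- tr[order(-as.integer(tr$cell_id)), ]
  expect_equal(likelihood_tree(swapped, theta_t, eta_t)$loglik, base)
})

test_that("MAP scenario matches brute-force argmax and k-best is ordered", {
  set.seed(333)
  for (i in 1:30) {
    tr <- random_genealogy(max_cells = sample(4:12, 1))
    mh <- map_hidden_tree(tr, theta_t, eta_t, k = 3)
    scen <- enumerate_hidden_trees(tr)
    lls <- vapply(scen, scenario_loglik_by_hand, numeric(1), cells = tr,
                  theta = theta_t, eta = eta_t)
    best_val <- max(lls)
    cand <- scen[abs(lls - best_val) <= 1e-12]
    bf <- sort(cand[[which.min(lengths(cand))]])
    expect_equal(mh$scenario_loglik[1], best_val, tolerance = 1e-9)
    expect_equal(sort(mh$decision_cells[[1]]), bf)
    # scores nonincreasing and dominated by the full sum
    expect_true(all(diff(mh$scenario_loglik) <= 1e-12))
    total <- likelihood_tree(tr, theta_t, eta_t)$loglik
    expect_true(all(mh$scenario_loglik <= total + 1e-9))
  }
})

test_that("predicted decision generations summarise the MAP antichain", {
  # onset in the root: the unique scenario is a generation-0 decision
  one <- chain_genealogy(10, onset_last = 6)
  dec <- predict_decisions(one, theta_t, eta_t)
  expect_equal(dec$cell_id, "1")
  expect_equal(dec$decision_generation, 0L)
  hist <- predicted_decision_generation(dec)
  expect_equal(hist$fraction, 1)
  # two onset cousins reported at their own generation when they carry the
  # decisions
  fam <- perfect_genealogy(2, onset_leaves = TRUE)
  fam <- fam[fam$cell_id %in% c("1", "2", "3", "4", "5"), ]
  fam$end_reason[fam$cell_id == "3"] <- "movie_end"
  fam <- validate_genealogies(fam)
  mh <- map_hidden_tree(fam, theta_t, eta_t, k = 5)
  two_cousins <- which(vapply(mh$decision_cells, function(d)
    setequal(d, c("4", "5")), logical(1)))
  if (length(two_cousins)) {
    gen <- fam$generation[match(mh$decision_cells[[two_cousins[1]]],
                                fam$cell_id)]
    expect_equal(gen, c(2L, 2L))
  }
})
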