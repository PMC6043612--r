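test_that("simulated genealogies are valid and onsets are terminal", {
  set.seed(31)
  sim <- simulate_trees(sim_config(n_trees = 10, movie_end = 60))
  expect_silent(validate_genealogies(sim))
  onset_keys <- paste(sim$tree_id, sim$cell_id)[!is.na(sim$onset_time)]
  kids_of_onset <- paste(sim$tree_id, sim$parent_id) %in% onset_keys
  expect_false(any(kids_of_onset))
  # binary structure: dividing cells have two tracked children
  expect_equal(sum(sim$end_reason == "division") * 2,
               sum(!is.na(sim$parent_id)))
})

test_that("no hazard means no decisions and no onsets", {
  set.seed(32)
  sim <- simulate_trees(sim_config(theta = decision_params(0, 0),
                                   n_trees = 15, movie_end = 40))
  expect_true(all(is.na(sim$onset_time)))
  expect_equal(nrow(decision_truth(sim)), 0)
})

test_that("instant decision and threshold one gives onsets at the root", {
  set.seed(33)
  sim <- simulate_trees(sim_config(theta = decision_params(50, 0),
                                   eta = delay_params(500, 0, 1),
                                   n_trees = 15, movie_end = 40))
  roots <- dplyr::filter(sim, is.na(parent_id))
  expect_true(all(!is.na(roots$onset_time)))
  expect_true(all(roots$onset_time < 1))
  expect_true(all(roots$generation == 0))
})

test_that("per-lineage decision times follow the decision distribution", {
  # alpha = 0: no onsets ever, so every lineage is followed to movie end and
  # the decision time observed on a fixed lineage (the leftmost path) is a
  # clean draw from the hazard model, truncated at the movie end
  set.seed(34)
  theta <- decision_params(0.08, 0)
  sim <- simulate_trees(sim_config(theta = theta,
                                   eta = delay_params(0, 0, 5),
                                   n_trees = 2000, movie_end = 30))
  truth <- decision_truth(sim)
  leftpath <- as.character(2^(0:10))
  path_dec <- truth %>%
    dplyr::filter(.data$cell_id %in% leftpath) %>%
    dplyr::group_by(.data$tree_id) %>%
    dplyr::summarise(t = min(.data$decision_time))
  expect_gt(nrow(path_dec), 1500)
  ks <- stats::ks.test(path_dec$t, function(q)
    decision_cdf(q, theta) / decision_cdf(30, theta))
  expect_gt(ks$p.value, 0.001)
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("sister onset correlation reflects when the decision happened", {
  # decisions after the last division: the memory-less hazard makes sister
  # decisions independent and a near-instant delay turns them into onsets in
  # the same cell. With near-deterministic division times (so sisters share
  # no timing beyond their common birth) first-generation sister onsets are
  # uncorrelated.
  set.seed(36)
  late <- simulate_trees(sim_config(
    theta = decision_params(0.15, 0),
    eta = delay_params(100, 0, 2),
    cellcycle = list(family = "gamma", mean = 10, sd = 0.02),
    n_trees = 3500, movie_end = 21))
  r_late <- sister_onset_correlation(
    dplyr::filter(late, .data$generation == 1))
  expect_gt(r_late$n_pairs, 300)
  expect_lt(abs(r_late$r), 0.1)
  # decision in the mother with a delay spanning divisions: the inherited
  # expression state correlates sister onsets
  set.seed(37)
  early <- simulate_trees(sim_config(
    theta = decision_params(1, 0),
    eta = delay_params(0.25, 0, 40),
    cellcycle = list(family = "gamma", mean = 40, sd = 10),
    n_trees = 250, movie_end = 400,
    stop_undecided_at = 40))
  r_early <- sister_onset_correlation(early)
  expect_gt(r_early$n_pairs, 200)
  expect_gt(r_early$r, 0.5)
  # identical onset pairs correlate perfectly
  dup <- dplyr::bind_rows(lapply(1:25, function(i) {
    g <- perfect_genealogy(1, life = 5, id = sprintf("d%d", i))
    g$onset_time[g$cell_id != "1"] <- 5 + i / 5
    g$end_time[g$cell_id != "1"] <- 11
    g
  }))
  expect_equal(sister_onset_correlation(dup)$r, 1)
  # too few pairs is flagged
  expect_warning(out <- sister_onset_correlation(dup[0, ]), "pairs")
  expect_true(is.na(out$r))
})

test_that("binomial inheritance partitions the expression state", {
  set.seed(38)
  sim <- simulate_trees(sim_config(n_trees = 30, movie_end = 60,
                                   inheritance_mode = "binomial"))
  expect_silent(validate_genealogies(sim))
})
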