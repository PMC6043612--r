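line_track <- function(cell, slope, t = 0:9, intercept = 50, area = 1,
                       tree = "t1") {
  tibble::tibble(tree_id = tree, cell_id = cell, time_h = t,
                 intensity = intercept + slope * t, area = area)
}

test_that("per-cell OLS slopes are exact on noiseless data", {
  tr <- dplyr::bind_rows(line_track("a", 2), line_track("b", 0))
  s <- fit_cell_slopes(tr)
  expect_equal(s$slope[s$cell_id == "a"], 2)
  expect_equal(s$slope[s$cell_id == "b"], 0)
  # concentration: intensity / area
  tr2 <- line_track("c", 4, area = 2)
  expect_equal(fit_cell_slopes(tr2)$slope, 2)
  expect_equal(fit_cell_slopes(tr2, use_concentration = FALSE)$slope, 4)
  # scaling equivariance
  tr3 <- tr; tr3$intensity <- tr3$intensity * 7
  expect_equal(fit_cell_slopes(tr3)$slope,
               fit_cell_slopes(tr)$slope * 7)
  expect_warning(fit_cell_slopes(line_track("d", 1, t = 0:1)), "skipped")
})

test_that("OLS confidence intervals cover a known slope at the right rate", {
  set.seed(61)
  covered <- replicate(400, {
    t <- seq(0, 9.5, by = 0.5)
    y <- 10 + 1.5 * t + stats::rnorm(length(t), 0, 0.5)
    f <- stats::lm(y ~ t)
    ci <- stats::confint(f)["t", ]
    ci[1] <= 1.5 && 1.5 <= ci[2]
  })
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("relative-generation grouping mirrors the antichain structure", {
  g <- perfect_genealogy(2)
  tracks <- dplyr::bind_rows(lapply(g$cell_id, function(cid)
    line_track(cid, as.numeric(cid),
               t = seq(g$birth_time[g$cell_id == cid],
                       g$end_time[g$cell_id == cid], by = 1),
               tree = "perfect")))
  slopes <- fit_cell_slopes(tracks)
  # decision at the root: one "0" record, two "+1", no "-1"
  dec_root <- tibble::tibble(tree_id = "perfect", cell_id = "1")
  gr <- group_by_relative_generation(g, slopes, dec_root)
  expect_equal(sum(gr$relative_generation == "0"), 1)
  expect_equal(sum(gr$relative_generation == "+1"), 2)
  expect_equal(sum(gr$relative_generation == "-1"), 0)
  # decision mid-tree: one record in each of -1 / 0 / +1
  dec_mid <- tibble::tibble(tree_id = "perfect", cell_id = "2")
  gr2 <- group_by_relative_generation(g, slopes, dec_mid)
  expect_equal(as.vector(table(gr2$relative_generation)[c("-1", "0", "+1")]),
               c(1L, 1L, 2L))
  # onset cells form their own group
  g_on <- perfect_genealogy(2, onset_leaves = TRUE)
  gr3 <- group_by_relative_generation(g_on, slopes, dec_root)
  expect_equal(sum(gr3$relative_generation == "onset"), 4)
})

test_that("rank-sum test has exact small-sample and separated-sample limits", {
  # all C(4,2) = 6 rank splits: 2 as or more extreme than {1,2} vs {3,4}
  expect_equal(ranksum_test(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(62)
  a <- stats::rnorm(100); b <- stats::rnorm(100, 5)
  expect_lt(ranksum_test(a, b), 1e-16)
  expect_error(ranksum_test(numeric(0), 1), "nonempty")
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(63)
  ps <- replicate(300, ranksum_test(stats::rnorm(30), stats::rnorm(30)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))  # p-values are discrete
  expect_gt(ks$p.value, 0.01)
})

test_that("slope comparisons on decision-independent tracks are null", {
  set.seed(64)
  sim <- simulate_trees(sim_config(eta = delay_params(1, 0.02, 10),
                                   n_trees = 25, movie_end = 60))
  tracks <- simulate_neutral_tracks(sim)
  slopes <- fit_cell_slopes(tracks)
  dec <- predict_decisions(sim, decision_params(0.15, -0.002),
                           delay_params(1, 0.02, 10))
  gr <- group_by_relative_generation(sim, slopes,
                                     dec[dec$scenario_rank == 1,
                                         c("tree_id", "cell_id")])
  tests <- slope_group_tests(gr)
  expect_true(all(tests$p_value > 1e-4, na.rm = TRUE))
})
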