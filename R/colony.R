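#' Discretise the decision hazard into per-generation probabilities
#'
#' The colony model runs in discrete generations. The continuous hazard is
#' converted into the probability that a cell of generation `i` decides
#' during its lifetime, `lambda(i) = E[1 - exp(-int_{s_i}^{s_i + c_i}
#' lambda)]`, where the expectation runs over the birth time `s_i` and cycle
#' length `c_i` of generation-`i` cells. Birth times are built recursively
#' from the same cycle draws (`s_1 = 0`, `s_{i+1} = s_i + c_i`), i.e. joint
#' lineage sampling.
#'
#' @inheritParams likelihood_tree
#' @param cellcycle Cycle-length spec as in [sim_config()]; `sd = 0` gives
#'   deterministic cycles (then the expectation is exact).
#' @param n_generations Number of generations `N`.
#' @param n_samples Monte-Carlo sample size (default 1e5).
#' @return A tibble `generation`, `lambda`.
#' @export
discretize_hazard <- function(theta, cellcycle = list(family = "gamma",
                                                      mean = 12, sd = 5),
                              n_generations = 10, n_samples = 1e5) {
  stopifnot(inherits(theta, "decision_params"), cellcycle$mean > 0,
            cellcycle$sd >= 0)
  draw <- function(gen, n) {
    m <- cellcycle$mean
    gm <- cellcycle$generation_means
    if (!is.null(gm) && gen <= length(gm)) m <- gm[gen]
    if (cellcycle$sd == 0) return(rep(m, n))
    shape <- (m / cellcycle$sd)^2
    stats::rgamma(n, shape = shape, rate = shape / m)
  }
  if (cellcycle$sd == 0) n_samples <- 1L
  s <- rep(0, n_samples)
  lam <- numeric(n_generations)
  for (i in seq_len(n_generations)) {
    ci <- draw(i, n_samples)
    lam[i] <- mean(1 - exp(-decision_cumhaz(s, s + ci, theta)))
    s <- s + ci
  }
  tibble(generation = seq_len(n_generations), lambda = lam)
}

pure_colony_freq <- function(lambda, p) {
  v <- 0
  for (i in rev(seq_along(lambda))) v <- lambda[i] * p + (1 - lambda[i]) * v^2
  v
}

#' Predicted colony-type frequencies
#'
#' Branching-process prediction of the frequencies of pure GM, pure MegE and
#' mixed GMMegE colonies grown from single founding cells over `N`
#' generations. A colony is pure GM when the founder decides for GM, or when
#' it stays undecided and both daughter colonies are pure GM; the recursion
#' bottoms out after `N` generations (colonies with any undecided lineage
#' left count as mixed, as the mixed frequency is defined as the
#' complement). The three frequencies sum to one.
#'
#' @param lambda_gen Per-generation decision probabilities, e.g. from
#'   [discretize_hazard()] (a numeric vector or a tibble with a `lambda`
#'   column); generation 1 is the founding cell.
#' @param p_gm Probability of choosing the GM lineage upon decision
#'   (`p_MegE = 1 - p_gm`).
#' @return A tibble `p_gm`, `F_GM`, `F_MegE`, `F_GMMegE`.
#' @export
colony_frequencies <- function(lambda_gen, p_gm) {
  lam <- if (is.data.frame(lambda_gen)) lambda_gen$lambda else lambda_gen
  stopifnot(all(lam >= 0 & lam <= 1), all(p_gm >= 0 & p_gm <= 1))
  purrr::map_dfr(p_gm, function(p) {
    fgm <- pure_colony_freq(lam, p)
    fme <- pure_colony_freq(lam, 1 - p)
    tibble(p_gm = p, F_GM = fgm, F_MegE = fme, F_GMMegE = 1 - fgm - fme)
  })
}

#' Sweep the lineage probability of the colony model
#'
#' Traces the curve of colony-type frequencies as the single free parameter
#' `p_gm` varies over a grid; endpoints correspond to the absence of MegE
#' (`p_gm = 1`) or GM (`p_gm = 0`) colonies.
#'
#' @inheritParams colony_frequencies
#' @param grid Grid of `p_gm` values in `[0, 1]`.
#' @return A tibble with one frequency triple per grid point.
#' @export
sweep_pgm <- function(lambda_gen, grid = seq(0, 1, by = 0.01)) {
  colony_frequencies(lambda_gen, grid)
}

#' Monte-Carlo colony assay simulation
#'
#' Direct branching simulation of colonies (independent oracle for
#' [colony_frequencies()]): per colony, each undecided cell of generation
#' `i` decides with probability `lambda(i)` (choosing GM with `p_gm`) or
#' divides; after `N` generations colonies are classified GM / MegE /
#' GMMegE, with any remaining undecided lineage forcing GMMegE.
#'
#' @inheritParams colony_frequencies
#' @param n_colonies Number of colonies.
#' @return A tibble `F_GM`, `F_MegE`, `F_GMMegE`, `n_colonies`.
#' @export
simulate_colony_assay <- function(lambda_gen, p_gm, n_colonies = 1e6) {
  lam <- if (is.data.frame(lambda_gen)) lambda_gen$lambda else lambda_gen
  n_undec <- rep(1L, n_colonies)
  any_gm <- logical(n_colonies)
  any_me <- logical(n_colonies)
  for (i in seq_along(lam)) {
    act <- n_undec > 0L
    ndec <- integer(n_colonies)
    ndec[act] <- stats::rbinom(sum(act), n_undec[act], lam[i])
    ngm <- integer(n_colonies)
    ngm[act] <- stats::rbinom(sum(act), ndec[act], p_gm)
    any_gm <- any_gm | ngm > 0L
    any_me <- any_me | (ndec - ngm) > 0L
    n_undec <- 2L * (n_undec - ndec)
  }
  undecided <- n_undec > 0L
  gm <- any_gm & !any_me & !undecided
  me <- any_me & !any_gm & !undecided
  tibble(F_GM = mean(gm), F_MegE = mean(me),
         F_GMMegE = 1 - mean(gm) - mean(me), n_colonies = n_colonies)
}
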