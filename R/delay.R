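#' Parameters of the marker-expression delay process
#'
#' After a cell has made its (unobserved) lineage decision, marker expression
#' starts from zero molecules and evolves as a birth-death process: production
#' at constant rate `alpha` (zeroth order) and degradation at rate
#' `gamma * x` (first order). The marker is detected when the copy number
#' first reaches the threshold `x_star`; the sub-threshold states
#' `0..x_star-1` therefore form a Markov chain with an absorbing boundary,
#' and the delay between decision and onset is the first-passage time.
#'
#' @param alpha Production rate per hour, `> 0` (0 allowed for degenerate
#'   checks: the marker then never turns on).
#' @param gamma Degradation rate per hour per molecule, `>= 0`.
#' @param x_star Detection threshold in molecules, integer `>= 1`.
#' @return An object of class `delay_params`.
#' @examples
#' eta <- delay_params(alpha = 0.5, gamma = 0.01, x_star = 25)
#' first_passage_density(eta, x0 = 0, t = c(10, 50, 100))
#' @export
delay_params <- function(alpha, gamma = 0, x_star) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha), alpha >= 0,
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma), gamma >= 0,
            is.numeric(x_star), length(x_star) == 1, x_star >= 1,
            x_star == round(x_star))
  structure(list(alpha = alpha, gamma = gamma, x_star = as.integer(x_star)),
            class = "delay_params")
}

#' @export
print.delay_params <- function(x, ...) {
  cat(sprintf("<delay_params> alpha = %g /h, gamma = %g /h, x* = %d\n",
              x$alpha, x$gamma, x$x_star))
  invisible(x)
}

#' Solve the master equation of the delay process
#'
#' Integrates the chemical master equation of the birth-death expression
#' process on the sub-threshold states `0..x_star-1` with an absorbing
#' boundary at `x_star`, starting from `x0` molecules. Matrix exponentials
#' are chained along the time grid, so the grid may be non-uniform.
#'
#' @param eta A [delay_params()] object.
#' @param x0 Initial copy number, integer in `0..x_star`. `x0 = x_star` means
#'   the marker is already detected (all mass absorbed at time 0).
#' @param t_grid Strictly increasing times in hours starting at 0.
#' @return A list of class `delay_solution` with elements `time_grid`,
#'   `sub_threshold_prob` (matrix, rows = times, cols = states `0..x_star-1`),
#'   `absorbed_mass` (cumulative crossing probability per time) and
#'   `start_state`.
#' @export
solve_master_equation <- function(eta, x0, t_grid) {
  stopifnot(inherits(eta, "delay_params"))
  if (x0 < 0 || x0 > eta$x_star) stop("x0 must lie in 0..x_star", call. = FALSE)
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must start at 0 and increase strictly", call. = FALSE)
  S <- eta$x_star
  n <- length(t_grid)
  probs <- matrix(0, n, S, dimnames = list(NULL, paste0("x", 0:(S - 1))))
  if (x0 == S) {
    out <- list(time_grid = t_grid, sub_threshold_prob = probs,
                absorbed_mass = rep(1, n), start_state = x0)
    return(structure(out, class = "delay_solution"))
  }
  p <- numeric(S); p[x0 + 1] <- 1
  probs[1, ] <- p
  for (i in seq_len(n - 1)) {
    E <- bd_propagator_cpp(eta$alpha, eta$gamma, S, t_grid[i + 1] - t_grid[i])
    p <- as.numeric(p %*% E)
    probs[i + 1, ] <- p
  }
  structure(list(time_grid = t_grid, sub_threshold_prob = probs,
                 absorbed_mass = 1 - rowSums(probs), start_state = x0),
            class = "delay_solution")
}

#' First-passage (delay) density of marker onset
#'
#' `psi_x0(t)`: the density of the first time the marker copy number reaches
#' `x_star` starting from `x0` molecules, computed as the probability flux
#' into the absorbing state, `alpha * P_{x0 -> x_star - 1}(t)`. Integrates to
#' the total crossing probability (which can be below 1 when `gamma > 0`).
#' For `x0 = x_star` detection is immediate (a point mass at `t = 0`,
#' returned as `Inf` at 0).
#'
#' @inheritParams solve_master_equation
#' @param t Times in hours (vectorised).
#' @return Density values per hour.
#' @export
first_passage_density <- function(eta, x0, t) {
  stopifnot(inherits(eta, "delay_params"))
  if (x0 < 0 || x0 > eta$x_star) stop("x0 must lie in 0..x_star", call. = FALSE)
  check_times(t)
  if (x0 == eta$x_star) return(ifelse(t == 0, Inf, 0))
  ord <- order(t)
  grid <- unique(c(0, t[ord]))
  sol <- solve_master_equation(eta, x0, grid)
  flux <- eta$alpha * sol$sub_threshold_prob[, eta$x_star]
  flux[match(t, grid)]
}

#' Sub-threshold propagator of the delay process
#'
#' `P_{x -> x'}(t)`: the probability that the expression process started in
#' state `x` is in state `x'` after time `t` without having crossed the
#' detection threshold in between. Because the threshold absorbs,
#' `sum_{x'} P <= 1`; the deficit equals the integrated first-passage flux.
#'
#' @inheritParams solve_master_equation
#' @param x_from,x_to States in `0..x_star-1`.
#' @param t Time in hours (scalar or vector).
#' @return Probabilities.
#' @export
delay_propagator <- function(eta, x_from, x_to, t) {
  stopifnot(inherits(eta, "delay_params"))
  S <- eta$x_star
  if (any(c(x_from, x_to) < 0) || any(c(x_from, x_to) >= S))
    stop("states must lie in 0..x_star-1", call. = FALSE)
  check_times(t)
  vapply(t, function(tt)
    bd_propagator_cpp(eta$alpha, eta$gamma, S, tt)[x_from + 1, x_to + 1],
    numeric(1))
}

#' Mean and variance of the first-passage delay
#'
#' Moments of `psi_x0` by quadrature of the master-equation flux on a fine
#' grid. With `gamma = 0` the delay is Erlang with shape `x_star - x0` and
#' rate `alpha` (mean `(x_star - x0) / alpha`).
#'
#' @inheritParams solve_master_equation
#' @param t_max Upper integration limit in hours (should carry nearly all
#'   crossing mass).
#' @param h Grid step in hours.
#' @return A tibble with `mean_h`, `var_h2` and `mass` (crossing probability
#'   captured up to `t_max`).
#' @export
first_passage_moments <- function(eta, x0 = 0, t_max = NULL, h = 0.01) {
  stopifnot(inherits(eta, "delay_params"))
  if (is.null(t_max)) {
    t_max <- if (eta$alpha > 0) 10 * eta$x_star / eta$alpha else 1
  }
  grid <- seq(0, t_max, by = h)
  psi <- first_passage_density(eta, x0, grid)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * h
  mass <- trap(psi)
  m1 <- trap(grid * psi) / mass
  m2 <- trap(grid^2 * psi) / mass
  tibble::tibble(mean_h = m1, var_h2 = m2 - m1^2, mass = mass)
}

#' Gillespie sample of the delay process
#'
#' Stochastic simulation of the birth-death expression process from `x0`
#' over `[0, t_max]`; reports whether and when the detection threshold was
#' crossed, and the final sub-threshold state otherwise.
#'
#' @inheritParams solve_master_equation
#' @param t_max Duration in hours.
#' @return A list with `crossed`, `t_cross`, `x_end`.
#' @export
sample_first_passage <- function(eta, x0 = 0, t_max = Inf) {
  stopifnot(inherits(eta, "delay_params"))
  ssa_birth_death_cpp(eta$alpha, eta$gamma, as.integer(x0), eta$x_star, t_max)
}

# grid engine shared by the likelihood machinery: propagator cube on a
# uniform grid of step h covering [0, K*h]
delay_engine <- function(eta, h, t_max) {
  K <- as.integer(ceiling(t_max / h + 1e-9))
  P <- bd_grid_cpp(eta$alpha, eta$gamma, eta$x_star, h, K)
  list(eta = eta, h = h, K = K, P = P,
       psi0 = eta$alpha * P[1, eta$x_star, ])
}
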