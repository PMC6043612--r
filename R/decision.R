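#' Parameters of the differentiation (decision) process
#'
#' The decision to commit to a lineage is modelled as a memory-less process
#' with a time-dependent hazard rate that is linear in absolute experiment
#' time, `lambda(t) = a0 + a1 * t`, clipped at zero so that the event density
#' stays a valid (sub-)density when `a1 < 0`. Time zero is the start of the
#' movie; the clock is shared by all cells of a genealogy (the decision
#' probability depends on factors that are not inherited at division).
#'
#' @param a0 Baseline hazard, per hour, `>= 0`.
#' @param a1 Linear change of the hazard, per hour squared (any sign).
#' @return An object of class `decision_params`.
#' @examples
#' theta <- decision_params(a0 = 0.15, a1 = -0.002)
#' decision_hazard(c(0, 50, 100), theta)
#' @export
decision_params <- function(a0, a1 = 0) {
  stopifnot(is.numeric(a0), length(a0) == 1, is.finite(a0), a0 >= 0,
            is.numeric(a1), length(a1) == 1, is.finite(a1))
  structure(list(a0 = a0, a1 = a1), class = "decision_params")
}

#' @export
print.decision_params <- function(x, ...) {
  cat(sprintf("<decision_params> hazard lambda(t) = max(0, %g + %g t) [1/h]\n",
              x$a0, x$a1))
  invisible(x)
}

check_times <- function(t) {
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0, na.rm = TRUE))
    stop("times must be nonnegative", call. = FALSE)
}

#' Decision hazard rate
#'
#' `lambda(t) = max(0, a0 + a1 t)`: the probability per unit time that an
#' undecided cell commits in `[t, t + dt)`.
#'
#' @param t Times in hours (vectorised), `>= 0`.
#' @param theta A [decision_params()] object.
#' @return Hazard values, per hour.
#' @export
decision_hazard <- function(t, theta) {
  check_times(t)
  pmax(0, theta$a0 + theta$a1 * t)
}

#' Integrated decision hazard over an interval
#'
#' Cumulative hazard `int_{t1}^{t2} max(0, a0 + a1 tau) dtau`, analytic for
#' the clipped linear hazard. Vectorised over `t1`, `t2`.
#'
#' @param t1,t2 Interval endpoints in hours, `0 <= t1 <= t2`.
#' @inheritParams decision_hazard
#' @return Cumulative hazard (dimensionless).
#' @export
decision_cumhaz <- function(t1, t2, theta) {
  check_times(t1); check_times(t2)
  if (any(t2 < t1)) stop("t2 must be >= t1", call. = FALSE)
  a0 <- theta$a0; a1 <- theta$a1
  raw <- function(u) a0 * u + a1 * u^2 / 2
  if (a1 >= 0) return(raw(t2) - raw(t1))
  tz <- a0 / (-a1)   # hazard hits zero here, stays zero after
  u1 <- pmin(t1, tz); u2 <- pmin(t2, tz)
  raw(u2) - raw(u1)
}

#' Decision event density
#'
#' The unconditional density of decision times,
#' `phi(t) = lambda(t) * exp(-int_0^t lambda)`. With a constant hazard this is
#' the exponential density `a0 * exp(-a0 t)`. For `a1 < 0` the density is
#' improper (total mass below one): the missing mass is the probability that a
#' cell never decides.
#'
#' @inheritParams decision_hazard
#' @return Density values, per hour.
#' @export
decision_density <- function(t, theta) {
  decision_hazard(t, theta) * exp(-decision_cumhaz(0 * t, t, theta))
}

#' Decision-time cumulative distribution
#'
#' `Phi(t) = 1 - exp(-int_0^t lambda)`; nondecreasing with `Phi(0) = 0`.
#' For `a1 < 0` it saturates at `1 - exp(-a0^2 / (2 |a1|)) < 1`.
#'
#' @inheritParams decision_hazard
#' @return Probabilities in `[0, 1]`.
#' @export
decision_cdf <- function(t, theta) {
  1 - exp(-decision_cumhaz(0 * t, t, theta))
}

#' Sample decision times
#'
#' Inverse-CDF sampling of the decision process, optionally conditioned on no
#' decision up to time `from` (used by the forward simulator for cells born at
#' `from`). Cells that never decide are returned as `Inf`.
#'
#' @param n Number of draws.
#' @inheritParams decision_hazard
#' @param from Conditioning time in hours (decision known not to have happened
#'   before `from`); default 0.
#' @return Numeric vector of decision times in hours; `Inf` means "never".
#' @export
sample_decision_time <- function(n, theta, from = 0) {
  stopifnot(length(from) == 1, from >= 0)
  a0 <- theta$a0; a1 <- theta$a1
  target <- decision_cumhaz(0, from, theta) + stats::rexp(n)
  invert_cumhaz(target, a0, a1)
}

# solve a0 t + a1 t^2 / 2 = target (pre-clipping region); Inf if unreachable
invert_cumhaz <- function(target, a0, a1) {
  if (a1 == 0) {
    if (a0 == 0) return(rep(Inf, length(target)))
    return(target / a0)
  }
  if (a1 > 0) {
    return((-a0 + sqrt(a0^2 + 2 * a1 * target)) / a1)
  }
  total <- a0^2 / (2 * -a1)
  disc <- a0^2 + 2 * a1 * target
  out <- rep(Inf, length(target))
  ok <- target < total
  out[ok] <- (-a0 + sqrt(disc[ok])) / a1
  out
}
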