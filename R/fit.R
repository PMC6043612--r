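#' Configuration for maximum-likelihood fitting
#'
#' Bounds, restart count and optimizer settings for [fit_genealogies()].
#' Continuous parameters are optimised by a bounded simplex search
#' (Nelder-Mead on logit-transformed coordinates); the integer detection
#' threshold `x_star` is profiled on a grid. Restart start points come from
#' a Latin-hypercube sample over the box. Default bounds cover decision
#' hazards up to 1/h and marker delays of hours to days at ~12 h cycles.
#'
#' @param bounds Named list of `c(lower, upper)` for `a0` (per h), `a1`
#'   (per h^2), `alpha` (per h), `gamma` (per h). The rate parameters
#'   `alpha` and `gamma` span decades and are explored on a log scale, so
#'   their lower bounds must be positive (a `gamma` of 1e-3/h is
#'   effectively no degradation on movie time scales).
#' @param x_star_grid Integer candidate values for the detection threshold.
#' @param n_explore Size of the Latin-hypercube screening sample (drawn
#'   jointly over the continuous box and the `x_star` grid; each point costs
#'   one likelihood evaluation).
#' @param n_restarts Local Nelder-Mead searches started from the
#'   best-scoring screened points. Each search is restarted with a fresh
#'   simplex until it stops improving (at most `n_rounds` rounds), then
#'   polished on the fine time grid.
#' @param n_rounds Maximum simplex restarts per local search.
#' @param maxit,reltol Nelder-Mead iteration cap (per round) and relative
#'   tolerance.
#' @param polish_maxit Iteration cap for the final fine-grid polish
#'   (defaults to `maxit`; the polish starts from a coarse-grid optimum, so
#'   a smaller cap is usually enough).
#' @param rng_seed Seed used for the restart sample (fit is then fully
#'   deterministic).
#' @param h Time-grid step in hours for the final likelihood quadrature.
#' @param coarse_h Coarser grid step used during screening and the local
#'   search rounds (the surface shape is insensitive to the step; the best
#'   point is re-optimised at `h`). Set equal to `h` to disable.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(bounds = list(a0 = c(0, 1), a1 = c(-0.05, 0.05),
                                     alpha = c(0.01, 5),
                                     gamma = c(1e-3, 1)),
                       x_star_grid = seq(5L, 100L, by = 5L),
                       n_explore = 200, n_restarts = 8, n_rounds = 3,
                       maxit = 300, reltol = 1e-7, polish_maxit = maxit,
                       rng_seed = 1L, h = 0.25, coarse_h = 0.5) {
  stopifnot(n_restarts >= 1, n_explore >= n_restarts, n_rounds >= 1,
            polish_maxit >= 1,
            all(lengths(bounds) == 2),
            all(vapply(bounds, function(b) b[1] <= b[2], logical(1))),
            bounds$alpha[1] > 0, bounds$gamma[1] > 0,
            all(x_star_grid >= 1), coarse_h >= h)
  structure(list(bounds = bounds[c("a0", "a1", "alpha", "gamma")],
                 x_star_grid = as.integer(x_star_grid),
                 n_explore = as.integer(n_explore),
                 n_restarts = as.integer(n_restarts),
                 n_rounds = as.integer(n_rounds), maxit = maxit,
                 reltol = reltol, polish_maxit = polish_maxit,
                 rng_seed = rng_seed, h = h,
                 coarse_h = coarse_h),
            class = "fit_config")
}

# bounded reparameterisation: sigmoid into the box, log scale for the rates
fit_par_log <- c(a0 = FALSE, a1 = FALSE, alpha = TRUE, gamma = TRUE)
to_box <- function(z, lo, hi) {
  u <- stats::plogis(z)
  out <- lo + (hi - lo) * u
  lg <- fit_par_log[names(lo)]
  out[lg] <- exp(log(lo[lg]) + (log(hi[lg]) - log(lo[lg])) * u[lg])
  out
}
from_box <- function(p, lo, hi) {
  lg <- fit_par_log[names(lo)]
  u <- (p - lo) / (hi - lo)
  u[lg] <- (log(p[lg]) - log(lo[lg])) / (log(hi[lg]) - log(lo[lg]))
  stats::qlogis(pmin(pmax(u, 0.001), 0.999))
}

# deterministic screening anchors: hazards of a few per-hour scales crossed
# with delay means of a few hours to days at each threshold (the alpha that
# matters scales with x_star, which random box sampling easily misses)
anchor_starts <- function(bl, bu, x_star_grid) {
  combos <- expand.grid(a0 = c(0.02, 0.2), delay_h = c(2, 6, 18, 54),
                        x_star = x_star_grid)
  z <- t(apply(combos, 1, function(r) {
    p <- c(a0 = min(max(r[["a0"]], bl[["a0"]]), bu[["a0"]]),
           a1 = 0,
           alpha = min(max(r[["x_star"]] / r[["delay_h"]], bl[["alpha"]]),
                       bu[["alpha"]]),
           gamma = sqrt(bl[["gamma"]] * bu[["gamma"]]))
    from_box(p, bl, bu)
  }))
  list(z = z, x_star = as.integer(combos$x_star))
}

#' Fit the decision + delay model to genealogies
#'
#' Maximum-likelihood estimation of the decision hazard `theta = (a0, a1)`
#' and the delay parameters `eta = (alpha, gamma, x_star)` from a set of
#' observed genealogies, by maximising the summed hidden-tree
#' log-likelihood over trees. Multistart bounded optimisation: a Latin
#' hypercube of start points over the parameter box, Nelder-Mead in
#' logit-transformed coordinates for the continuous parameters, and the
#' integer threshold `x_star` profiled over its grid.
#'
#' @param cells A validated genealogy tibble (fit GM- and MegE-fated trees
#'   separately, as their delay processes differ).
#' @param config A [fit_config()].
#' @inheritParams likelihood_tree
#' @return An object of class `delaytree_fit` with elements `theta_hat`,
#'   `eta_hat`, `logLik`, `restarts` (per-restart trace tibble), `config`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_genealogies <- function(cells, config = fit_config(),
                            inheritance_mode = c("copy", "binomial")) {
  inheritance_mode <- match.arg(inheritance_mode)
  cells <- validate_genealogies(cells)
  if (!any(!is.na(cells$onset_time)))
    warning("no marker onsets in the data: delay parameters are unidentifiable")
  imode <- inherit_code(inheritance_mode)
  bl <- vapply(config$bounds, `[`, numeric(1), 1)
  bu <- vapply(config$bounds, `[`, numeric(1), 2)
  pre_fine <- preprocess_forest(cells, config$h)
  pre_coarse <- if (config$coarse_h > config$h)
    preprocess_forest(cells, config$coarse_h) else pre_fine

  negll_on <- function(pre, h) function(z, x_star) {
    p <- to_box(z, bl, bu)
    eng <- delay_engine(delay_params(p[["alpha"]], p[["gamma"]], x_star),
                        h, pre$K * h)
    ll <- forest_loglik_cpp(pre$ib, pre$ie, pre$ion, pre$c1, pre$c2, pre$root,
                            p[["a0"]], p[["a1"]], eng$P, h,
                            p[["alpha"]], imode)
    if (!is.finite(ll)) 1e10 else -ll
  }
  negll_c <- negll_on(pre_coarse, config$coarse_h)
  negll_f <- negll_on(pre_fine, config$h)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$rng_seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  # stage 1: Latin-hypercube screen of the box on the coarse grid (x_star
  # stratified by the fifth LHS column); stage 2: restarted simplex searches
  # from the best screened points; stage 3: fine-grid polish of each search
  lh <- lhs::randomLHS(config$n_explore, 5)
  starts <- t(apply(lh[, 1:4, drop = FALSE], 1, function(u)
    stats::qlogis(pmin(pmax(u, 0.02), 0.98))))
  xs_idx <- pmin(1L + as.integer(floor(lh[, 5] * length(config$x_star_grid))),
                 length(config$x_star_grid))
  xs_all <- config$x_star_grid[xs_idx]
  anch <- anchor_starts(bl, bu, config$x_star_grid)
  colnames(starts) <- names(bl)
  starts <- rbind(starts, anch$z)
  xs_all <- c(xs_all, anch$x_star)
  screen <- vapply(seq_len(nrow(starts)),
                   function(r) negll_c(starts[r, ], xs_all[r]), numeric(1))
  # local searches start from the best screened point of each threshold
  # value (the basins of attraction cluster by x_star, and the global top-k
  # often all sit in one basin); remaining slots go to the next best overall
  best_per_xs <- vapply(split(seq_along(screen), xs_all),
                        function(i) i[which.min(screen[i])], integer(1))
  picks <- best_per_xs[order(screen[best_per_xs])]
  picks <- picks[seq_len(min(config$n_restarts, length(picks)))]
  if (length(picks) < config$n_restarts) {
    extra <- setdiff(order(screen), picks)
    picks <- c(picks, extra[seq_len(config$n_restarts - length(picks))])
  }

  trace <- vector("list", length(picks))
  best <- NULL
  for (j in seq_along(picks)) {
    r <- picks[j]
    xs <- xs_all[r]
    z <- starts[r, ]
    val <- screen[r]
    for (round in seq_len(config$n_rounds)) {
      opt <- stats::optim(z, negll_c, x_star = xs, method = "Nelder-Mead",
                          control = list(maxit = config$maxit,
                                         reltol = config$reltol))
      z <- opt$par
      improved <- val - opt$value
      val <- opt$value
      if (improved < 0.5) break
    }
    opt <- stats::optim(z, negll_f, x_star = xs, method = "Nelder-Mead",
                        control = list(maxit = config$polish_maxit,
                                       reltol = config$reltol))
    p <- to_box(opt$par, bl, bu)
    trace[[j]] <- tibble(restart = j, x_star = xs,
                         a0 = p[["a0"]], a1 = p[["a1"]],
                         alpha = p[["alpha"]], gamma = p[["gamma"]],
                         start_loglik = -screen[r],
                         loglik = -opt$value, convergence = opt$convergence)
    if (is.null(best) || -opt$value > best$loglik)
      best <- list(p = p, x_star = xs, loglik = -opt$value)
  }
  if (is.null(best) || !is.finite(best$loglik) || best$loglik <= -1e9)
    stop("fit error: no restart reached a finite likelihood", call. = FALSE)
  structure(list(
    theta_hat = decision_params(best$p[["a0"]], best$p[["a1"]]),
    eta_hat = delay_params(best$p[["alpha"]], best$p[["gamma"]], best$x_star),
    logLik = best$loglik,
    restarts = bind_rows(trace),
    n_trees = length(unique(cells$tree_id)),
    inheritance_mode = inheritance_mode,
    config = config), class = "delaytree_fit")
}

#' @export
print.delaytree_fit <- function(x, ...) {
  cat("<delaytree_fit>\n")
  cat(sprintf("  theta: a0 = %.4g /h, a1 = %.4g /h^2\n",
              x$theta_hat$a0, x$theta_hat$a1))
  cat(sprintf("  eta:   alpha = %.4g /h, gamma = %.4g /h, x* = %d\n",
              x$eta_hat$alpha, x$eta_hat$gamma, x$eta_hat$x_star))
  cat(sprintf("  log-likelihood %.3f over %d trees (%d restarts)\n",
              x$logLik, x$n_trees, nrow(x$restarts)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_genealogies
#' @param x A `delaytree_fit`.
#' @param ... Unused.
#' @export
tidy.delaytree_fit <- function(x, ...) {
  tibble(term = c("a0", "a1", "alpha", "gamma", "x_star"),
         estimate = c(x$theta_hat$a0, x$theta_hat$a1, x$eta_hat$alpha,
                      x$eta_hat$gamma, x$eta_hat$x_star),
         unit = c("1/h", "1/h^2", "1/h", "1/h", "molecules"))
}

#' @rdname fit_genealogies
#' @export
glance.delaytree_fit <- function(x, ...) {
  tibble(logLik = x$logLik, n_trees = x$n_trees,
         n_restarts = nrow(x$restarts),
         converged = any(x$restarts$convergence == 0))
}

# empirical CDF pair distance on the union of jump points
ecdf_sup_distance <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(g) - stats::ecdf(b)(g)))
}

#' Predicted vs empirical cumulative onset distribution
#'
#' Compares the pooled empirical CDF of observed marker onset times with the
#' model-predicted onset CDF at the fitted parameters. The prediction is a
#' forward simulation that matches the observed trees' cell-cycle structure
#' (cycle mean/sd estimated from the observed division cells) and
#' observation window.
#'
#' @param cells The genealogies the fit was computed from.
#' @param fit A `delaytree_fit`.
#' @param n_sim_trees Trees to simulate for the prediction (default 400).
#' @return A list of class `onset_fit`: `curves` (tibble `time_h`,
#'   `empirical`, `predicted`) and `sup_distance`.
#' @export
onset_distribution_fit <- function(cells, fit, n_sim_trees = 400) {
  stopifnot(inherits(fit, "delaytree_fit"))
  obs <- cells$onset_time[!is.na(cells$onset_time)]
  if (!length(obs)) stop("no onsets observed", call. = FALSE)
  cyc <- cells$end_time - cells$birth_time
  cyc <- cyc[cells$end_reason == "division"]
  cc <- list(family = "gamma",
             mean = mean(cyc), sd = max(stats::sd(cyc), 1e-3))
  sim <- simulate_trees(sim_config(theta = fit$theta_hat, eta = fit$eta_hat,
                                   cellcycle = cc,
                                   movie_end = max(cells$end_time),
                                   n_trees = n_sim_trees,
                                   inheritance_mode = fit$inheritance_mode))
  pred <- sim$onset_time[!is.na(sim$onset_time)]
  g <- sort(unique(c(obs, pred)))
  curves <- tibble(time_h = g, empirical = stats::ecdf(obs)(g),
                   predicted = if (length(pred)) stats::ecdf(pred)(g) else 0)
  structure(list(curves = curves,
                 sup_distance = if (length(pred))
                   ecdf_sup_distance(obs, pred) else 1,
                 n_onsets_observed = length(obs),
                 n_onsets_predicted = length(pred)),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("<onset_fit> sup-norm distance %.3f (%d observed, %d simulated onsets)\n",
              x$sup_distance, x$n_onsets_observed, x$n_onsets_predicted))
  invisible(x)
}

#' Mean decision-to-onset delay of a fitted model
#'
#' Monte-Carlo estimate of the mean delay between a lineage decision and the
#' marker onsets it produces, under the fitted model. Because the
#' sub-threshold state is inherited at division, the delay spans
#' generations. Onsets are weighted by `2^-d` (`d` = divisions since the
#' decision), which makes the estimate the mean delay of a single lineage
#' followed downward from the decision; without this weight, branches with
#' longer delays would dominate simply because they have divided more often
#' by the time they cross the threshold.
#'
#' @param fit A `delaytree_fit`, or a list with elements `theta_hat`,
#'   `eta_hat`.
#' @param cellcycle Cell-cycle spec as in [sim_config()] (default 12 +/- 5 h
#'   gamma); pass a huge mean to forbid divisions.
#' @param n_trees Monte-Carlo size (default 300).
#' @param movie_end Observation window; defaults to a multiple of the
#'   expected first-passage time so that censoring is negligible.
#' @param method `"mc"` (forward-simulation estimate; default) or
#'   `"analytic"` (mean of the master-equation first-passage density from
#'   state 0; under copy inheritance a single lineage's delay is exactly the
#'   first-passage time, so the two agree up to Monte-Carlo error).
#' @return A tibble with `mean_delay_h` and `n_onsets` (`NA` for the
#'   analytic method).
#' @export
mean_delay <- function(fit, cellcycle = list(family = "gamma", mean = 12, sd = 5),
                       n_trees = 300, movie_end = NULL,
                       method = c("mc", "analytic")) {
  method <- match.arg(method)
  eta <- fit$eta_hat; theta <- fit$theta_hat
  fp <- if (eta$alpha > 0) eta$x_star / eta$alpha else 1
  if (method == "analytic") {
    m <- first_passage_moments(eta, 0, t_max = 12 * fp, h = 0.05)
    return(tibble(mean_delay_h = m$mean_h, n_onsets = NA_integer_))
  }
  dec <- if (theta$a0 > 0) 1 / theta$a0 else 1
  if (is.null(movie_end)) movie_end <- 6 * fp + 3 * dec + 24
  sim <- simulate_trees(sim_config(theta = theta, eta = eta,
                                   cellcycle = cellcycle,
                                   movie_end = movie_end, n_trees = n_trees,
                                   stop_undecided_at = 3 * dec + 24))
  d <- onset_delays(sim)
  tibble(mean_delay_h = stats::weighted.mean(d$delay, d$weight),
         n_onsets = nrow(d))
}

# decision-to-onset intervals of a simulated tree set with attached truth;
# weight 2^-(divisions since decision) undoes branch multiplication
onset_delays <- function(sim) {
  truth <- decision_truth(sim)
  per_tree <- function(df) {
    tt <- truth[truth$tree_id == df$tree_id[1], ]
    pidx <- match(df$parent_id, df$cell_id)
    dec_t <- rep(NA_real_, nrow(df))
    dec_g <- rep(NA_integer_, nrow(df))
    own <- match(df$cell_id, tt$cell_id)
    dec_t[!is.na(own)] <- tt$decision_time[own[!is.na(own)]]
    dec_g[!is.na(own)] <- df$generation[!is.na(own)]
    for (j in order(df$generation)) {
      p <- pidx[j]
      if (is.na(dec_t[j]) && !is.na(p)) {
        dec_t[j] <- dec_t[p]
        dec_g[j] <- dec_g[p]
      }
    }
    on <- !is.na(df$onset_time) & !is.na(dec_t)
    tibble(delay = df$onset_time[on] - dec_t[on],
           weight = 2^-(df$generation[on] - dec_g[on]))
  }
  sim %>%
    group_by(.data$tree_id) %>%
    dplyr::group_map(~ per_tree(dplyr::mutate(.x, tree_id = .y$tree_id))) %>%
    bind_rows()
}
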