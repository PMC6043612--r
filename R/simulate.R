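#' Configuration of the forward genealogy simulator
#'
#' Bundles the generative model: the decision process (`theta`), the
#' expression delay (`eta`), the cell-cycle distribution, the observation
#' window and the state-inheritance rule at division. Defaults emulate
#' time-lapse movies of differentiating hematopoietic progenitors: gamma
#' distributed cell cycles of 12 +/- 5 h, a 120 h movie, decisions with a
#' slowly decreasing hazard and marker onsets delayed by tens of hours
#' across one or more divisions.
#'
#' @param theta A [decision_params()] object.
#' @param eta A [delay_params()] object.
#' @param cellcycle A list: `family` (only `"gamma"`), `mean` and `sd` in
#'   hours, and optionally `generation_means`, a numeric vector of
#'   per-generation mean cycle lengths for the first generations (later
#'   generations fall back to `mean`; models the prolonged first cycles of
#'   freshly activated stem cells).
#' @param movie_end Observation window in hours (global right-censoring).
#' @param n_trees Number of genealogies.
#' @param inheritance_mode `"copy"` (both daughters inherit the mother's
#'   expression state; default) or `"binomial"` (molecules split
#'   binomially).
#' @param loss_rate Optional per-hour rate of tracking loss (default 0).
#' @param fate_label Label given to trees that show at least one onset.
#' @param stop_undecided_at Stop following still-undecided branches born
#'   after this time (hours; default `Inf` = follow everything to
#'   `movie_end`). With a hazard that vanishes at late times, undecided
#'   lineages otherwise proliferate indefinitely in long movies; dropping
#'   them (their cells end `"lost"`) leaves all decision and onset
#'   statistics untouched.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(theta = decision_params(0.15, -0.002),
                       eta = delay_params(0.5, 0.01, 25),
                       cellcycle = list(family = "gamma", mean = 12, sd = 5),
                       movie_end = 120, n_trees = 200,
                       inheritance_mode = c("copy", "binomial"),
                       loss_rate = 0, fate_label = "GM",
                       stop_undecided_at = Inf) {
  inheritance_mode <- match.arg(inheritance_mode)
  stopifnot(inherits(theta, "decision_params"), inherits(eta, "delay_params"),
            cellcycle$mean > 0, cellcycle$sd > 0, movie_end > 0, n_trees >= 1,
            loss_rate >= 0, stop_undecided_at > 0)
  if (!identical(cellcycle$family, "gamma"))
    stop("only gamma cell-cycle distributions are supported", call. = FALSE)
  structure(list(theta = theta, eta = eta, cellcycle = cellcycle,
                 movie_end = movie_end, n_trees = as.integer(n_trees),
                 inheritance_mode = inheritance_mode, loss_rate = loss_rate,
                 fate_label = fate_label,
                 stop_undecided_at = stop_undecided_at),
            class = "sim_config")
}

sample_cycle <- function(cc, generation) {
  m <- cc$mean
  gm <- cc$generation_means
  if (!is.null(gm) && generation < length(gm)) m <- gm[generation + 1]
  shape <- (m / cc$sd)^2
  stats::rgamma(1, shape = shape, rate = shape / m)
}

#' Simulate annotated genealogies under the decision + delay model
#'
#' Forward simulation of the generative model: each tree starts from one
#' cell at time 0; cells divide at sampled cycle lengths until the movie
#' ends; every cell on an undecided lineage is exposed to the decision
#' hazard `lambda(t)` on the absolute clock; once a lineage decides,
#' marker expression starts at zero molecules and runs as a Gillespie
#' birth-death sample, with the sub-threshold state passed to both
#' daughters at division (per the inheritance mode). The first
#' threshold crossing on a branch is recorded as the marker onset and the
#' branch is no longer followed (its cell ends `"lost"` if it would have
#' divided). Ground-truth decisions are attached as attribute `"truth"`
#' (a tibble `tree_id`, `cell_id`, `decision_time`).
#'
#' @param config A [sim_config()] object.
#' @return A validated genealogy tibble with attribute `"truth"`.
#' @export
simulate_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  th <- config$theta; eta <- config$eta
  rows <- vector("list", 0)
  truths <- vector("list", 0)
  binom_split <- config$inheritance_mode == "binomial"
  for (tr in seq_len(config$n_trees)) {
    tid <- sprintf("t%03d", tr)
    # stack entries: heap index, birth, generation, decided, t_dec, x at birth
    stack <- list(list(k = 1, birth = 0, gen = 0L,
                       decided = FALSE, t_dec = NA_real_, x = 0L))
    trows <- list(); ttruth <- list()
    any_onset <- FALSE
    while (length(stack)) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      cyc <- sample_cycle(config$cellcycle, cell$gen)
      sched <- cell$birth + cyc
      end <- min(sched, config$movie_end)
      reason <- if (sched <= config$movie_end) "division" else "movie_end"
      if (config$loss_rate > 0) {
        tl <- cell$birth + stats::rexp(1, config$loss_rate)
        if (tl < end) { end <- tl; reason <- "lost" }
      }
      decided <- cell$decided
      t_dec <- cell$t_dec
      if (!decided) {
        cand <- sample_decision_time(1, th, from = cell$birth)
        if (cand <= end) {
          decided <- TRUE; t_dec <- cand
          ttruth[[length(ttruth) + 1]] <-
            list(cell_id = sprintf("%.0f", cell$k), decision_time = cand)
        }
      }
      onset <- NA_real_
      x_end <- cell$x
      if (decided) {
        from_t <- if (is.na(t_dec) || t_dec < cell$birth) cell$birth else t_dec
        x_start <- if (!cell$decided) 0L else cell$x
        ssa <- ssa_birth_death_cpp(eta$alpha, eta$gamma, x_start, eta$x_star,
                                   end - from_t)
        if (ssa$crossed) {
          onset <- from_t + ssa$t_cross
          any_onset <- TRUE
          if (reason == "division") reason <- "lost"  # branch not followed on
        } else {
          x_end <- ssa$x_end
        }
      }
      if (reason == "division" && !decided &&
          end > config$stop_undecided_at) {
        reason <- "lost"   # undecided branch beyond the tracking cutoff
      }
      if (reason == "division") {
        for (side in 0:1) {
          stack[[length(stack) + 1]] <-
            list(k = 2 * cell$k + side, birth = end, gen = cell$gen + 1L,
                 decided = decided, t_dec = t_dec, x = x_end)
        }
        if (binom_split && decided) {
          x1 <- stats::rbinom(1, x_end, 0.5)
          stack[[length(stack)]]$x <- x_end - x1
          stack[[length(stack) - 1]]$x <- x1
        }
      }
      trows[[length(trows) + 1]] <- list(
        cell_id = sprintf("%.0f", cell$k),
        parent_id = if (cell$k == 1) NA_character_
                    else sprintf("%.0f", cell$k %/% 2),
        birth_time = cell$birth, end_time = end, end_reason = reason,
        onset_time = onset, generation = cell$gen)
    }
    pull_chr <- function(rows, f) vapply(rows, `[[`, character(1), f)
    pull_dbl <- function(rows, f) vapply(rows, `[[`, numeric(1), f)
    df <- tibble(
      tree_id = tid,
      cell_id = pull_chr(trows, "cell_id"),
      parent_id = vapply(trows, function(r)
        if (is.null(r$parent_id) || is.na(r$parent_id)) NA_character_
        else r$parent_id, character(1)),
      birth_time = pull_dbl(trows, "birth_time"),
      end_time = pull_dbl(trows, "end_time"),
      end_reason = pull_chr(trows, "end_reason"),
      onset_time = pull_dbl(trows, "onset_time"),
      generation = vapply(trows, `[[`, integer(1), "generation"),
      fate_label = if (any_onset) config$fate_label else "none")
    rows[[tr]] <- df
    if (length(ttruth)) {
      truths[[tr]] <- tibble(
        tree_id = tid,
        cell_id = pull_chr(ttruth, "cell_id"),
        decision_time = pull_dbl(ttruth, "decision_time"))
    }
  }
  out <- validate_genealogies(bind_rows(rows))
  truth <- if (length(truths))
    bind_rows(truths)[c("tree_id", "cell_id", "decision_time")]
  else tibble(tree_id = character(), cell_id = character(),
              decision_time = numeric())
  attr(out, "truth") <- truth
  out
}

#' Ground-truth decisions of a simulated genealogy set
#'
#' @param cells Output of [simulate_trees()].
#' @return A tibble `tree_id`, `cell_id`, `decision_time`.
#' @export
decision_truth <- function(cells) {
  tt <- attr(cells, "truth")
  if (is.null(tt)) stop("no ground truth attached", call. = FALSE)
  tt
}

#' Correlation of sister-cell onset times
#'
#' Pearson correlation of onset times across sister pairs where both
#' sisters show an onset. Divisions during the delay make sisters inherit
#' the same expression state, which correlates their onsets; decisions
#' after the last division give uncorrelated onsets.
#'
#' @param cells A genealogy tibble.
#' @param min_pairs Minimum number of complete pairs (default 20); fewer
#'   gives `NA` with a warning.
#' @return A tibble with `r` and `n_pairs`. Each unordered sister pair
#'   enters once.
#' @export
sister_onset_correlation <- function(cells, min_pairs = 20) {
  on <- filter(cells, !is.na(.data$onset_time), !is.na(.data$parent_id))
  if (nrow(on) < 2) {
    warning(sprintf("only 0 complete sister pairs (< %d); correlation undefined",
                    min_pairs))
    return(tibble(r = NA_real_, n_pairs = 0L))
  }
  pairs <- on %>%
    group_by(.data$tree_id, .data$parent_id) %>%
    filter(n() == 2) %>%
    summarise(o1 = min(.data$onset_time), o2 = max(.data$onset_time),
              flip = stats::runif(1) < 0.5, .groups = "drop") %>%
    mutate(a = ifelse(.data$flip, .data$o1, .data$o2),
           b = ifelse(.data$flip, .data$o2, .data$o1))
  n <- nrow(pairs)
  if (n < min_pairs) {
    warning(sprintf("only %d complete sister pairs (< %d); correlation undefined",
                    n, min_pairs))
    return(tibble(r = NA_real_, n_pairs = n))
  }
  tibble(r = stats::cor(pairs$a, pairs$b), n_pairs = n)
}

#' Simulate decision-independent signal tracks
#'
#' Generates per-cell linear fluorescence tracks whose slopes are drawn
#' independently of any decision structure (the negative control for the
#' slope statistics: under this generator, production-slope comparisons
#' around the predicted decision must be null).
#'
#' @param cells A genealogy tibble.
#' @param slope_mean,slope_sd Mean and sd of per-cell slopes (units per h).
#' @param noise_sd Gaussian measurement noise on intensity.
#' @param dt Sampling interval in hours.
#' @return A signal-track tibble (`area` is constant 1, so intensity equals
#'   concentration).
#' @export
simulate_neutral_tracks <- function(cells, slope_mean = 0, slope_sd = 1,
                                    noise_sd = 0.5, dt = 0.5) {
  cells %>%
    group_by(.data$tree_id, .data$cell_id) %>%
    dplyr::reframe({
      tt <- seq(.data$birth_time[1], .data$end_time[1], by = dt)
      sl <- stats::rnorm(1, slope_mean, slope_sd)
      tibble(time_h = tt,
             intensity = 50 + sl * (tt - tt[1]) + stats::rnorm(length(tt), 0, noise_sd),
             area = 1)
    })
}
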