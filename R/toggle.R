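#' Parameters of the tristable toggle switch
#'
#' Two mutually repressing, self-activating transcription factors A (the
#' PU.1-like, GM-associated species) and B (the GATA1-like, MegE-associated
#' species). Production of each species is `act * X^n / (K^n + X^n) +
#' rep * K^n / (K^n + Y^n)` (Hill self-activation plus repression by the
#' other factor) and degradation is linear. The default parameterisation is
#' symmetric and yields three stable states: a central progenitor state with
#' both factors at intermediate levels, and two committed states with one
#' factor high and the other low; commitment happens by noise-driven escape
#' from the central basin. Tristability of a parameterisation can be checked
#' with [quasi_potential()].
#'
#' @param act Maximal self-activation rate, molecules per hour.
#' @param rep Maximal repressed-production rate, molecules per hour.
#' @param K Hill threshold, molecules.
#' @param hill Hill coefficient, `>= 1`.
#' @param deg Degradation rate per hour per molecule.
#' @param division `"binomial"` (molecules partitioned binomially at
#'   division; default) or `"copy"`.
#' @return A list of class `toggle_params`.
#' @export
toggle_params <- function(act = 5, rep = 5, K = 10, hill = 4, deg = 0.25,
                          division = c("binomial", "copy")) {
  division <- match.arg(division)
  stopifnot(act >= 0, rep >= 0, K > 0, hill >= 1, deg > 0)
  structure(list(act = act, rep = rep, K = K, hill = hill, deg = deg,
                 division = division), class = "toggle_params")
}

#' Gillespie trajectory of the toggle switch
#'
#' Exact stochastic simulation of the two-species toggle switch, recorded
#' on a regular time grid.
#'
#' @param params A [toggle_params()].
#' @param init Integer vector `c(A, B)` initial copy numbers.
#' @param duration Hours.
#' @param record_dt Recording interval in hours.
#' @return A tibble `time_h`, `A`, `B`.
#' @export
ssa_toggle <- function(params, init, duration, record_dt = 0.5) {
  stopifnot(inherits(params, "toggle_params"), length(init) == 2,
            all(init >= 0), duration > 0)
  m <- ssa_toggle_cpp(params$act, params$rep, params$K, params$hill,
                      params$deg, as.integer(init[1]), as.integer(init[2]),
                      duration, record_dt)
  tibble(time_h = m[, 1], A = m[, 2], B = m[, 3])
}

#' Quasi-potential of the toggle switch
#'
#' Estimates `-log(P)` of the occupancy distribution over the `(A, B)`
#' copy-number plane from an ensemble of division-free Gillespie runs
#' started in the progenitor region (committed states are effectively
#' absorbing on simulation time scales, so a single long run would not
#' revisit all basins), and counts the wells: local occupancy peaks after
#' light smoothing, separated by at least `min_sep` molecules and carrying
#' at least `min_frac` of the strongest peak.
#'
#' @inheritParams ssa_toggle
#' @param n_runs Ensemble size.
#' @param run_time Duration per run in hours.
#' @param burnin Discarded initial time per run in hours.
#' @param amax,bmax Histogram extent (defaults scale with the parameters).
#' @param smooth Half-width of the smoothing box in molecules.
#' @param min_sep,min_frac Well-detection settings (`min_sep` defaults to
#'   twice the Hill threshold `K`).
#' @return A list of class `quasi_potential`: `grid` (tibble `A`, `B`,
#'   `occupancy`, `potential`), `wells` (tibble of well coordinates), and
#'   `n_wells`.
#' @export
quasi_potential <- function(params, init = NULL, n_runs = 40, run_time = 400,
                            burnin = 5, amax = NULL, bmax = NULL, smooth = 2,
                            min_sep = NULL, min_frac = 0.02) {
  stopifnot(inherits(params, "toggle_params"))
  top <- ceiling(2.5 * (params$act + params$rep) / params$deg / 2)
  if (is.null(amax)) amax <- top
  if (is.null(bmax)) bmax <- top
  if (is.null(min_sep)) min_sep <- 2 * params$K
  if (is.null(init)) init <- round(c(2 * params$K, 2 * params$K))
  occ <- matrix(0, amax + 1, bmax + 1)
  for (r in seq_len(n_runs))
    occ <- occ + toggle_occupancy_cpp(params$act, params$rep, params$K,
                                      params$hill, params$deg,
                                      as.integer(init[1]), as.integer(init[2]),
                                      burnin, run_time,
                                      as.integer(amax), as.integer(bmax))
  tot <- sum(occ)
  if (tot <= 0) stop("no occupancy recorded; increase t_total", call. = FALSE)
  p <- occ / tot
  sm <- box_smooth(p, smooth)
  wells <- find_peaks(sm, min_sep = min_sep, min_frac = min_frac)
  grid <- tidyr::expand_grid(A = 0:amax, B = 0:bmax)
  grid$occupancy <- as.vector(p[cbind(grid$A + 1, grid$B + 1)])
  grid$potential <- ifelse(grid$occupancy > 0, -log(grid$occupancy), NA_real_)
  structure(list(grid = grid, wells = wells, n_wells = nrow(wells),
                 smoothed = sm, params = params),
            class = "quasi_potential")
}

box_smooth <- function(m, r) {
  if (r <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  # separable box filter, edge-clamped
  pad <- function(idx, n) pmin(pmax(idx, 1), n)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    rows <- pad((i - r):(i + r), n1)
    out[i, ] <- colMeans(m[rows, , drop = FALSE])
  }
  out2 <- matrix(0, n1, n2)
  for (j in seq_len(n2)) {
    cols <- pad((j - r):(j + r), n2)
    out2[, j] <- rowMeans(out[, cols, drop = FALSE])
  }
  out2
}

find_peaks <- function(m, min_sep, min_frac) {
  idx <- which(m > 0, arr.ind = TRUE)
  v <- m[idx]
  o <- order(v, decreasing = TRUE)
  idx <- idx[o, , drop = FALSE]; v <- v[o]
  keep <- v >= min_frac * v[1]
  idx <- idx[keep, , drop = FALSE]; v <- v[keep]
  peaks <- matrix(numeric(0), 0, 2)
  vals <- numeric(0)
  for (i in seq_along(v)) {
    # greedy non-maximum suppression: a peak is the largest value within
    # min_sep of itself
    if (nrow(peaks) == 0 ||
        min(sqrt((peaks[, 1] - idx[i, 1])^2 + (peaks[, 2] - idx[i, 2])^2)) >
          min_sep) {
      peaks <- rbind(peaks, idx[i, ])
      vals <- c(vals, v[i])
    }
  }
  tibble(A = peaks[, 1] - 1, B = peaks[, 2] - 1, occupancy = vals)
}

#' Basin geometry of a tristable toggle switch
#'
#' Identifies the progenitor (central) and the two committed wells from a
#' [quasi_potential()] estimate and builds linear separatrices: for each
#' committed well, the barrier point is the occupancy minimum along the
#' straight segment from the central well, and the separatrix is the line
#' through that point perpendicular to the segment. A state is called
#' committed once it lies beyond the separatrix.
#'
#' @param qp A `quasi_potential` object with exactly 3 wells.
#' @return A list of class `toggle_basins`: `central`, `well_A`, `well_B`
#'   (coordinates), and per-lineage separatrix normals/offsets.
#' @export
toggle_basins <- function(qp) {
  stopifnot(inherits(qp, "quasi_potential"))
  if (qp$n_wells != 3)
    stop(sprintf("parameterisation is not tristable (found %d wells)",
                 qp$n_wells), call. = FALSE)
  w <- qp$wells
  bal <- abs(w$A - w$B) / pmax(w$A + w$B, 1)
  cen <- which.min(bal)
  others <- setdiff(1:3, cen)
  aw <- others[which.max(w$A[others] - w$B[others])]
  bw <- setdiff(others, aw)
  centre <- c(w$A[cen], w$B[cen])
  sep <- function(target) {
    tw <- c(w$A[target], w$B[target])
    u <- (tw - centre); u <- u / sqrt(sum(u^2))
    # barrier: smoothed-occupancy minimum along the segment
    tt <- seq(0.15, 0.85, length.out = 60)
    pts <- cbind(centre[1] + tt * (tw[1] - centre[1]),
                 centre[2] + tt * (tw[2] - centre[2]))
    ij <- pmax(round(pts) + 1, 1)
    occ <- qp$smoothed[cbind(pmin(ij[, 1], nrow(qp$smoothed)),
                             pmin(ij[, 2], ncol(qp$smoothed)))]
    bar <- pts[which.min(occ), ]
    list(normal = u, offset = sum(u * bar))
  }
  structure(list(central = centre,
                 well_A = c(w$A[aw], w$B[aw]), well_B = c(w$A[bw], w$B[bw]),
                 sep_A = sep(aw), sep_B = sep(bw)),
            class = "toggle_basins")
}

#' Classify toggle states into basins
#'
#' @param basins A [toggle_basins()] object.
#' @param A,B Copy numbers (vectorised).
#' @return Character vector: `"progenitor"`, `"A_committed"`, or
#'   `"B_committed"`.
#' @export
basin_of <- function(basins, A, B) {
  sa <- A * basins$sep_A$normal[1] + B * basins$sep_A$normal[2] -
    basins$sep_A$offset
  sb <- A * basins$sep_B$normal[1] + B * basins$sep_B$normal[2] -
    basins$sep_B$offset
  out <- rep("progenitor", length(A))
  out[sa > 0 & sa >= sb] <- "A_committed"
  out[sb > 0 & sb > sa] <- "B_committed"
  out
}

#' Simulate genealogies from the toggle switch
#'
#' Grows dividing lineages whose intracellular dynamics follow the toggle
#' switch (Gillespie per cell; molecules partitioned at division per the
#' division mode). A branch acquires its marker onset when its trajectory
#' first enters a committed basin (A-basin entry is the GM-like onset,
#' B-basin the MegE-like one); from then on the branch is no longer
#' followed, matching how genealogies with terminal onsets are tracked.
#' Exports a standard genealogy table plus per-cell `(A, B)` signal tracks
#' (intensity = A copy number, `area = 1`; B exported in the companion
#' column `intensity_b`).
#'
#' @inheritParams ssa_toggle
#' @param basins A [toggle_basins()] object for the same parameters.
#' @param n_trees Number of genealogies.
#' @param cellcycle Cycle spec as in [sim_config()].
#' @param movie_end Observation window in hours.
#' @param record_dt Track sampling interval in hours.
#' @param burnin Pre-movie equilibration of the founding cell inside the
#'   progenitor basin, in hours (roots that commit during burn-in are
#'   redrawn). This emulates sorting undifferentiated progenitors before
#'   imaging: without it every tree starts exactly at the central fixed
#'   point and the relaxation transient synchronises early escapes to the
#'   movie start.
#' @return A list of class `toggle_sim`: `trees` (genealogy tibble with
#'   `fate_label` set from the basin reached), `tracks` (signal tibble with
#'   extra column `intensity_b`), and `basin_calls` (tibble `tree_id`,
#'   `cell_id`, `state`, `entry_time`).
#' @export
simulate_toggle_trees <- function(params, basins, n_trees = 50,
                                  cellcycle = list(family = "gamma",
                                                   mean = 12, sd = 5),
                                  movie_end = 72, record_dt = 0.5,
                                  init = NULL, burnin = 24) {
  stopifnot(inherits(params, "toggle_params"), inherits(basins, "toggle_basins"))
  if (is.null(init)) init <- round(basins$central)
  draw_root <- function() {
    if (burnin <= 0) return(as.integer(init))
    for (try in 1:100) {
      tr <- ssa_toggle(params, init, burnin, record_dt = 1)
      if (all(basin_of(basins, tr$A, tr$B) == "progenitor"))
        return(as.integer(c(tr$A[nrow(tr)], tr$B[nrow(tr)])))
    }
    stop("could not equilibrate a progenitor root; barrier too low?",
         call. = FALSE)
  }
  rows <- list(); track_rows <- list(); call_rows <- list()
  for (tr in seq_len(n_trees)) {
    tid <- sprintf("g%03d", tr)
    root_state <- draw_root()
    stack <- list(list(k = 1, birth = 0, gen = 0L,
                       A = root_state[1], B = root_state[2]))
    any_A <- FALSE; any_B <- FALSE
    while (length(stack)) {
      cell <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      cyc <- sample_cycle(cellcycle, cell$gen)
      sched <- cell$birth + cyc
      end <- min(sched, movie_end)
      reason <- if (sched <= movie_end) "division" else "movie_end"
      traj <- ssa_toggle(params, c(cell$A, cell$B), end - cell$birth,
                         record_dt)
      states <- basin_of(basins, traj$A, traj$B)
      committed <- which(states != "progenitor")
      onset <- NA_real_
      call <- "progenitor"; entry <- NA_real_
      if (length(committed)) {
        j <- committed[1]
        call <- states[j]
        entry <- cell$birth + traj$time_h[j]
        onset <- entry
        if (call == "A_committed") any_A <- TRUE else any_B <- TRUE
        if (reason == "division") reason <- "lost"  # branch not followed on
      }
      if (reason == "division") {
        nA <- traj$A[nrow(traj)]; nB <- traj$B[nrow(traj)]
        if (params$division == "binomial") {
          a1 <- stats::rbinom(1, nA, 0.5); b1 <- stats::rbinom(1, nB, 0.5)
          kid_states <- list(c(a1, b1), c(nA - a1, nB - b1))
        } else kid_states <- list(c(nA, nB), c(nA, nB))
        for (side in 0:1)
          stack[[length(stack) + 1]] <-
            list(k = 2 * cell$k + side, birth = end, gen = cell$gen + 1L,
                 A = kid_states[[side + 1]][1], B = kid_states[[side + 1]][2])
      }
      cid <- sprintf("%.0f", cell$k)
      rows[[length(rows) + 1]] <- tibble(
        tree_id = tid, cell_id = cid,
        parent_id = if (cell$k == 1) NA_character_
                    else sprintf("%.0f", cell$k %/% 2),
        birth_time = cell$birth, end_time = end, end_reason = reason,
        onset_time = onset, generation = cell$gen)
      track_rows[[length(track_rows) + 1]] <- tibble(
        tree_id = tid, cell_id = cid, time_h = cell$birth + traj$time_h,
        intensity = traj$A, area = 1, intensity_b = traj$B)
      call_rows[[length(call_rows) + 1]] <- tibble(
        tree_id = tid, cell_id = cid, state = call, entry_time = entry)
    }
    fate <- if (any_A && any_B) "mixed" else if (any_A) "GM"
            else if (any_B) "MegE" else "none"
    for (j in seq_along(rows)) if (rows[[j]]$tree_id[1] == tid)
      rows[[j]]$fate_label <- fate
  }
  trees <- validate_genealogies(bind_rows(rows))
  structure(list(trees = trees, tracks = bind_rows(track_rows),
                 basin_calls = bind_rows(call_rows)),
            class = "toggle_sim")
}

#' Lineage fate of predicted decision branches
#'
#' Assigns each predicted decision cell the fate of its branch: `"GM"` when
#' every committed basin call in its subtree is A-committed, `"MegE"` when
#' all are B-committed, `"mixed"` otherwise and `NA` when no cell below it
#' committed. Because lineages escape the progenitor basin independently, a
#' single genealogy can contain decisions of both fates; fate is therefore a
#' property of the decision branch, not of the tree.
#'
#' @param sim A `toggle_sim` object.
#' @param decisions Tibble `tree_id`, `cell_id` of decision cells.
#' @return Character vector of fates, parallel to the rows of `decisions`.
#' @export
decision_branch_fate <- function(sim, decisions) {
  stopifnot(inherits(sim, "toggle_sim"))
  vapply(seq_len(nrow(decisions)), function(i) {
    tid <- decisions$tree_id[i]
    sub <- subtree(filter(sim$trees, .data$tree_id == tid),
                   decisions$cell_id[i])
    st <- sim$basin_calls$state[sim$basin_calls$tree_id == tid &
                                  sim$basin_calls$cell_id %in% sub$cell_id]
    st <- st[st != "progenitor"]
    if (!length(st)) NA_character_
    else if (all(st == "A_committed")) "GM"
    else if (all(st == "B_committed")) "MegE"
    else "mixed"
  }, character(1))
}

#' Align single-cell trajectories to the predicted decision time
#'
#' Re-indexes per-cell `(A, B)` trajectories so that time 0 is the
#' predicted decision time of the lineage (the posterior-mean latent
#' decision time of each rank-1 predicted decision cell); trajectories of
#' the decision cell and its descendants are collected over the alignment
#' window. The divergence of the two factors (their difference) around 0
#' visualises whether the inferred decision coincides with the tilt of the
#' toggle.
#'
#' @param sim A `toggle_sim` object.
#' @param dec_times Tibble `tree_id`, `cell_id`, `decision_time` (e.g. from
#'   [decision_time_posterior()] on the predicted decision cells, or the
#'   ground-truth basin entry times for a positive control).
#' @param window Alignment window `c(lo, hi)` in hours around 0.
#' @return A tibble `tree_id`, `origin_cell`, `cell_id`, `rel_time_h`, `A`,
#'   `B`, `divergence` (= A - B).
#' @export
divergence_alignment <- function(sim, dec_times, window = c(-24, 24)) {
  trees <- if (inherits(sim, "toggle_sim")) sim$trees else sim
  tracks <- if (inherits(sim, "toggle_sim")) sim$tracks else
    stop("give a toggle_sim", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(dec_times)), function(i) {
    tid <- dec_times$tree_id[i]; d <- dec_times$cell_id[i]
    t0 <- dec_times$decision_time[i]
    df <- filter(trees, .data$tree_id == tid)
    ids <- subtree(df, d)$cell_id
    filter(tracks, .data$tree_id == tid, .data$cell_id %in% ids) %>%
      mutate(rel_time_h = .data$time_h - t0) %>%
      filter(.data$rel_time_h >= window[1], .data$rel_time_h <= window[2]) %>%
      dplyr::transmute(tree_id = tid, origin_cell = d,
                       cell_id = .data$cell_id,
                       rel_time_h = .data$rel_time_h,
                       A = .data$intensity, B = .data$intensity_b,
                       divergence = .data$intensity - .data$intensity_b)
  })
}
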