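#' @useDynLib delaytree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Discretise a validated genealogy table onto a uniform time grid and bring
# cells into post-order (children before mothers). Descendants of onset cells
# are pruned: once the expression process is absorbed the subtree below
# carries no information. Returns 0-based child indices for the C++ DP.
preprocess_forest <- function(cells, h) {
  cells <- validate_genealogies(cells)
  keep <- cells %>%
    group_by(.data$tree_id) %>%
    dplyr::group_modify(function(df, key) {
      pidx <- match(df$parent_id, df$cell_id)
      below <- rep(FALSE, nrow(df))
      for (j in order(df$generation)) {
        p <- pidx[j]
        if (!is.na(p)) below[j] <- below[p] || !is.na(df$onset_time[p])
      }
      df[!below, ]
    }) %>%
    ungroup() %>%
    arrange(.data$tree_id, -.data$generation)
  ib <- as.integer(round(keep$birth_time / h))
  ie <- pmax(ib + 1L, as.integer(round(keep$end_time / h)))
  ion <- ifelse(is.na(keep$onset_time), -1L,
                pmin(pmax(as.integer(round(keep$onset_time / h)), ib), ie))
  key <- paste(keep$tree_id, keep$cell_id)
  child_of <- split(seq_len(nrow(keep)),
                    factor(paste(keep$tree_id, keep$parent_id), levels = key))
  c1 <- rep(-1L, nrow(keep)); c2 <- rep(-1L, nrow(keep))
  for (i in seq_len(nrow(keep))) {
    kids <- child_of[[i]]
    if (length(kids) == 2) { c1[i] <- kids[1] - 1L; c2[i] <- kids[2] - 1L }
    else if (length(kids) == 1)
      stop("internal: dividing cell lost a child during pruning")
  }
  list(cells = keep, ib = ib, ie = ie, ion = as.integer(ion),
       c1 = c1, c2 = c2, root = is.na(keep$parent_id),
       h = h, K = max(ie))
}

inherit_code <- function(mode) match(mode, c("copy", "binomial")) - 1L

#' Likelihood of observed genealogies under the decision + delay model
#'
#' Computes, per tree, the log-likelihood of the observed division structure
#' and marker onsets: the sum over all differentiation scenarios ("hidden
#' trees", antichains of decision-bearing cells covering every onset) of the
#' scenario likelihood. The default method is a post-order dynamic
#' programme whose per-cell messages are sum-product vectors over the
#' sub-threshold expression state; `method = "enumeration"` sums scenarios
#' explicitly (exponential cost, small trees only) and serves as an
#' independent route through [likelihood_undiff()] and
#' [likelihood_subtree()].
#'
#' Latent decision times are integrated on a uniform grid of step `h`
#' (trapezoidal rule); all event times are snapped to that grid.
#'
#' @param cells A validated genealogy tibble (any number of trees).
#' @param theta A [decision_params()] object.
#' @param eta A [delay_params()] object.
#' @param h Grid step in hours (default 0.25).
#' @param inheritance_mode State inheritance at division: `"copy"` or
#'   `"binomial"`.
#' @param method `"dp"` (default) or `"enumeration"`.
#' @return A tibble with `tree_id` and `loglik`.
#' @export
likelihood_tree <- function(cells, theta, eta, h = 0.25,
                            inheritance_mode = c("copy", "binomial"),
                            method = c("dp", "enumeration")) {
  inheritance_mode <- match.arg(inheritance_mode)
  method <- match.arg(method)
  stopifnot(inherits(theta, "decision_params"), inherits(eta, "delay_params"))
  if (method == "enumeration") {
    ids <- unique(cells$tree_id)
    ll <- vapply(ids, function(id)
      likelihood_tree_enum(filter(cells, .data$tree_id == id), theta, eta, h,
                           inheritance_mode), numeric(1))
    return(tibble(tree_id = ids, loglik = unname(ll)))
  }
  pre <- preprocess_forest(cells, h)
  eng <- delay_engine(eta, h, pre$K * h)
  res <- forest_dp_cpp(pre$ib, pre$ie, pre$ion, pre$c1, pre$c2, pre$root,
                       theta$a0, theta$a1, eng$P, h, eta$alpha,
                       inherit_code(inheritance_mode), TRUE)
  tibble(tree_id = pre$cells$tree_id[pre$root],
         loglik = res$logB[pre$root])
}

#' Enumerate the hidden trees of a genealogy
#'
#' Lists every differentiation scenario: an antichain of decision cells such
#' that each observed onset lies at or below a decision cell. Cells
#' unrelated to any onset may or may not carry an (invisible) decision, so
#' both variants are enumerated. Intended as a brute-force oracle; the
#' number of scenarios grows double-exponentially, hence the size guard.
#'
#' @param cells A genealogy tibble holding a single tree.
#' @param max_cells Guard on the number of cells (default 31).
#' @return A list of character vectors of decision `cell_id`s.
#' @export
enumerate_hidden_trees <- function(cells, max_cells = 31) {
  cells <- validate_genealogies(cells)
  if (length(unique(cells$tree_id)) != 1)
    stop("give a single tree", call. = FALSE)
  if (nrow(cells) > max_cells)
    stop(sprintf("tree has %d cells (> %d); enumeration refused", nrow(cells),
                 max_cells), call. = FALSE)
  pidx <- match(cells$parent_id, cells$cell_id)
  kids_of <- lapply(seq_len(nrow(cells)), function(i) which(pidx == i))
  rec <- function(i) {
    own <- list(cells$cell_id[i])
    if (!is.na(cells$onset_time[i])) return(own)   # onset: cover here or above
    kids <- kids_of[[i]]
    if (length(kids) == 0) return(c(own, list(character(0))))
    s1 <- rec(kids[1]); s2 <- rec(kids[2])
    combos <- unlist(lapply(s1, function(a) lapply(s2, function(b) c(a, b))),
                     recursive = FALSE)
    c(own, combos)
  }
  rec(which(is.na(cells$parent_id)))
}

#' Log-likelihood of the undecided part of a hidden tree
#'
#' Cells in `U` (not at or below any decision cell) contribute the
#' probability of not deciding during their lifetime,
#' `exp(-int_{birth}^{end} lambda)`; the process is memory-less so the
#' contribution factorises across cells.
#'
#' @param cells Genealogy rows forming `U`.
#' @inheritParams likelihood_tree
#' @return The summed log-probability.
#' @export
likelihood_undiff <- function(cells, theta) {
  if (nrow(cells) == 0) return(0)
  -sum(decision_cumhaz(cells$birth_time, cells$end_time, theta))
}

# sum-product state messages for an already-decided subtree in post-order
state_messages <- function(pre, idx, eng, inheritance_mode) {
  S <- eng$eta$x_star
  A <- matrix(0, S, length(idx))
  la <- numeric(length(idx))
  pos <- match(seq_along(pre$ib) - 1L, idx - 1L)   # global (0-based) -> local
  for (j in seq_along(idx)) {
    i <- idx[j]
    kb <- pre$ib[i]; ke <- pre$ie[i]; kon <- pre$ion[i]
    c1 <- pre$c1[i]; c2 <- pre$c2[i]
    if (kon >= 0) {
      Av <- eng$eta$alpha * matrix(eng$P[, , kon - kb + 1], S, S)[, S]
      lav <- 0
    } else if (c1 >= 0) {
      j1 <- pos[c1 + 1L]; j2 <- pos[c2 + 1L]
      W <- combine_daughters(A[, j1], A[, j2], inheritance_mode)
      Av <- matrix(eng$P[, , ke - kb + 1], S, S) %*% W
      lav <- la[j1] + la[j2]
    } else {
      Av <- rowSums(matrix(eng$P[, , ke - kb + 1], S, S))
      lav <- 0
    }
    m <- max(Av)
    if (m > 0) { A[, j] <- Av / m; la[j] <- lav + log(m) }
    else { la[j] <- -Inf }
  }
  list(A = A, la = la, pos = pos)
}

combine_daughters <- function(a1, a2, mode) {
  if (mode == "copy") return(a1 * a2)
  S <- length(a1)
  vapply(seq_len(S) - 1L, function(y) {
    k <- 0:y
    sum(stats::dbinom(k, y, 0.5) * a1[k + 1] * a2[y - k + 1])
  }, numeric(1))
}

#' Log-likelihood of a decision-rooted subtree
#'
#' The likelihood contribution of one `D_i`: the subtree rooted at a
#' decision cell, with leaves that are onset cells (observed first-passage
#' times) or censored cells (no crossing by their end). The root's latent
#' decision time is integrated over its admissible window, weighted by
#' `lambda(t') exp(-int_{birth}^{t'} lambda)` (conditioned on lineage
#' survival to the root's birth; survival factors of ancestors live in `U`).
#' From the decision the expression state starts at zero molecules and is
#' propagated down the tree by sum-product messages over the sub-threshold
#' states, with the inheritance rule applied at divisions.
#'
#' @param cells A genealogy tibble holding the tree that contains `root_cell`.
#' @param root_cell `cell_id` of the decision cell.
#' @inheritParams likelihood_tree
#' @return The log-likelihood of `D_i` (can be `-Inf`, e.g. an onset leaf
#'   with `alpha = 0`).
#' @export
likelihood_subtree <- function(cells, root_cell, theta, eta, h = 0.25,
                               inheritance_mode = c("copy", "binomial")) {
  inheritance_mode <- match.arg(inheritance_mode)
  pre <- preprocess_forest(cells, h)
  r <- which(pre$cells$cell_id == root_cell)
  if (length(r) != 1) stop(sprintf("unknown cell_id '%s'", root_cell),
                           call. = FALSE)
  idx <- subtree_indices(pre, r)
  eng <- delay_engine(eta, h, pre$K * h)
  msg <- state_messages(pre, idx, eng, inheritance_mode)
  decide_here_loglik(pre, r, theta, eng, msg, inheritance_mode)
}

# post-order global indices of the subtree rooted at local row r
subtree_indices <- function(pre, r) {
  n <- length(pre$ib)
  keep <- logical(n); keep[r] <- TRUE
  for (i in rev(seq_len(n))) {   # reverse post-order = parents first
    if (keep[i] && pre$c1[i] >= 0) keep[c(pre$c1[i], pre$c2[i]) + 1L] <- TRUE
  }
  which(keep)   # increasing order preserves post-order within the subtree
}

# log integral over the root's decision time of density x downstream message
decide_here_loglik <- function(pre, i, theta, eng, msg, mode) {
  S <- eng$eta$x_star
  h <- pre$h
  kb <- pre$ib[i]; ke <- pre$ie[i]; kon <- pre$ion[i]
  iu <- if (kon >= 0) kon else ke
  if (iu == kb) return(-Inf)
  lsc <- 0
  if (kon < 0 && pre$c1[i] >= 0) {
    j1 <- msg$pos[pre$c1[i] + 1L]; j2 <- msg$pos[pre$c2[i] + 1L]
    W <- combine_daughters(msg$A[, j1], msg$A[, j2], mode)
    lsc <- msg$la[j1] + msg$la[j2]
  }
  ks <- kb:iu
  tj <- ks * h
  g <- vapply(ks, function(k) {
    sl <- matrix(eng$P[, , (if (kon >= 0) kon else ke) - k + 1], S, S)
    if (kon >= 0) eng$eta$alpha * sl[1, S]
    else if (pre$c1[i] >= 0) sum(sl[1, ] * W)
    else sum(sl[1, ])
  }, numeric(1))
  # exact per-interval decision mass times trapezoid-averaged delay factor
  Sj <- exp(-decision_cumhaz(rep(kb * h, length(tj)), tj, theta))
  val <- sum(-diff(Sj) * (g[-length(g)] + g[-1]) / 2)
  if (val <= 0) -Inf else lsc + log(val)
}

#' Posterior-mean latent decision time of decision cells
#'
#' Within a given scenario, the decision time of a decision cell is latent
#' with density proportional to `lambda(t') exp(-int_{birth}^{t'} lambda)`
#' times the downstream delay likelihood. Returns its posterior mean per
#' requested decision cell (used e.g. to align trajectories to the inferred
#' decision).
#'
#' @inheritParams likelihood_tree
#' @param decisions Tibble `tree_id`, `cell_id` of decision cells (e.g. the
#'   rank-1 rows of [predict_decisions()]).
#' @return `decisions` with an added `decision_time` column (hours).
#' @export
decision_time_posterior <- function(cells, theta, eta, decisions, h = 0.25,
                                    inheritance_mode = c("copy", "binomial")) {
  inheritance_mode <- match.arg(inheritance_mode)
  cells <- validate_genealogies(cells)
  out <- decisions
  out$decision_time <- NA_real_
  for (tid in unique(decisions$tree_id)) {
    df <- filter(cells, .data$tree_id == tid)
    pre <- preprocess_forest(df, h)
    eng <- delay_engine(eta, h, pre$K * h)
    for (i in which(decisions$tree_id == tid)) {
      r <- which(pre$cells$cell_id == decisions$cell_id[i])
      if (length(r) != 1) next
      idx <- subtree_indices(pre, r)
      msg <- state_messages(pre, idx, eng, inheritance_mode)
      out$decision_time[i] <-
        decide_here_moment(pre, r, theta, eng, msg, inheritance_mode)
    }
  }
  out
}

# posterior mean of the latent decision time t' for cell i as decision cell
decide_here_moment <- function(pre, i, theta, eng, msg, mode) {
  S <- eng$eta$x_star
  h <- pre$h
  kb <- pre$ib[i]; ke <- pre$ie[i]; kon <- pre$ion[i]
  iu <- if (kon >= 0) kon else ke
  if (iu == kb) return(kb * h)
  if (kon < 0 && pre$c1[i] >= 0) {
    j1 <- msg$pos[pre$c1[i] + 1L]; j2 <- msg$pos[pre$c2[i] + 1L]
    W <- combine_daughters(msg$A[, j1], msg$A[, j2], mode)
  }
  ks <- kb:iu
  tj <- ks * h
  g <- vapply(ks, function(k) {
    sl <- matrix(eng$P[, , (if (kon >= 0) kon else ke) - k + 1], S, S)
    if (kon >= 0) eng$eta$alpha * sl[1, S]
    else if (pre$c1[i] >= 0) sum(sl[1, ] * W)
    else sum(sl[1, ])
  }, numeric(1))
  Sj <- exp(-decision_cumhaz(rep(kb * h, length(tj)), tj, theta))
  wint <- -diff(Sj) * (g[-length(g)] + g[-1]) / 2
  tmid <- (tj[-length(tj)] + tj[-1]) / 2
  den <- sum(wint)
  if (den <= 0) mean(range(tj)) else sum(wint * tmid) / den
}

# explicit scenario sum (oracle route)
likelihood_tree_enum <- function(cells, theta, eta, h, inheritance_mode) {
  cells <- validate_genealogies(cells)
  pre <- preprocess_forest(cells, h)
  eng <- delay_engine(eta, h, pre$K * h)
  scen <- enumerate_hidden_trees(cells)
  pidx <- match(pre$cells$parent_id, pre$cells$cell_id)
  lls <- vapply(scen, function(dec) {
    # membership: at/below a decision cell?
    dec_i <- match(dec, pre$cells$cell_id)
    inD <- logical(nrow(pre$cells)); inD[dec_i] <- TRUE
    for (j in order(pre$cells$generation)) {
      p <- pidx[j]
      if (!is.na(p) && inD[p]) inD[j] <- TRUE
    }
    # survival factors of U on the same snapped grid as the DP
    llU <- -sum(decision_cumhaz(pre$ib[!inD] * h, pre$ie[!inD] * h, theta))
    llD <- vapply(dec_i, function(r) {
      idx <- subtree_indices(pre, r)
      msg <- state_messages(pre, idx, eng, inheritance_mode)
      decide_here_loglik(pre, r, theta, eng, msg, inheritance_mode)
    }, numeric(1))
    llU + sum(llD)
  }, numeric(1))
  m <- max(lls)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(lls - m)))
}

#' Most likely hidden trees (MAP and k-best)
#'
#' Finds the `k` highest-likelihood differentiation scenarios of one
#' genealogy by a max-sum dynamic programme over the same per-cell messages
#' as [likelihood_tree()] (each candidate keeps its decision-cell set;
#' children's candidate lists are combined at divisions). Ties within
#' `1e-12` log-units prefer fewer decision cells (the earlier decision).
#'
#' @inheritParams likelihood_tree
#' @param k Number of top scenarios to return.
#' @param tree_id Tree to analyse when `cells` holds several.
#' @return A tibble with `scenario_rank`, `scenario_loglik` and the
#'   list-column `decision_cells` (character vectors of `cell_id`s).
#' @export
map_hidden_tree <- function(cells, theta, eta, k = 1, h = 0.25,
                            inheritance_mode = c("copy", "binomial"),
                            tree_id = NULL) {
  inheritance_mode <- match.arg(inheritance_mode)
  if (!is.null(tree_id)) cells <- filter(cells, .data$tree_id == !!tree_id)
  if (length(unique(cells$tree_id)) != 1)
    stop("give a single tree (or tree_id)", call. = FALSE)
  pre <- preprocess_forest(cells, h)
  eng <- delay_engine(eta, h, pre$K * h)
  res <- forest_dp_cpp(pre$ib, pre$ie, pre$ion, pre$c1, pre$c2, pre$root,
                       theta$a0, theta$a1, eng$P, h, eta$alpha,
                       inherit_code(inheritance_mode), TRUE)
  lopt1 <- res$log_decide_here
  n <- length(pre$ib)
  surv <- -decision_cumhaz(pre$ib * h, pre$ie * h, theta)
  better <- function(a, b) {   # is candidate a better than b?
    if (abs(a$val - b$val) <= 1e-12) length(a$cells) < length(b$cells)
    else a$val > b$val
  }
  top_k <- function(cands) {
    o <- order(vapply(cands, `[[`, numeric(1), "val"),
               -vapply(cands, function(c) length(c$cells), integer(1)),
               decreasing = TRUE)
    cands[o[seq_len(min(k, length(o)))]]
  }
  best <- vector("list", n)
  for (i in seq_len(n)) {
    cands <- list(list(val = lopt1[i], cells = i))
    if (pre$ion[i] < 0) {
      if (pre$c1[i] >= 0) {
        b1 <- best[[pre$c1[i] + 1L]]; b2 <- best[[pre$c2[i] + 1L]]
        for (x in b1) for (y in b2)
          cands[[length(cands) + 1]] <-
            list(val = surv[i] + x$val + y$val, cells = c(x$cells, y$cells))
      } else {
        cands[[length(cands) + 1]] <- list(val = surv[i], cells = integer(0))
      }
    }
    cands <- cands[vapply(cands, function(c) c$val > -Inf, logical(1))]
    if (!length(cands)) cands <- list(list(val = -Inf, cells = integer(0)))
    best[[i]] <- top_k(cands)
  }
  out <- best[[which(pre$root)]]
  tibble(scenario_rank = seq_along(out),
         scenario_loglik = vapply(out, `[[`, numeric(1), "val"),
         decision_cells = lapply(out, function(c)
           sort(pre$cells$cell_id[c$cells])))
}

#' Predict decision cells across a set of genealogies
#'
#' Runs [map_hidden_tree()] on every tree and emits one row per (tree,
#' cell, scenario): which cells are predicted to carry the lineage decision,
#' in which generation, under which scenario rank.
#'
#' @inheritParams likelihood_tree
#' @param k Scenarios per tree (default 1: the MAP scenario only).
#' @return A tibble `tree_id, cell_id, is_predicted_decision,
#'   decision_generation, scenario_rank, scenario_loglik`.
#' @export
predict_decisions <- function(cells, theta, eta, k = 1, h = 0.25,
                              inheritance_mode = c("copy", "binomial")) {
  inheritance_mode <- match.arg(inheritance_mode)
  cells <- validate_genealogies(cells)
  ids <- unique(cells$tree_id)
  purrr::map_dfr(ids, function(id) {
    df <- filter(cells, .data$tree_id == id)
    mh <- map_hidden_tree(df, theta, eta, k = k, h = h,
                          inheritance_mode = inheritance_mode)
    purrr::map_dfr(seq_len(nrow(mh)), function(r) {
      dec <- mh$decision_cells[[r]]
      tibble(tree_id = id, cell_id = dec, is_predicted_decision = TRUE,
             decision_generation =
               df$generation[match(dec, df$cell_id)],
             scenario_rank = mh$scenario_rank[r],
             scenario_loglik = mh$scenario_loglik[r])
    })
  })
}

#' Generation histogram of predicted decisions
#'
#' Summarises in which generation (root = 0) the predicted decision cells
#' of a tree set sit.
#'
#' @param decisions Output of [predict_decisions()] (rank-1 rows are used).
#' @return A tibble `generation`, `n`, `fraction`.
#' @export
predicted_decision_generation <- function(decisions) {
  d <- filter(decisions, .data$scenario_rank == 1)
  d %>%
    dplyr::count(generation = .data$decision_generation) %>%
    mutate(fraction = .data$n / sum(.data$n))
}
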