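# fixture builders shared by the test files (everything is generated in code)

# random small genealogy with random topology, lifetimes and terminal onsets
random_genealogy <- function(id = "t1", max_cells = 15, p_div = 0.55,
                             p_onset = 0.35, max_depth = 4) {
  rows <- list()
  n <- 0
  grow <- function(k, birth, gen, blocked) {
    n <<- n + 1
    end <- birth + stats::runif(1, 3, 15)
    onset <- NA_real_
    if (!blocked && stats::runif(1) < p_onset)
      onset <- stats::runif(1, birth, end)
    divide <- n + 2 <= max_cells && stats::runif(1) < p_div && gen < max_depth
    rows[[length(rows) + 1]] <<- tibble::tibble(
      tree_id = id, cell_id = as.character(k),
      parent_id = if (k == 1) NA_character_ else as.character(k %/% 2),
      birth_time = birth, end_time = end,
      end_reason = if (divide) "division" else "movie_end",
      onset_time = onset, fate_label = "none")
    if (divide) {
      grow(2 * k, end, gen + 1, blocked || !is.na(onset))
      grow(2 * k + 1, end, gen + 1, blocked || !is.na(onset))
    }
  }
  grow(1, 0, 0, FALSE)
  dplyr::bind_rows(rows)
}

# single cell, or a division path with censored sibling leaves (cells on the
# path are 1, 2, 4, ...; siblings 3, 5, ... are leaves), onset on the last
# path cell
chain_genealogy <- function(lifetimes, onset_last = NA_real_, id = "chain") {
  n <- length(lifetimes)
  b <- cumsum(c(0, lifetimes[-n]))
  e <- cumsum(lifetimes)
  if (n == 1)
    return(tibble::tibble(tree_id = id, cell_id = "1",
                          parent_id = NA_character_, birth_time = 0,
                          end_time = e, end_reason = "movie_end",
                          onset_time = onset_last, fate_label = "none"))
  path <- tibble::tibble(
    tree_id = id, cell_id = as.character(2^(seq_len(n) - 1)),
    parent_id = c(NA_character_, as.character(2^(seq_len(n - 1) - 1))),
    birth_time = b, end_time = e,
    end_reason = c(rep("division", n - 1), "movie_end"),
    onset_time = c(rep(NA_real_, n - 1), onset_last),
    fate_label = "none")
  sibs <- tibble::tibble(
    tree_id = id, cell_id = as.character(2^(seq_len(n - 1)) + 1),
    parent_id = as.character(2^(seq_len(n - 1) - 1)),
    birth_time = e[-n], end_time = e[-n] + lifetimes[-1],
    end_reason = "movie_end", onset_time = NA_real_, fate_label = "none")
  dplyr::bind_rows(path, sibs)
}

# perfect binary tree of given depth with unit-ish lifetimes
perfect_genealogy <- function(depth = 2, life = 5, onset_leaves = FALSE,
                              id = "perfect") {
  rows <- list()
  for (g in 0:depth) {
    for (k in (2^g):(2^(g + 1) - 1)) {
      leaf <- g == depth
      rows[[length(rows) + 1]] <- tibble::tibble(
        tree_id = id, cell_id = as.character(k),
        parent_id = if (k == 1) NA_character_ else as.character(k %/% 2),
        birth_time = g * life, end_time = (g + 1) * life,
        end_reason = if (leaf) "movie_end" else "division",
        onset_time = if (leaf && onset_leaves) (g + 0.5) * life else NA_real_,
        fate_label = "none")
    }
  }
  dplyr::bind_rows(rows)
}

# scenario log-likelihood summed by hand from the exported building blocks
scenario_loglik_by_hand <- function(cells, decision_cells, theta, eta,
                                    h = 0.25) {
  pre <- delaytree:::preprocess_forest(cells, h)
  pidx <- match(pre$cells$parent_id, pre$cells$cell_id)
  dec_i <- match(decision_cells, pre$cells$cell_id)
  inD <- logical(nrow(pre$cells))
  inD[dec_i] <- TRUE
  for (j in order(pre$cells$generation)) {
    p <- pidx[j]
    if (!is.na(p) && inD[p]) inD[j] <- TRUE
  }
  llU <- -sum(decision_cumhaz(pre$ib[!inD] * h, pre$ie[!inD] * h, theta))
  llD <- vapply(decision_cells, function(d)
    likelihood_subtree(cells, d, theta, eta, h = h), numeric(1))
  llU + sum(llD)
}
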