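#' Per-cell marker production slopes
#'
#' Fits an ordinary least-squares line to each cell's signal over its
#' lifetime and reports the slope (the production rate proxy). With
#' `use_concentration = TRUE` (default) the response is intensity divided
#' by cell area, i.e. the concentration.
#'
#' @param tracks A signal-track tibble (`tree_id`, `cell_id`, `time_h`,
#'   `intensity`, `area`).
#' @param use_concentration Fit intensity/area instead of raw intensity.
#' @param min_samples Cells with fewer samples are skipped with a warning.
#' @return A tibble `tree_id`, `cell_id`, `slope` (units per hour),
#'   `intercept`, `fit_residual` (residual standard deviation),
#'   `n_samples`.
#' @export
fit_cell_slopes <- function(tracks, use_concentration = TRUE,
                            min_samples = 3) {
  y <- if (use_concentration) tracks$intensity / tracks$area else
    tracks$intensity
  df <- tracks %>% mutate(.y = y)
  counts <- df %>% dplyr::count(.data$tree_id, .data$cell_id)
  n_skip <- sum(counts$n < min_samples)
  if (n_skip > 0)
    warning(sprintf("%d cell(s) with < %d samples skipped", n_skip,
                    min_samples))
  # closed-form simple OLS per cell (slope = cov(t, y) / var(t))
  df %>%
    group_by(.data$tree_id, .data$cell_id) %>%
    filter(n() >= min_samples) %>%
    summarise(
      slope = stats::cov(.data$time_h, .data$.y) / stats::var(.data$time_h),
      intercept = mean(.data$.y) - .data$slope * mean(.data$time_h),
      fit_residual = sqrt(sum((.data$.y - .data$intercept -
                                 .data$slope * .data$time_h)^2) /
                            max(dplyr::n() - 2, 1)),
      n_samples = dplyr::n(), .groups = "drop")
}

#' Group slopes by generation relative to the predicted decision
#'
#' For every predicted decision cell, its own slope is labelled relative
#' generation `"0"`, its mother's `"-1"` and its daughters' `"+1"`; cells
#' with an observed marker onset form the `"onset"` group. A cell can play
#' several roles across different decision cells (antichains) and then
#' contributes one record per role. Decisions at the root have no `"-1"`
#' record.
#'
#' @param cells A genealogy tibble.
#' @param slopes Output of [fit_cell_slopes()].
#' @param decisions Tibble `tree_id`, `cell_id` of predicted decision cells
#'   (e.g. rank-1 rows of [predict_decisions()]).
#' @return `slopes` rows annotated with `relative_generation` in
#'   `c("-1", "0", "+1", "onset")`.
#' @export
group_by_relative_generation <- function(cells, slopes, decisions) {
  roles <- purrr::map_dfr(seq_len(nrow(decisions)), function(i) {
    tid <- decisions$tree_id[i]; d <- decisions$cell_id[i]
    df <- filter(cells, .data$tree_id == tid)
    r <- df[df$cell_id == d, ]
    if (nrow(r) == 0) return(tibble())
    kids <- df$cell_id[!is.na(df$parent_id) & df$parent_id == d]
    bind_rows(
      tibble(tree_id = tid, cell_id = d, relative_generation = "0"),
      if (!is.na(r$parent_id))
        tibble(tree_id = tid, cell_id = r$parent_id,
               relative_generation = "-1"),
      if (length(kids))
        tibble(tree_id = tid, cell_id = kids, relative_generation = "+1"))
  })
  onset <- cells %>%
    filter(!is.na(.data$onset_time)) %>%
    dplyr::transmute(.data$tree_id, .data$cell_id,
                     relative_generation = "onset")
  bind_rows(roles, onset) %>%
    dplyr::inner_join(slopes, by = c("tree_id", "cell_id"))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Convenience wrapper returning the two-sided rank-sum (Mann-Whitney)
#' p-value: exact for small samples without ties, normal approximation with
#' tie correction otherwise (no continuity correction, so identical samples
#' give p = 1).
#'
#' @param group_a,group_b Numeric samples (both nonempty).
#' @return The two-sided p-value.
#' @export
ranksum_test <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be nonempty", call. = FALSE)
  suppressWarnings(stats::wilcox.test(group_a, group_b,
                                      correct = FALSE)$p.value)
}

#' Pairwise rank-sum comparisons of slope groups
#'
#' @param grouped Output of [group_by_relative_generation()].
#' @param pairs List of 2-vectors of group labels to compare.
#' @return A tibble `group_a`, `group_b`, `n_a`, `n_b`, `p_value`.
#' @export
slope_group_tests <- function(grouped,
                              pairs = list(c("-1", "0"), c("0", "+1"))) {
  purrr::map_dfr(pairs, function(pr) {
    a <- grouped$slope[grouped$relative_generation == pr[1]]
    b <- grouped$slope[grouped$relative_generation == pr[2]]
    tibble(group_a = pr[1], group_b = pr[2], n_a = length(a),
           n_b = length(b),
           p_value = if (length(a) && length(b))
             suppressWarnings(ranksum_test(a, b)) else NA_real_)
  })
}
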