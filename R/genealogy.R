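#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n across all_of rename row_number pull distinct
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

genealogy_cols <- c("tree_id", "cell_id", "parent_id", "birth_time",
                    "end_time", "end_reason", "onset_time", "fate_label")
end_reasons <- c("division", "movie_end", "lost")
fate_labels <- c("GM", "MegE", "mixed", "none")

#' Validate a genealogy table
#'
#' A genealogy table holds one row per tracked cell, possibly for many trees
#' (column `tree_id`). Checks the structural invariants of annotated
#' single-cell genealogies: strictly positive lifetimes, onsets within the
#' cell's lifetime, binary division (a dividing cell has exactly two
#' children, censored cells none), children born exactly when the mother
#' ends, one root per tree, no cycles, and no onset annotations below an
#' onset cell (onset is terminal for a tracked branch). The derived
#' `generation` column (root = 0) is (re)computed.
#'
#' @param cells A data frame with columns `tree_id`, `cell_id`, `parent_id`
#'   (`NA` for roots), `birth_time`, `end_time` (hours), `end_reason`
#'   (`"division"`, `"movie_end"`, `"lost"`), `onset_time` (hours or `NA`)
#'   and `fate_label` (`"GM"`, `"MegE"`, `"mixed"`, `"none"`).
#' @param tol Tolerance for the mother-end/daughter-birth time match, hours.
#' @return The validated table as a tibble with a `generation` column.
#' @export
validate_genealogies <- function(cells, tol = 1e-6) {
  cells <- as_tibble(cells)
  missing <- setdiff(setdiff(genealogy_cols, "fate_label"), names(cells))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!"fate_label" %in% names(cells)) cells$fate_label <- "none"
  if (nrow(cells) == 0) {
    cells$generation <- integer(0)
    return(cells[c(genealogy_cols, "generation")])
  }
  bad <- function(who, rule) {
    stop(sprintf("invalid genealogy: cell '%s': %s", who, rule), call. = FALSE)
  }
  if (anyDuplicated(cells[c("tree_id", "cell_id")]))
    stop("invalid genealogy: duplicated cell_id within a tree", call. = FALSE)
  if (!all(cells$end_reason %in% end_reasons))
    bad(cells$cell_id[!cells$end_reason %in% end_reasons][1],
        "unknown end_reason")
  if (!all(cells$fate_label %in% fate_labels))
    bad(cells$cell_id[!cells$fate_label %in% fate_labels][1],
        "unknown fate_label")
  i <- which(!(cells$end_time > cells$birth_time))
  if (length(i)) bad(cells$cell_id[i[1]], "end_time must exceed birth_time")
  has_on <- !is.na(cells$onset_time)
  i <- which(has_on & (cells$onset_time < cells$birth_time |
                         cells$onset_time > cells$end_time))
  if (length(i)) bad(cells$cell_id[i[1]],
                     "onset_time outside [birth_time, end_time]")

  out <- cells %>%
    group_by(.data$tree_id) %>%
    dplyr::group_modify(function(df, key) {
      id <- df$cell_id
      pidx <- match(df$parent_id, id)
      roots <- which(is.na(df$parent_id))
      if (length(roots) != 1)
        stop(sprintf("invalid genealogy: tree '%s': must have exactly one root",
                     key$tree_id[1]), call. = FALSE)
      orphan <- which(!is.na(df$parent_id) & is.na(pidx))
      if (length(orphan)) bad(id[orphan[1]], "parent_id not present in tree")
      nkids <- tabulate(pidx, nbins = nrow(df))
      i <- which(df$end_reason == "division" & nkids != 2)
      if (length(i)) bad(id[i[1]], "dividing cell must have exactly 2 children")
      i <- which(df$end_reason != "division" & nkids > 0)
      if (length(i)) bad(id[i[1]], "non-dividing cell must have no children")
      i <- which(!is.na(pidx) &
                   abs(df$birth_time - df$end_time[pidx]) > tol)
      if (length(i)) bad(id[i[1]], "birth_time must equal mother's end_time")
      gen <- rep(NA_integer_, nrow(df))
      gen[roots] <- 0L
      frontier <- roots
      while (length(frontier)) {
        nxt <- which(pidx %in% frontier)
        gen[nxt] <- gen[pidx[nxt]] + 1L
        frontier <- nxt
      }
      if (anyNA(gen))
        stop(sprintf("invalid genealogy: tree '%s': cycle or disconnected cells",
                     key$tree_id[1]), call. = FALSE)
      # onsets are terminal: no annotation below an onset-bearing cell
      on_anc <- rep(FALSE, nrow(df))
      ord <- order(gen)
      for (j in ord) {
        p <- pidx[j]
        if (!is.na(p)) on_anc[j] <- on_anc[p] || !is.na(df$onset_time[p])
      }
      i <- which(on_anc & !is.na(df$onset_time))
      if (length(i)) bad(id[i[1]], "onset annotation below an onset cell")
      df$generation <- gen
      df
    }) %>%
    ungroup()
  out[c(genealogy_cols, "generation")]
}

#' Read genealogies from a cell-table file
#'
#' Reads the tab-separated cell-table format (one header line; columns
#' `tree_id cell_id parent_id birth_time_h end_time_h end_reason onset_time_h
#' fate_label`; `NA` for missing parent or onset) and validates it.
#'
#' @param path Path to a cell-table file.
#' @return A validated genealogy tibble (see [validate_genealogies()]).
#' @export
read_genealogies <- function(path) {
  df <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                        col_types = readr::cols(
                          tree_id = readr::col_character(),
                          cell_id = readr::col_character(),
                          parent_id = readr::col_character(),
                          birth_time_h = readr::col_double(),
                          end_time_h = readr::col_double(),
                          end_reason = readr::col_character(),
                          onset_time_h = readr::col_double(),
                          fate_label = readr::col_character()))
  prob <- readr::problems(df)
  if (nrow(prob) > 0)
    stop(sprintf("parse error in '%s' at line %d: %s", path,
                 prob$row[1] + 1L, prob$expected[1]), call. = FALSE)
  df <- rename(df, birth_time = "birth_time_h", end_time = "end_time_h",
               onset_time = "onset_time_h")
  validate_genealogies(df)
}

#' Write genealogies to a cell-table file
#'
#' Inverse of [read_genealogies()]; numeric fields keep full double
#' precision so a written table reads back field-for-field identical.
#'
#' @param cells A validated genealogy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genealogies <- function(cells, path) {
  cells <- validate_genealogies(cells)
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out <- cells %>%
    mutate(birth_time_h = fmt(.data$birth_time),
           end_time_h = fmt(.data$end_time),
           onset_time_h = fmt(.data$onset_time)) %>%
    select(all_of(c("tree_id", "cell_id", "parent_id", "birth_time_h",
                    "end_time_h", "end_reason", "onset_time_h", "fate_label")))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Extract the subtree rooted at a cell
#'
#' Returns the induced subtree (the cell and all its descendants) of one
#' genealogy, preserving all times and annotations.
#'
#' @param cells A genealogy tibble.
#' @param cell_id The root of the requested subtree.
#' @param tree_id Tree to look in; may be omitted when `cells` holds one tree.
#' @return A genealogy tibble fragment (root keeps its original
#'   `generation`; its `parent_id` is set to `NA`).
#' @export
subtree <- function(cells, cell_id, tree_id = NULL) {
  if (is.null(tree_id)) {
    ids <- unique(cells$tree_id)
    if (length(ids) != 1)
      stop("cells holds several trees; give tree_id", call. = FALSE)
    tree_id <- ids
  }
  df <- filter(cells, .data$tree_id == !!tree_id)
  if (!cell_id %in% df$cell_id)
    stop(sprintf("unknown cell_id '%s' in tree '%s'", cell_id, tree_id),
         call. = FALSE)
  keep <- cell_id
  frontier <- cell_id
  while (length(frontier)) {
    kids <- df$cell_id[!is.na(df$parent_id) & df$parent_id %in% frontier]
    keep <- c(keep, kids)
    frontier <- kids
  }
  out <- filter(df, .data$cell_id %in% keep)
  out$parent_id[out$cell_id == cell_id] <- NA_character_
  out
}

#' Export genealogy topology to Newick
#'
#' Lossy export: labels are cell ids, branch lengths are cell lifetimes;
#' onset annotations and end reasons are dropped.
#'
#' @param cells A genealogy tibble holding the tree `tree_id`.
#' @param tree_id Which tree to export (default: the only one present).
#' @return A Newick string (with trailing semicolon).
#' @export
genealogy_newick <- function(cells, tree_id = NULL) {
  if (is.null(tree_id)) {
    ids <- unique(cells$tree_id)
    if (length(ids) != 1) stop("give tree_id", call. = FALSE)
    tree_id <- ids
  }
  df <- filter(cells, .data$tree_id == !!tree_id)
  rec <- function(id) {
    kids <- df$cell_id[!is.na(df$parent_id) & df$parent_id == id]
    row <- df[df$cell_id == id, ]
    len <- row$end_time - row$birth_time
    if (length(kids) == 0) return(sprintf("%s:%g", id, len))
    sprintf("(%s,%s)%s:%g", rec(kids[1]), rec(kids[2]), id, len)
  }
  root <- df$cell_id[is.na(df$parent_id)]
  paste0(rec(root), ";")
}

#' Read or write per-cell fluorescence signal tracks
#'
#' Signal tracks are tab-separated tables `tree_id cell_id time_h intensity
#' area` with strictly increasing times per cell; `area` allows converting
#' intensity to concentration (intensity per area).
#'
#' @param path File path.
#' @return A tibble with the five track columns.
#' @export
read_signal_tracks <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  col_types = readr::cols(
                    tree_id = readr::col_character(),
                    cell_id = readr::col_character(),
                    time_h = readr::col_double(),
                    intensity = readr::col_double(),
                    area = readr::col_double()))
}

#' @rdname read_signal_tracks
#' @param tracks A signal-track tibble.
#' @export
write_signal_tracks <- function(tracks, path) {
  readr::write_tsv(tracks[c("tree_id", "cell_id", "time_h",
                            "intensity", "area")], path, na = "NA")
  invisible(path)
}
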