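test_that("cell-table round trip is the identity on valid genealogies", {
  set.seed(11)
  trees <- dplyr::bind_rows(lapply(1:20, function(i)
    random_genealogy(id = sprintf("t%02d", i),
                     max_cells = sample(3:15, 1))))
  trees <- validate_genealogies(trees)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genealogies(trees, path)
  back <- read_genealogies(path)
  expect_equal(as.data.frame(back), as.data.frame(trees))
  # NA onset serialised as literal NA
  raw <- readLines(path)
  expect_true(any(grepl("\tNA\t", raw)))
  # header-only file for an empty table
  write_genealogies(trees[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("single-cell file parses with generation 0 and derived fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "tree_id\tcell_id\tparent_id\tbirth_time_h\tend_time_h\tend_reason\tonset_time_h\tfate_label",
    "t1\tc1\tNA\t0\t42.5\tmovie_end\tNA\tnone"), path)
  g <- read_genealogies(path)
  expect_equal(nrow(g), 1)
  expect_equal(g$generation, 0L)
  expect_true(is.na(g$onset_time))
})

test_that("structural invariants are enforced with informative errors", {
  base <- perfect_genealogy(1)
  bad <- base
  bad$end_time[2] <- bad$birth_time[2]          # zero lifetime
  expect_error(validate_genealogies(bad), "end_time")
  bad <- base
  bad$onset_time[2] <- 100                      # onset outside lifetime
  expect_error(validate_genealogies(bad), "onset_time")
  bad <- base
  bad$end_reason[2] <- "apoptosis"
  expect_error(validate_genealogies(bad), "end_reason")
  bad <- base
  bad$parent_id[1] <- "2"                       # cycle, no root
  expect_error(validate_genealogies(bad), "root")
  # dividing cell with a single child
  bad <- perfect_genealogy(1)[-2, ]
  expect_error(validate_genealogies(bad), "2 children")
  # onset below an onset is rejected loudly
  bad <- perfect_genealogy(2, onset_leaves = TRUE)
  bad$onset_time[bad$cell_id == "2"] <- 7
  expect_error(validate_genealogies(bad), "below an onset")
  # mother-end / daughter-birth mismatch
  bad <- perfect_genealogy(1)
  bad$birth_time[bad$cell_id == "2"] <- 4
  expect_error(validate_genealogies(bad), "mother")
})

test_that("generations derive from the root and subtree extraction counts add up", {
  set.seed(21)
  g <- validate_genealogies(random_genealogy(max_cells = 15))
  pidx <- match(g$parent_id, g$cell_id)
  expect_equal(g$generation[!is.na(pidx)], g$generation[pidx[!is.na(pidx)]] + 1L)
  # number of dividing cells = (cells - 1) / 2 in a binary tree
  expect_equal(sum(g$end_reason == "division"), (nrow(g) - 1) / 2)
  root <- g$cell_id[is.na(g$parent_id)]
  expect_equal(nrow(subtree(g, root)), nrow(g))
  div <- g$cell_id[g$end_reason == "division"][1]
  if (!is.na(div)) {
    kids <- g$cell_id[!is.na(g$parent_id) & g$parent_id == div]
    n_par <- nrow(subtree(g, div))
    expect_equal(nrow(subtree(g, kids[1])) + nrow(subtree(g, kids[2])) + 1,
                 n_par)
  }
  leaf <- g$cell_id[g$end_reason != "division"][1]
  expect_equal(nrow(subtree(g, leaf)), 1)
  expect_error(subtree(g, "no-such-cell"), "unknown cell_id")
})

test_that("newick export preserves topology and lifetimes", {
  g <- perfect_genealogy(2, life = 5)
  nwk <- genealogy_newick(g)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), 4)
  expect_true(all(abs(ph$edge.length - 5) < 1e-9))
})

test_that("signal tracks round trip through their table format", {
  tr <- tibble::tibble(tree_id = "t1", cell_id = c("1", "1", "2"),
                       time_h = c(0, 1.5, 3), intensity = c(10, 11, 12.5),
                       area = c(100, 101, 99))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal_tracks(tr, path)
  expect_equal(as.data.frame(read_signal_tracks(path)), as.data.frame(tr))
})
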