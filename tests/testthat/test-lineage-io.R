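test_that("a single nucleus parses to one censored track", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_lineage(chain_lineage(1), path)
  lin <- read_lineage(path, embryo_id = "one", group = "wild_type",
                      frame_interval_min = 60)
  expect_equal(nrow(lin$nodes), 1)
  expect_equal(nrow(lin$tracks), 1)
  expect_equal(lin$tracks$fate, "censored")
})

test_that("a division row pattern yields three tracks and fate=divides", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_lineage(bifurcation_lineage(), path)
  lin <- read_lineage(path, embryo_id = "div", frame_interval_min = 60)
  expect_equal(nrow(lin$tracks), 3)
  root <- lin$tracks[is.na(lin$tracks$mother_track_id), ]
  expect_equal(root$fate, "divides")
  expect_setequal(lin$tracks$fate, c("divides", "censored"))
})

test_that("write/read round-trips the node table field for field", {
  lin <- toy_lineage(toy_nodes(
    node_id = c(10L, 11L, 12L, 13L),
    predecessor_id = c(NA, 10L, 11L, 11L),
    timestep = 0:3 - c(0L, 0L, 0L, 1L),  # 0,1,2,2
    x = c(0.1, -2.5, 3.25, 1e-3), y = c(1, 2, 3, 4) / 3, z = c(0, 0, 1.5, -8),
    validated = c(TRUE, TRUE, FALSE, TRUE),
    identity = c(NA, "inner", NA, "outer"),
    death = c(FALSE, FALSE, FALSE, TRUE)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lineage(lin, path)
  back <- read_lineage(path, embryo_id = "rt", frame_interval_min = 60)
  expect_equal(as.data.frame(back$nodes[, lineage_columns]),
               as.data.frame(lin$nodes[, lineage_columns]))
})

test_that("empty lineage writes a header-only file and reads back empty", {
  lin <- toy_lineage(toy_nodes(integer(), integer(), integer()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lineage(lin, path)
  expect_equal(length(readLines(path)), 1)
  back <- read_lineage(path, embryo_id = "empty")
  expect_equal(nrow(back$nodes), 0)
})

test_that("unset identities are written as empty fields, not sentinels", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_lineage(chain_lineage(2), path)
  lines <- readLines(path)
  # identity is the 9th field; it must be empty on every data row
  fields <- strsplit(lines[-1], ",")
  expect_true(all(vapply(fields, function(f) f[9] == "", logical(1))))
})

test_that("format errors abort the read with informative conditions", {
  path <- withr::local_tempfile(fileext = ".csv")

  # predecessor at the same timestep
  bad <- toy_nodes(node_id = 1:2, predecessor_id = c(NA, 1L),
                   timestep = c(0L, 0L))
  readr::write_csv(bad, path, na = "")
  expect_error(read_lineage(path, embryo_id = "x"),
               "same or a later timestep")

  # duplicate node id
  dup <- toy_nodes(node_id = c(1L, 1L), predecessor_id = c(NA, NA),
                   timestep = c(0L, 1L))
  readr::write_csv(dup, path, na = "")
  expect_error(read_lineage(path, embryo_id = "x"), "duplicate node_id")

  # missing required column (readr also warns about the unmatched parser)
  readr::write_csv(toy_nodes(1L, NA, 0L)[, -5], path, na = "")
  suppressWarnings(
    expect_error(read_lineage(path, embryo_id = "x"),
                 "missing required column"))

  # out-of-vocabulary identity value
  oov <- toy_nodes(1L, NA, 0L, identity = "middle")
  readr::write_csv(oov, path, na = "")
  expect_error(read_lineage(path, embryo_id = "x"), "identity")
})

test_that("build_tracks partitions chains at divisions and roots", {
  expect_equal(nrow(build_tracks(chain_lineage(5)$nodes)), 1)
  expect_equal(build_tracks(chain_lineage(5)$nodes)$n_nodes, 5)
  expect_equal(nrow(build_tracks(bifurcation_lineage()$nodes)), 3)
  tr <- build_tracks(binary_tree_lineage()$nodes)
  expect_equal(nrow(tr), 7)
  expect_equal(sum(tr$fate == "divides"), 3)
  expect_equal(sum(tr$fate == "censored"), 4)
})

test_that("track partition identities hold on random synthetic lineages", {
  for (s in 1:5) {
    emb <- simulate_embryo(quick_params(), seed = 400 + s)
    tr <- emb$lineage$tracks
    nodes <- emb$lineage$nodes
    # every node in exactly one track
    expect_equal(sum(tr$n_nodes), nrow(nodes))
    n_roots <- sum(is.na(tr$mother_track_id))
    n_div <- sum(tr$fate == "divides")
    expect_equal(nrow(tr), n_roots + 2 * n_div)
  }
})

test_that("three successors of one node is rejected", {
  nodes <- toy_nodes(node_id = 1:4, predecessor_id = c(NA, 1L, 1L, 1L),
                     timestep = c(0L, 1L, 1L, 1L))
  expect_error(build_tracks(nodes), "3 or more successors")
  # but a lineage object can still be constructed and reports the problem
  lin <- toy_lineage(nodes)
  rep <- validate_lineage(lin)
  expect_false(attr(rep, "pass"))
})

test_that("validate_lineage flags the documented defect classes", {
  expect_true(attr(validate_lineage(binary_tree_lineage()), "pass"))

  # death-flagged node with a successor
  dead <- toy_lineage(toy_nodes(node_id = 1:2, predecessor_id = c(NA, 1L),
                                timestep = 0:1, death = c(TRUE, FALSE)))
  rep <- validate_lineage(dead)
  expect_false(attr(rep, "pass"))
  expect_true("death_not_terminal" %in% rep$code)

  # skipped timestep inside a track
  gap <- toy_lineage(toy_nodes(node_id = 1:2, predecessor_id = c(NA, 1L),
                               timestep = c(0L, 2L), time_hp = c(0, 2)))
  rep <- validate_lineage(gap)
  expect_false(attr(rep, "pass"))
  expect_true("gap_in_track" %in% rep$code)

  # time_hp off the frame grid
  skew <- toy_lineage(toy_nodes(node_id = 1:3,
                                predecessor_id = c(NA, 1L, 2L),
                                timestep = 0:2, time_hp = c(0, 1, 2.4)))
  rep <- validate_lineage(skew)
  expect_false(attr(rep, "pass"))
  expect_true("time_spacing" %in% rep$code)
})
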