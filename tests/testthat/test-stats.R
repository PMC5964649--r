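test_that("proportion of inner cells is the direct ratio", {
  counts <- tibble::tibble(n_inner = c(0, 9, 5), n_outer = c(7, 23, 5),
                           n_total = c(7, 32, 10))
  pic <- proportion_inner(counts)$pic
  expect_equal(pic, c(0, 0.28125, 0.5))
  # PIC + proportion outer = 1
  expect_equal(pic + counts$n_outer / counts$n_total, rep(1, 3))
  # zero totals flagged, not zero-filled
  z <- tibble::tibble(n_inner = 0, n_outer = 0, n_total = 0)
  expect_warning(out <- proportion_inner(z), "flagged")
  expect_true(is.na(out$pic))
})

test_that("binned asymmetric-division proportions count per mother type", {
  div <- tibble::tibble(
    time_na = c(0.81, 0.82, 0.83, 0.84, 0.87, 0.91, 0.92),
    mother_identity = c(rep("outer", 5), "inner", "outer"),
    division_type = c("asymmetric", "symmetric", "symmetric", "symmetric",
                      "asymmetric", "asymmetric", "asymmetric"))
  oad <- asymmetric_division_proportion(div, "outer", 0.05,
                                        window = c(0.8, 0.95))
  expect_equal(oad$n_divisions, c(4L, 1L, 1L))
  expect_equal(oad$proportion[1], 0.25)   # 1 asymmetric of 4
  expect_equal(oad$proportion[2:3], c(1, 1))
  iad <- asymmetric_division_proportion(div, "inner", 0.05,
                                        window = c(0.8, 0.95))
  expect_true(iad$empty[1] && iad$empty[2])
  expect_true(is.na(iad$proportion[1]))
  expect_equal(iad$proportion[3], 1)
})

test_that("a division exactly on a bin edge joins the right-hand bin", {
  div <- tibble::tibble(time_na = 0.85, mother_identity = "outer",
                        division_type = "symmetric")
  oad <- asymmetric_division_proportion(div, "outer", 0.05,
                                        window = c(0.8, 0.9))
  expect_equal(oad$n_divisions, c(0L, 1L))
})

test_that("normalized death ratio matches hand arithmetic", {
  # 5 inner + 15 outer tracks, deaths 2 inner + 1 outer
  tracks <- tibble::tibble(
    track_id = 1:20,
    identity = rep(c("inner", "outer"), c(5, 15)),
    birth_time_hp = 0.5, last_time_hp = 1.5)
  deaths <- tibble::tibble(track_id = c(1, 2, 6),
                           identity = c("inner", "inner", "outer"),
                           time_hp = c(1, 1.2, 0.9))
  ann <- forge_annotated(tracks, deaths = deaths)
  r <- normalized_death_ratio(ann, forge_timescale(1), window = c(0, 2))
  expect_equal(r$ratio[r$identity == "inner"], (2 / 3) / (5 / 20))
  expect_equal(r$ratio[r$identity == "outer"], (1 / 3) / (15 / 20))
  # type-weighted identity: sum_T (N_T/N) r_T = 1
  expect_equal(sum(r$n_tracks / r$total_tracks * r$ratio), 1)
})

test_that("death ratio is exactly 1 under proportional allocation", {
  tracks <- tibble::tibble(
    track_id = 1:40,
    identity = rep(c("inner", "outer"), c(10, 30)),
    birth_time_hp = 0.5, last_time_hp = 1.5)
  deaths <- tibble::tibble(track_id = c(1, 11, 12, 13),
                           identity = c("inner", rep("outer", 3)),
                           time_hp = 1)
  ann <- forge_annotated(tracks, deaths = deaths)
  r <- normalized_death_ratio(ann, forge_timescale(1), window = c(0, 2))
  expect_equal(r$ratio, c(1, 1))
})

test_that("embryos without deaths in the window are flagged", {
  tracks <- tibble::tibble(track_id = 1:6,
                           identity = rep(c("inner", "outer"), 3),
                           birth_time_hp = 0.5, last_time_hp = 1.5)
  ann <- forge_annotated(tracks)
  expect_warning(r <- normalized_death_ratio(ann, forge_timescale(1),
                                             window = c(0, 2)),
                 "no deaths")
  expect_true(all(is.na(r$ratio)))
})

test_that("death exposure only counts tracks overlapping the window", {
  tracks <- tibble::tibble(
    track_id = 1:4, identity = c("inner", "inner", "outer", "outer"),
    birth_time_hp = c(0, 5, 0, 5), last_time_hp = c(1, 6, 1, 6))
  deaths <- tibble::tibble(track_id = 1, identity = "inner", time_hp = 0.8)
  ann <- forge_annotated(tracks, deaths = deaths)
  r <- normalized_death_ratio(ann, forge_timescale(1), window = c(0, 2))
  expect_equal(r$n_tracks, c(1L, 1L))  # late tracks not exposed
  expect_equal(r$ratio[r$identity == "inner"], (1 / 1) / (1 / 2))
})

test_that("coefficient of variation is sample sd over mean", {
  counts <- tibble::tibble(
    embryo_id = rep(c("a", "b"), each = 2),
    time_na = rep(c(0.8, 0.9), 2),
    n_inner = c(2, 3, 4, 3), n_outer = c(10, 10, 10, 10))
  cv <- coefficient_of_variation(counts)
  expect_equal(cv$cv[cv$type == "inner" & cv$time_na == 0.8],
               sd(c(2, 4)) / 3)
  expect_equal(sd(c(2, 4)) / 3, sqrt(2) / 3)
  expect_equal(sqrt(2) / 3, 0.4714045, tolerance = 1e-6)
  expect_equal(cv$cv[cv$type == "outer"], c(0, 0))
  expect_error(coefficient_of_variation(counts[counts$embryo_id == "a", ]),
               "at least 2")
  # zero mean flagged undefined
  zc <- tibble::tibble(embryo_id = c("a", "b"), time_na = 1,
                       n_inner = c(0, 0), n_outer = c(1, 1))
  expect_true(is.na(coefficient_of_variation(zc)$cv[1]))
})

test_that("neighbourhood composition matches brute-force k-NN", {
  # frame at t=1: mother at origin, 4 same-frame neighbours, k=4, exactly
  # one of the other type among them
  nodes <- dplyr::bind_rows(
    toy_nodes(node_id = 1L, predecessor_id = NA_integer_, timestep = 0L),
    toy_nodes(node_id = 2:3, predecessor_id = 1L, timestep = 1L,
              x = c(0.5, -0.5), identity = c("outer", "outer")),
    toy_nodes(node_id = 4:7, predecessor_id = NA_integer_, timestep = 0L,
              x = c(1, 2, 3, 4.2), y = c(0.1, -0.2, 0.15, 0),
              identity = c("inner", "outer", "outer", "outer")),
    toy_nodes(node_id = 8:11, predecessor_id = 4:7, timestep = 1L,
              x = c(1, 2, 3, 4.2), y = c(0.1, -0.2, 0.15, 0),
              identity = c("inner", "outer", "outer", "outer")))
  lin <- toy_lineage(nodes)
  ann <- annotate_lineage(lin)
  # mother is node 1 (track dividing at t=0); neighbours at t=0 are nodes 4:7
  nb <- neighborhood_composition(ann, k = 4)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$frac_other, 0.25)
  expect_false(nb$short)
  # with k larger than available cells: all used, flagged
  expect_warning(nb8 <- neighborhood_composition(ann, k = 8), "fewer than k")
  expect_equal(nb8$k_used, 4)
  expect_true(nb8$short)
})

test_that("founder clones count mitoses and final composition", {
  # founder that never divides
  solo <- annotate_lineage(chain_lineage(3, identity = "outer"))
  fs <- founder_clone_summary(solo)
  expect_equal(fs$n_mitoses, 0)
  expect_equal(fs$n_final_outer, 1)

  # founder whose both daughters divide once each: 3 mitoses, 4 final cells
  lin <- binary_tree_lineage(rep("outer", 4))
  fs2 <- founder_clone_summary(annotate_lineage(lin))
  expect_equal(fs2$n_mitoses, 3)
  expect_equal(fs2$n_final_outer, 4)

  # N_mit = final + deaths - 1 on simulated embryos
  emb <- simulate_embryo(quick_params(), seed = 91)
  fs3 <- founder_clone_summary(annotate_lineage(emb$lineage))
  expect_true(all(fs3$n_mitoses ==
                    fs3$n_final_inner + fs3$n_final_outer + fs3$n_deaths - 1))
  expect_equal(nrow(fs3), 17)  # 12 + 5 initial cells
})

test_that("relative developmental speed matches the printed collapse times", {
  expect_equal(relative_developmental_speed(80, c(80, 80)), 0)
  wt <- c(80.7, 77.7, 86.8)
  expect_equal(relative_developmental_speed(92.3, wt), 12.928, tolerance = 1e-3)
  expect_equal(relative_developmental_speed(96.0, wt), 17.455, tolerance = 1e-3)
  expect_error(relative_developmental_speed(90, numeric(0)), "empty")
})
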