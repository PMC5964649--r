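# Toy lineage builders used across test files. Times default to the 60-min
# frame so time_hp == timestep.

toy_nodes <- function(node_id, predecessor_id, timestep,
                      time_hp = NULL, x = 0, y = 0, z = 0,
                      validated = TRUE, identity = NA_character_,
                      death = FALSE) {
  n <- length(node_id)
  tibble::tibble(
    node_id = as.integer(node_id),
    predecessor_id = as.integer(predecessor_id),
    timestep = as.integer(timestep),
    time_hp = if (is.null(time_hp)) as.numeric(timestep) else time_hp,
    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    validated = rep_len(validated, n),
    identity = rep_len(identity, n),
    death = rep_len(death, n)
  )
}

toy_lineage <- function(nodes, frame_interval_min = 60, embryo_id = "toy",
                        group = "wild_type") {
  blastotrace:::new_lineage(
    nodes, embryo_id = embryo_id, group = group,
    time_origin = "fertilization", fertilization_offset_h = 8,
    frame_interval_min = frame_interval_min)
}

# linear chain of n nodes (one cell followed over n timesteps)
chain_lineage <- function(n, identity = NA_character_, death_last = FALSE) {
  toy_lineage(toy_nodes(
    node_id = seq_len(n),
    predecessor_id = c(NA, seq_len(n - 1)),
    timestep = seq_len(n) - 1L,
    identity = identity,
    death = c(rep(FALSE, n - 1), death_last)))
}

# one division: A at t=0, daughters B and C at t=1
bifurcation_lineage <- function(identities = c(NA, NA, NA)) {
  toy_lineage(toy_nodes(
    node_id = 1:3, predecessor_id = c(NA, 1L, 1L), timestep = c(0L, 1L, 1L),
    identity = identities))
}

# full binary tree of depth 2: 1 root, 2 children, 4 grandchildren (7 tracks)
binary_tree_lineage <- function(leaf_identities = rep(NA_character_, 4)) {
  toy_lineage(toy_nodes(
    node_id = 1:7,
    predecessor_id = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
    timestep = c(0L, 1L, 1L, 2L, 2L, 2L, 2L),
    identity = c(NA, NA, NA, leaf_identities)))
}

# Forged annotated objects, for statistics that only touch tracks/records.
forge_annotated <- function(tracks, deaths = NULL, divisions = NULL,
                            nodes = NULL, embryo_id = "toy",
                            group = "wild_type") {
  empty_deaths <- tibble::tibble(track_id = integer(), timestep = integer(),
                                 time_hp = double(), identity = character())
  structure(
    list(nodes = nodes, tracks = tracks,
         divisions = divisions, deaths = deaths %||% empty_deaths,
         embryo_id = embryo_id, group = group,
         time_origin = "fertilization", fertilization_offset_h = 8,
         frame_interval_min = 60, structural_errors = character()),
    class = c("annotated_lineage", "embryo_lineage"))
}

forge_timescale <- function(t_collapse_hp = 1, lo = 0, hi = 2) {
  structure(list(embryo_id = "toy", group = "wild_type",
                 t_collapse_hp = t_collapse_hp, collapse_timestep = 0L,
                 window_lo_na = lo, window_hi_na = hi),
            class = "embryo_timescale")
}

`%||%` <- rlang::`%||%`

# fast, small simulation parameter set for property loops
quick_params <- function(...) {
  sim_params("wt_like",
             n_initial_outer = 12, n_initial_inner = 5,
             t_start_h = 62, t_end_h = 72, t_collapse_h = 68,
             cycle_mean_h = 6, p_asym_outer_peak = 0.4,
             p_asym_outer_peak_na = 62 / 68 + 0.04,
             p_asym_outer_width_na = 0.1,
             p_asym_inner = 0.3, h_outer = 0.01, h_inner = 0.02,
             ...)
}
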