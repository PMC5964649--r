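#' Parameters of the synthetic embryo generator
#'
#' Presets emulate the study conditions: embryos observed from about the
#' 32-cell stage to hatching at 15-min frames, a wave of outer-cell
#' asymmetric divisions between the 32- and 64-cell stages, and (clone
#' preset) a strong bias toward inner-cell death with fewer initial inner
#' cells and delayed, scarce inner-cell asymmetric divisions.
#'
#' Hazards are per cell-hour; the death-hazard bias is
#' `beta = h_inner / h_outer` (1 for the wild-type preset, 4 for clones).
#' The collapse is scripted: at `t_collapse_h` the embryo radius is scaled
#' by `(1 - collapse_volume_drop)^(1/3)`, i.e. the hull volume drops by
#' `collapse_volume_drop` (default 0.15, above the 0.10 detection
#' threshold). The outer asymmetric-division probability is a Gaussian bump
#' in normalized age; the inner one is constant, a late-onset step, or a
#' feedback controller that raises the export of inner daughters when the
#' proportion of inner cells exceeds `target_pic` (an asymmetric inner
#' division keeps the inner count constant while adding an outer cell, so
#' it can only lower the proportion of inner cells).
#'
#' @param preset `"wt_like"` or `"clone_like"`.
#' @param ... Named overrides of any listed field.
#' @return A `sim_params` list.
#' @export
sim_params <- function(preset = c("wt_like", "clone_like"), ...) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset,
    n_initial_outer = 23,
    n_initial_inner = if (preset == "wt_like") 9 else 3,
    t_start_h = if (preset == "wt_like") 62 else 72,
    t_end_h = if (preset == "wt_like") 90 else 101,
    t_collapse_h = if (preset == "wt_like") 81 else 94,
    t_collapse_sd_h = 2,
    frame_interval_min = 15,
    cycle_mean_h = 14,
    cycle_cv = 0.2,
    p_asym_outer_peak = 0.25,
    p_asym_outer_peak_na = 0.82,
    p_asym_outer_width_na = 0.08,
    inner_asym_mode = if (preset == "wt_like") "constant" else "late_step",
    p_asym_inner = 0.08,
    inner_onset_na = 0.95,
    target_pic = 0.25,
    p_inner_hi = 0.35,
    p_inner_lo = 0.02,
    h_outer = if (preset == "wt_like") 0.004 else 0.003,
    h_inner = if (preset == "wt_like") 0.004 else 0.012,
    radius0_um = 55,
    growth_um_h = 0.6,
    inner_radius_frac = 0.45,
    jitter_sd_um = 1.5,
    jitter_dyn_um = 0.4,
    collapse_volume_drop = 0.15
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_params field(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  stopifnot(
    p$p_asym_outer_peak >= 0, p$p_asym_outer_peak <= 1,
    p$p_asym_inner >= 0, p$p_asym_inner <= 1,
    p$h_outer >= 0, p$h_inner >= 0,
    p$collapse_volume_drop >= 0, p$collapse_volume_drop < 1,
    p$t_start_h < p$t_end_h, p$frame_interval_min > 0
  )
  structure(p, class = "sim_params")
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

perturb_direction <- function(dir, angle_sd = 0.25) {
  d <- dir + rnorm(3, sd = angle_sd)
  d / sqrt(sum(d^2))
}

#' Simulate one synthetic embryo lineage with ground truth
#'
#' Discrete-time branching simulation at frame resolution. Each cell draws
#' a log-normal cycle length and an exponential death waiting time (the
#' earlier event wins); at a division, asymmetry is Bernoulli with the
#' type- and time-appropriate probability and the off-type daughter is
#' relocated to the other compartment. Outer cells sit on a sphere of
#' radius `R(t)` (linear growth with a scripted multiplicative collapse at
#' `t_collapse_h`), inner cells at `inner_radius_frac * R(t)`, both with
#' Gaussian positional jitter. Reproducible given `(params, seed)`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer RNG seed.
#' @return A list with `$lineage` (an `embryo_lineage` whose `identity`
#'   and `death` columns carry the ground truth), `$truth` (per-track
#'   identity, division log with off-type daughters, deaths), `$params`
#'   and `$seed`. If every cell dies, the partial lineage is still emitted
#'   with attribute `extinct = TRUE` on `$truth`.
#' @export
simulate_embryo <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  frame_h <- params$frame_interval_min / 60
  times <- seq(params$t_start_h, params$t_end_h, by = frame_h)
  nF <- length(times)
  t_c <- params$t_collapse_h
  sdlog <- sqrt(log(1 + params$cycle_cv^2))
  meanlog <- log(params$cycle_mean_h) - sdlog^2 / 2

  cap <- 4096L
  type <- character(cap); mother <- integer(cap)
  birth <- integer(cap); end_f <- integer(cap)
  div_f <- numeric(cap); death_f <- numeric(cap)
  fate <- character(cap)
  dir <- matrix(0, cap, 3); rfrac <- numeric(cap)
  n_tracks <- 0L
  n_live <- c(inner = 0L, outer = 0L)

  grow <- function() {
    cap2 <- 2L * cap
    length(type) <<- cap2; length(mother) <<- cap2
    length(birth) <<- cap2; length(end_f) <<- cap2
    length(div_f) <<- cap2; length(death_f) <<- cap2
    length(fate) <<- cap2
    dir2 <- matrix(0, cap2, 3); dir2[seq_len(cap), ] <- dir; dir <<- dir2
    length(rfrac) <<- cap2
    cap <<- cap2
  }

  new_track <- function(ty, mom, bf, direction, rf, initial = FALSE) {
    if (n_tracks == cap) grow()
    i <- n_tracks + 1L
    n_tracks <<- i
    type[i] <<- ty; mother[i] <<- mom; birth[i] <<- bf
    cycle_f <- max(2L, as.integer(round(rlnorm(1, meanlog, sdlog) / frame_h)))
    age_f <- if (initial) sample.int(cycle_f, 1L) - 1L else 0L
    div_f[i] <<- bf + cycle_f - age_f
    h <- if (ty == "inner") params$h_inner else params$h_outer
    death_f[i] <<- if (h > 0)
      bf + max(1, ceiling(rexp(1, h) / frame_h)) else Inf
    end_f[i] <<- NA_integer_; fate[i] <<- NA_character_
    dir[i, ] <<- direction; rfrac[i] <<- rf
    n_live[ty] <<- n_live[ty] + 1L
    i
  }

  p_asym <- function(ty, na) {
    if (ty == "outer") {
      params$p_asym_outer_peak *
        exp(-(na - params$p_asym_outer_peak_na)^2 /
              (2 * params$p_asym_outer_width_na^2))
    } else {
      switch(params$inner_asym_mode,
        constant = params$p_asym_inner,
        late_step = if (na >= params$inner_onset_na) params$p_asym_inner else 0,
        feedback = {
          pic <- n_live["inner"] / max(1L, sum(n_live))
          if (pic > params$target_pic) params$p_inner_hi else params$p_inner_lo
        })
    }
  }

  u0 <- random_unit_vectors(params$n_initial_outer + params$n_initial_inner)
  for (j in seq_len(params$n_initial_outer)) {
    new_track("outer", 0L, 1L, u0[j, ], 1, initial = TRUE)
  }
  for (j in seq_len(params$n_initial_inner)) {
    new_track("inner", 0L, 1L, u0[params$n_initial_outer + j, ],
              params$inner_radius_frac, initial = TRUE)
  }

  truth_div <- list()
  for (f in seq_len(nF)) {
    na <- times[f] / t_c
    active <- which(seq_len(n_tracks) <= n_tracks & is.na(fate[seq_len(n_tracks)]))
    sched <- pmin(div_f[active], death_f[active])
    due <- active[sched == f]
    for (i in due) {
      if (death_f[i] <= div_f[i]) {
        fate[i] <- "dies"; end_f[i] <- f
        n_live[type[i]] <- n_live[type[i]] - 1L
      } else if (f < nF) {
        fate[i] <- "divides"; end_f[i] <- f
        ty <- type[i]
        n_live[ty] <- n_live[ty] - 1L
        asym <- runif(1) < p_asym(ty, na)
        d1 <- new_track(ty, i, f + 1L, perturb_direction(dir[i, ]), rfrac[i])
        if (asym) {
          if (ty == "outer") {
            d2 <- new_track("inner", i, f + 1L, random_unit_vectors(1)[1, ],
                            params$inner_radius_frac)
          } else {
            d2 <- new_track("outer", i, f + 1L, perturb_direction(dir[i, ]), 1)
          }
        } else {
          d2 <- new_track(ty, i, f + 1L, perturb_direction(dir[i, ]), rfrac[i])
        }
        truth_div[[length(truth_div) + 1L]] <- c(
          mother = i, daughter1 = d1, daughter2 = d2,
          offtype = if (asym) d2 else NA_integer_)
      }
      # divisions scheduled at the final frame are left to run out (censored)
    }
    if (sum(n_live) == 0L) break
  }
  open <- which(is.na(fate[seq_len(n_tracks)]))
  fate[open] <- "censored"
  end_f[open] <- nF

  idx <- seq_len(n_tracks)
  type <- type[idx]; mother <- mother[idx]; birth <- birth[idx]
  end_f <- as.integer(end_f[idx]); fate <- fate[idx]
  dir <- dir[idx, , drop = FALSE]; rfrac <- rfrac[idx]
  extinct <- max(end_f) < nF

  # ---- emit the node table (vectorized over all tracks) ----
  radius <- (params$radius0_um + params$growth_um_h * (times - params$t_start_h)) *
    ifelse(times >= t_c, (1 - params$collapse_volume_drop)^(1 / 3), 1)
  nf_per <- end_f - birth + 1L
  row_track <- rep.int(idx, nf_per)
  row_frame <- sequence(nf_per) + rep.int(birth, nf_per) - 1L
  ord <- order(row_frame, row_track)
  row_track <- row_track[ord]; row_frame <- row_frame[ord]
  n_nodes <- length(row_track)
  node_id <- seq_len(n_nodes)
  key <- row_track * (nF + 1L) + row_frame
  pred_key <- ifelse(row_frame > birth[row_track], key - 1L,
                     ifelse(mother[row_track] > 0L,
                            mother[row_track] * (nF + 1L) + row_frame - 1L,
                            NA_integer_))
  predecessor <- node_id[match(pred_key, key)]
  r_here <- radius[row_frame] * rfrac[row_track]
  # positional noise: a persistent per-track offset (cells keep their place in
  # the epithelium/ICM between frames) plus a small per-frame detection jitter
  offset <- matrix(rnorm(3 * n_tracks, sd = params$jitter_sd_um), ncol = 3)
  pos <- dir[row_track, , drop = FALSE] * r_here + offset[row_track, , drop = FALSE] +
    matrix(rnorm(3 * n_nodes, sd = params$jitter_dyn_um), ncol = 3)
  nodes <- tibble(
    node_id = node_id,
    predecessor_id = as.integer(predecessor),
    timestep = row_frame - 1L,
    time_hp = times[row_frame],
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    validated = TRUE,
    identity = type[row_track],
    death = fate[row_track] == "dies" & row_frame == end_f[row_track]
  )
  lineage <- new_lineage(
    nodes,
    embryo_id = paste0("sim_", params$preset, "_seed", seed),
    group = if (params$preset == "wt_like") "wild_type" else "clone",
    time_origin = if (params$preset == "wt_like") "fertilization" else "activation",
    fertilization_offset_h = 8,
    frame_interval_min = params$frame_interval_min
  )

  # re-key generator track ids to the lineage's track ids via first nodes
  first_node <- node_id[match(idx * (nF + 1L) + birth, key)]
  lt_id <- lineage$tracks$track_id[match(first_node, lineage$tracks$first_node_id)]
  remap <- function(g) lt_id[g]
  div <- if (length(truth_div) > 0) {
    m <- do.call(rbind, truth_div)
    tibble(
      mother_track_id = remap(m[, "mother"]),
      daughter1 = remap(m[, "daughter1"]),
      daughter2 = remap(m[, "daughter2"]),
      division_type = ifelse(is.na(m[, "offtype"]), "symmetric", "asymmetric"),
      offtype_daughter = remap(m[, "offtype"]),
      time_hp = times[end_f[m[, "mother"]]])
  } else {
    tibble(mother_track_id = integer(), daughter1 = integer(),
           daughter2 = integer(), division_type = character(),
           offtype_daughter = integer(), time_hp = double())
  }
  truth <- list(
    tracks = tibble(track_id = remap(idx), identity = type, fate = fate),
    divisions = div,
    deaths = tibble(track_id = remap(which(fate == "dies")),
                    identity = type[fate == "dies"],
                    time_hp = times[end_f[fate == "dies"]]),
    t_collapse_h = t_c
  )
  attr(truth, "extinct") <- extinct
  list(lineage = lineage, truth = truth, params = params, seed = seed)
}

#' Simulate a cohort of synthetic embryos
#'
#' Independent embryos with per-embryo seeds derived deterministically from
#' the master seed; per-embryo collapse times are jittered around the
#' preset anchor (`t_collapse_sd_h`) so cohort members develop at slightly
#' different paces, as the study's specimens did.
#'
#' @param preset `"wt_like"` or `"clone_like"` (ignored if `params` given).
#' @param n_embryos Number of embryos.
#' @param seed Master seed.
#' @param params Optional [sim_params()] shared by the cohort.
#' @return Named list of [simulate_embryo()] results.
#' @export
simulate_cohort <- function(preset = c("wt_like", "clone_like"), n_embryos,
                            seed, params = NULL) {
  params <- params %||% sim_params(match.arg(preset))
  set.seed(seed)
  tc <- params$t_collapse_h + rnorm(n_embryos, 0, params$t_collapse_sd_h)
  out <- vector("list", n_embryos)
  for (i in seq_len(n_embryos)) {
    p_i <- params
    p_i$t_collapse_h <- tc[i]
    seed_i <- as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
    emb <- simulate_embryo(p_i, seed_i)
    emb$lineage$embryo_id <- paste0(params$preset, "_", i)
    out[[i]] <- emb
  }
  names(out) <- paste0(params$preset, "_", seq_len(n_embryos))
  out
}
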