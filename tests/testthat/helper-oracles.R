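# Independent geometric and stochastic oracles. None of these share code
# with the package implementation they check.

# Brute-force O(n^3) enumeration of convex-hull supporting planes: a triple
# of points spans a hull plane iff every point lies on one side of it.
# Returns outward-oriented unit normals and offsets.
oracle_hull_planes <- function(pts) {
  n <- nrow(pts)
  planes <- list()
  tol <- 1e-9 * max(abs(pts), 1)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- pts[j, ] - pts[i, ]; v <- pts[k, ] - pts[i, ]
    nn <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    nrm <- sqrt(sum(nn^2))
    if (nrm < tol) next
    nn <- nn / nrm
    d <- pts %*% nn - sum(nn * pts[i, ])
    if (all(d <= tol)) {
      planes[[length(planes) + 1]] <- c(nn, sum(nn * pts[i, ]))
    } else if (all(d >= -tol)) {
      planes[[length(planes) + 1]] <- c(-nn, -sum(nn * pts[i, ]))
    }
  }
  m <- unique(do.call(rbind, planes))
  list(normals = m[, 1:3, drop = FALSE], offsets = m[, 4])
}

# min perpendicular distance of each point to the hull boundary planes
oracle_min_facet_distance <- function(pts) {
  pl <- oracle_hull_planes(pts)
  d <- sweep(-(pts %*% t(pl$normals)), 2, pl$offsets, "+")
  apply(d, 1, min)
}

# Monte-Carlo hull volume: sample the bounding box, count points inside
# every supporting half-space.
oracle_hull_volume_mc <- function(pts, n_samples = 2e5, seed = 1) {
  set.seed(seed)
  pl <- oracle_hull_planes(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  s <- cbind(runif(n_samples, lo[1], hi[1]),
             runif(n_samples, lo[2], hi[2]),
             runif(n_samples, lo[3], hi[3]))
  d <- sweep(s %*% t(pl$normals), 2, pl$offsets, "-")
  inside <- rowSums(d > 1e-12) == 0
  mean(inside) * prod(hi - lo)
}

# Recursive frame-binned branching process: expected number of cells alive
# at the final frame (no death, no types). Mirrors the generator's event
# arithmetic but is a wholly separate implementation.
oracle_branching_count <- function(n0, cycle_mean_h, cycle_cv, n_frames,
                                   frame_h, seed) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cycle_cv^2))
  meanlog <- log(cycle_mean_h) - sdlog^2 / 2
  draw_cycle <- function() {
    max(2L, as.integer(round(rlnorm(1, meanlog, sdlog) / frame_h)))
  }
  alive_from <- function(div_frame) {
    if (div_frame >= n_frames) return(1L)
    alive_from(div_frame + 1L + draw_cycle()) +
      alive_from(div_frame + 1L + draw_cycle())
  }
  total <- 0L
  for (j in seq_len(n0)) {
    cf <- draw_cycle()
    age <- sample.int(cf, 1L) - 1L
    total <- total + alive_from(1L + cf - age)
  }
  total
}

# Recursive typed branching process with death hazards and asymmetric
# divisions; returns the normalized inner-cell death ratio over an n.a.
# window, or NA when the replicate has no usable deaths.
oracle_death_ratio <- function(params, window_na, seed) {
  set.seed(seed)
  frame_h <- params$frame_interval_min / 60
  sdlog <- sqrt(log(1 + params$cycle_cv^2))
  meanlog <- log(params$cycle_mean_h) - sdlog^2 / 2
  n_frames <- length(seq(params$t_start_h, params$t_end_h, by = frame_h))
  t_c <- params$t_collapse_h
  time_of <- function(f) params$t_start_h + (f - 1) * frame_h
  p_asym <- function(ty, na) {
    if (ty == "outer") {
      params$p_asym_outer_peak *
        exp(-(na - params$p_asym_outer_peak_na)^2 /
              (2 * params$p_asym_outer_width_na^2))
    } else if (params$inner_asym_mode == "late_step") {
      if (na >= params$inner_onset_na) params$p_asym_inner else 0
    } else {
      params$p_asym_inner
    }
  }
  recs <- list()
  sim_cell <- function(ty, bf, initial = FALSE) {
    cf <- max(2L, as.integer(round(rlnorm(1, meanlog, sdlog) / frame_h)))
    if (initial) cf <- cf - (sample.int(cf, 1L) - 1L)
    h <- if (ty == "inner") params$h_inner else params$h_outer
    df <- if (h > 0) max(1, ceiling(rexp(1, h) / frame_h)) else Inf
    div_f <- bf + cf; death_f <- bf + df
    if (death_f <= div_f && death_f <= n_frames) {
      recs[[length(recs) + 1]] <<- c(ty == "inner", bf, death_f, 1)
    } else if (div_f < n_frames && div_f < death_f) {
      recs[[length(recs) + 1]] <<- c(ty == "inner", bf, div_f, 0)
      asym <- runif(1) < p_asym(ty, time_of(div_f) / t_c)
      sim_cell(ty, div_f + 1L)
      sim_cell(if (asym) (if (ty == "outer") "inner" else "outer") else ty,
               div_f + 1L)
    } else {
      recs[[length(recs) + 1]] <<- c(ty == "inner", bf, n_frames, 0)
    }
  }
  for (j in seq_len(params$n_initial_outer)) sim_cell("outer", 1L, initial = TRUE)
  for (j in seq_len(params$n_initial_inner)) sim_cell("inner", 1L, initial = TRUE)
  m <- do.call(rbind, recs)
  birth_na <- time_of(m[, 2]) / t_c
  last_na <- time_of(m[, 3]) / t_c
  alive <- birth_na <= window_na[2] & last_na >= window_na[1]
  died <- m[, 4] == 1 & last_na >= window_na[1] & last_na <= window_na[2]
  n_all <- sum(alive); n_in <- sum(alive & m[, 1] == 1)
  d_all <- sum(died); d_in <- sum(died & m[, 1] == 1)
  if (d_all == 0 || n_in == 0) return(NA_real_)
  (d_in / d_all) / (n_in / n_all)
}
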