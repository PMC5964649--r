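#' Inner and outer cell counts over time
#'
#' Step functions of validated-cell counts by identity, per timestep, with
#' optional evaluation on a normalized-age grid (piecewise-constant: the
#' count at grid time `t` is the count at the latest frame at or before
#' `t`).
#'
#' @param annotated An `annotated_lineage`.
#' @param timescale Optional `embryo_timescale`; adds a `time_na` column.
#' @param grid Optional numeric n.a. grid (requires `timescale`); must lie
#'   within the embryo's observed window.
#' @return A tibble with `timestep`/`time_hp` (`time_na` when rescaled),
#'   `n_inner`, `n_outer`, `n_total`.
#' @export
counts_by_type <- function(annotated, timescale = NULL, grid = NULL) {
  stopifnot(inherits(annotated, "annotated_lineage"))
  nodes <- validated_nodes(annotated)
  idmap <- setNames(annotated$tracks$identity, annotated$tracks$track_id)
  nodes$identity_track <- unname(idmap[as.character(nodes$track_id)])
  counts <- nodes |>
    group_by(.data$timestep) |>
    summarise(
      time_hp = .data$time_hp[1],
      n_inner = sum(.data$identity_track == "inner"),
      n_outer = sum(.data$identity_track == "outer"),
      .groups = "drop") |>
    mutate(n_total = .data$n_inner + .data$n_outer) |>
    arrange(.data$timestep)
  if (!is.null(timescale)) {
    counts$time_na <- normalized_age(counts$time_hp, timescale)
  }
  if (!is.null(grid)) {
    if (is.null(timescale)) abort("grid evaluation requires a timescale")
    if (min(grid) < min(counts$time_na) - 1e-12 ||
        max(grid) > max(counts$time_na) + 1e-12) {
      abort("grid outside the embryo's observed window")
    }
    step <- function(v) approx(counts$time_na, v, xout = grid,
                               method = "constant", f = 0,
                               ties = "ordered")$y
    counts <- tibble(
      time_na = grid,
      n_inner = step(counts$n_inner),
      n_outer = step(counts$n_outer),
      n_total = step(counts$n_total))
  }
  class(counts) <- c("bt_counts", class(counts))
  counts
}

#' Proportion of inner cells (PIC)
#'
#' Adds `pic = n_inner / n_total` to a count series; timesteps with no
#' validated cells are flagged with `NA` rather than zero-filled.
#'
#' @param counts Output of [counts_by_type()].
#' @return The input with a `pic` column.
#' @export
proportion_inner <- function(counts) {
  stopifnot(all(c("n_inner", "n_total") %in% names(counts)))
  pic <- ifelse(counts$n_total > 0, counts$n_inner / counts$n_total, NA_real_)
  if (anyNA(pic)) warn("timesteps with zero validated cells: PIC flagged NA")
  counts$pic <- pic
  counts
}

#' Binned proportion of asymmetric divisions (OAD / IAD)
#'
#' Per normalized-age bin, the proportion of asymmetric divisions among
#' divisions whose mother has the requested identity: OAD for outer
#' mothers, IAD for inner mothers. Bins are half-open `[lo, hi)`, aligned
#' at `window[1]`; bins without divisions of that mother type are flagged
#' empty, not zero-filled.
#'
#' @param divisions Division records carrying a `time_na` column (see
#'   [divisions_with_na()]); pool several embryos by row-binding theirs.
#' @param mother_type `"outer"` or `"inner"`.
#' @param bin_width Bin size in n.a. (default 0.05).
#' @param window Length-2 numeric, the n.a. window to bin over.
#' @return A tibble with bin edges and midpoint, `n_divisions`,
#'   `n_asymmetric`, `proportion` (`NA` when `empty`).
#' @export
asymmetric_division_proportion <- function(divisions,
                                           mother_type = c("outer", "inner"),
                                           bin_width = 0.05,
                                           window) {
  mother_type <- match.arg(mother_type)
  stopifnot("time_na" %in% names(divisions), length(window) == 2,
            window[1] < window[2])
  n_bins <- ceiling((window[2] - window[1]) / bin_width - 1e-9)
  lo <- window[1] + (seq_len(n_bins) - 1) * bin_width
  div <- filter(divisions, .data$mother_identity == mother_type)
  # half-open bins [lo, hi): a division exactly on an edge joins the right bin
  idx <- floor((div$time_na - window[1]) / bin_width + 1e-9) + 1L
  keep <- idx >= 1L & idx <= n_bins
  idx <- idx[keep]
  div <- div[keep, ]
  n_div <- tabulate(idx, nbins = n_bins)
  n_asym <- tabulate(idx[div$division_type == "asymmetric"], nbins = n_bins)
  out <- tibble(
    bin_lo = lo, bin_hi = lo + bin_width, bin_mid = lo + bin_width / 2,
    mother_type = mother_type,
    n_divisions = n_div, n_asymmetric = n_asym,
    empty = n_div == 0,
    proportion = ifelse(n_div > 0, n_asym / n_div, NA_real_))
  class(out) <- c("bt_binned", class(out))
  out
}

#' Attach normalized-age times to division or death records
#'
#' @param records A tibble with a `time_hp` column (divisions or deaths).
#' @param timescale An `embryo_timescale`.
#' @return The records with a `time_na` column.
#' @export
divisions_with_na <- function(records, timescale) {
  mutate(records, time_na = normalized_age(.data$time_hp, timescale))
}

#' Normalized death ratio
#'
#' For identity `T` within an n.a. window, `r_T = (D_T / D) / (N_T / N)`
#' where `D_T` counts deaths of identity `T` in the window, `D` all deaths,
#' `N_T` distinct validated tracks of identity `T` alive at any point in the
#' window and `N` all such tracks. `r_T = 1` when death is independent of
#' cell type; values above 1 indicate preferential death of that type.
#'
#' @param annotated An `annotated_lineage`.
#' @param timescale The embryo's `embryo_timescale`.
#' @param window Length-2 n.a. window.
#' @return Tibble with one row per identity: `n_tracks`, `n_deaths`,
#'   `ratio` (all `NA` ratios if the embryo has no deaths in the window,
#'   with a warning).
#' @export
normalized_death_ratio <- function(annotated, timescale, window) {
  stopifnot(inherits(annotated, "annotated_lineage"), length(window) == 2)
  tracks <- annotated$tracks
  birth_na <- normalized_age(tracks$birth_time_hp, timescale)
  last_na <- normalized_age(tracks$last_time_hp, timescale)
  alive <- birth_na <= window[2] & last_na >= window[1]
  deaths <- divisions_with_na(annotated$deaths, timescale) |>
    filter(.data$time_na >= window[1], .data$time_na <= window[2])
  n_tot <- sum(alive)
  d_tot <- nrow(deaths)
  out <- tibble(identity = c("inner", "outer")) |>
    rowwise() |>
    mutate(
      n_tracks = sum(alive & tracks$identity == .data$identity),
      n_deaths = sum(deaths$identity == .data$identity)) |>
    ungroup() |>
    mutate(
      total_tracks = n_tot, total_deaths = d_tot,
      ratio = ifelse(d_tot > 0 & .data$n_tracks > 0,
                     (.data$n_deaths / d_tot) / (.data$n_tracks / n_tot),
                     NA_real_))
  if (d_tot == 0) {
    warn(paste0("embryo ", annotated$embryo_id,
                " has no deaths in the window: ratios flagged NA"))
  }
  out
}

#' Mean, standard deviation and standard error across embryos
#'
#' Both the sample standard deviation and the standard error are reported;
#' dispersion is flagged `NA` for a single embryo.
#'
#' @param values Numeric vector of per-embryo values (NAs dropped).
#' @return One-row tibble: `n`, `mean`, `sd`, `se`.
#' @export
group_stat <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  s <- if (n >= 2) sd(values) else NA_real_
  tibble(n = n, mean = if (n > 0) mean(values) else NA_real_,
         sd = s, se = s / sqrt(n))
}

#' Coefficient of variation of cell counts across embryos
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, per
#' grid point and cell type, across embryos resampled to a common grid.
#'
#' @param counts Long tibble with columns `embryo_id`, `time_na` and the
#'   count columns in `value_cols` (one row per embryo per grid point).
#' @param value_cols Count columns to evaluate (default inner and outer).
#' @return Long tibble: `time_na`, `type`, `n_embryos`, `mean`, `sd`, `cv`
#'   (`cv` is `NA` where the mean is zero).
#' @export
coefficient_of_variation <- function(counts,
                                     value_cols = c("n_inner", "n_outer")) {
  stopifnot(all(c("embryo_id", "time_na") %in% names(counts)))
  if (length(unique(counts$embryo_id)) < 2) {
    abort_stage("stats", "coefficient of variation needs at least 2 embryos")
  }
  out <- counts |>
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "type",
                        values_to = "count") |>
    mutate(type = sub("^n_", "", .data$type)) |>
    group_by(.data$time_na, .data$type) |>
    summarise(n_embryos = dplyr::n(), mean = mean(.data$count),
              sd = sd(.data$count), .groups = "drop") |>
    mutate(cv = ifelse(.data$mean > 0, .data$sd / .data$mean, NA_real_))
  class(out) <- c("bt_cv", class(out))
  out
}

#' Neighbourhood composition around dividing cells
#'
#' For each division, the fraction of the mother's `k` nearest neighbours
#' (Euclidean distance among validated nuclei of the mother's last frame)
#' whose identity differs from the mother's. When fewer than `k` other
#' cells exist, all available are used and the row is flagged.
#'
#' @param annotated An `annotated_lineage`.
#' @param k Number of nearest neighbours (default 8).
#' @return Per-division tibble: `mother_track_id`, `division_type`,
#'   `mother_identity`, `timestep`, `k_used`, `frac_other`, `short`.
#' @export
neighborhood_composition <- function(annotated, k = 8) {
  stopifnot(inherits(annotated, "annotated_lineage"))
  divisions <- annotated$divisions
  nodes <- validated_nodes(annotated)
  idmap <- setNames(annotated$tracks$identity, annotated$tracks$track_id)
  moms <- match(
    vapply(match(divisions$mother_track_id, annotated$tracks$track_id),
           function(i) annotated$tracks$last_node_id[i], integer(1)),
    nodes$node_id)
  res <- vector("list", nrow(divisions))
  for (j in seq_len(nrow(divisions))) {
    ts <- divisions$timestep[j]
    frame <- nodes[nodes$timestep == ts, ]
    mother_node <- annotated$tracks$last_node_id[
      match(divisions$mother_track_id[j], annotated$tracks$track_id)]
    mi <- match(mother_node, frame$node_id)
    if (is.na(mi)) {
      abort_stage("stats", paste0("mother node ", mother_node,
                                  " not validated at timestep ", ts))
    }
    others <- frame[-mi, ]
    d <- sqrt((others$x - frame$x[mi])^2 + (others$y - frame$y[mi])^2 +
                (others$z - frame$z[mi])^2)
    k_used <- min(k, nrow(others))
    nn <- others[order(d)[seq_len(k_used)], ]
    nn_id <- unname(idmap[as.character(nn$track_id)])
    res[[j]] <- tibble(
      mother_track_id = divisions$mother_track_id[j],
      division_type = divisions$division_type[j],
      mother_identity = divisions$mother_identity[j],
      timestep = ts,
      k_used = k_used,
      frac_other = if (k_used > 0)
        mean(nn_id != divisions$mother_identity[j]) else NA_real_,
      short = k_used < k)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0 && any(out$short)) {
    warn("some divisions had fewer than k other cells; all available used")
  }
  out
}

#' Founder-clone summaries
#'
#' Each validated cell present at the first validated timestep (a founder)
#' heads a clone: its entire subtree of descendants. Summarises, per
#' founder, the number of mitoses in the clone and the clone's final
#' composition (censored leaves by identity, plus deaths). For a binary
#' tree, `n_mitoses = final cells + deaths - 1`.
#'
#' @param annotated An `annotated_lineage`.
#' @return One row per founder: `founder_track_id`, `founder_identity`,
#'   `n_mitoses`, `n_final_inner`, `n_final_outer`, `n_deaths`.
#' @export
founder_clone_summary <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_lineage"))
  tracks <- annotated$tracks
  first_ts <- min(tracks$birth_timestep)
  # propagate each track's founder ancestor down the tree, in birth order
  founder <- rep(NA_integer_, nrow(tracks))
  ord <- order(tracks$birth_timestep)
  for (i in ord) {
    if (tracks$birth_timestep[i] == first_ts || is.na(tracks$mother_track_id[i])) {
      founder[i] <- tracks$track_id[i]
    } else {
      founder[i] <- founder[match(tracks$mother_track_id[i], tracks$track_id)]
    }
  }
  tracks |>
    mutate(founder = founder) |>
    group_by(.data$founder) |>
    summarise(
      founder_identity = .data$identity[.data$track_id == .data$founder[1]],
      n_mitoses = sum(.data$fate == "divides"),
      n_final_inner = sum(.data$fate == "censored" & .data$identity == "inner"),
      n_final_outer = sum(.data$fate == "censored" & .data$identity == "outer"),
      n_deaths = sum(.data$fate == "dies"),
      .groups = "drop") |>
    rename(founder_track_id = "founder") |>
    arrange(.data$founder_track_id)
}

#' Relative developmental speed of clones
#'
#' Slowdown of a clone relative to the wild-type group, measured on the
#' collapse anchors of the timescales:
#' `100 * (t_collapse(clone) / mean(t_collapse(wild types)) - 1)` percent.
#'
#' @param clone Collapse time(s) in hours, or `embryo_timescale` object(s).
#' @param wild_types Collapse times (hours) or `embryo_timescale`s of the
#'   wild-type reference group.
#' @return Numeric vector of percent slowdown, one value per clone.
#' @export
relative_developmental_speed <- function(clone, wild_types) {
  t_of <- function(x) {
    if (inherits(x, "embryo_timescale")) return(x$t_collapse_hp)
    if (is.list(x)) return(vapply(x, t_of, numeric(1)))
    as.numeric(x)
  }
  wt <- t_of(wild_types)
  if (length(wt) == 0) abort_stage("stats", "empty wild-type reference set")
  100 * (t_of(clone) / mean(wt) - 1)
}
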