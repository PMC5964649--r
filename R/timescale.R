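#' Convex-hull volume series of an embryo
#'
#' The overall embryo volume at each timestep is estimated as the volume of
#' the 3D convex hull enveloping the validated nucleus centers.
#'
#' @param lineage An `embryo_lineage`.
#' @return A tibble with `timestep`, `time_hp`, `n_cells` and `volume`
#'   (cubic micrometres), one row per validated timestep.
#' @export
hull_volume_series <- function(lineage) {
  stopifnot(inherits(lineage, "embryo_lineage"))
  nodes <- validated_nodes(lineage)
  if (nrow(nodes) == 0) abort_stage("rescale", "no validated nodes")
  nodes |>
    group_by(.data$timestep) |>
    summarise(time_hp = .data$time_hp[1], n_cells = dplyr::n(),
              volume = frame_volume(.data$x, .data$y, .data$z, .data$timestep[1]),
              .groups = "drop") |>
    arrange(.data$timestep)
}

frame_volume <- function(x, y, z, ts) {
  pts <- cbind(x, y, z)
  tryCatch(.hull3d_cpp(pts)$volume,
           error = function(e) abort_stage("rescale", paste0(
             "degenerate frame at timestep ", ts, ": ", conditionMessage(e))))
}

#' Detect the first blastocoel collapse
#'
#' The first decrease of more than `drop_threshold` (strictly) in the hull
#' volume from one timestep to the next is taken as the first blastocoel
#' collapse. The collapse is reported at the later timestep of the pair --
#' the first frame exhibiting the reduced volume.
#'
#' @param volumes A volume series from [hull_volume_series()] (columns
#'   `timestep`, `time_hp`, `volume`).
#' @param drop_threshold Fractional drop that qualifies as a collapse
#'   (default 0.10: `V(t+1) < 0.9 V(t)`).
#' @return One-row tibble: `timestep`, `time_hp`, `volume_ratio`.
#' @export
detect_first_collapse <- function(volumes, drop_threshold = 0.10) {
  stopifnot(is.data.frame(volumes), nrow(volumes) >= 2)
  v <- volumes$volume
  ratio <- v[-1] / v[-length(v)]
  hit <- which(ratio < 1 - drop_threshold)
  if (length(hit) == 0) {
    abort_stage("collapse", "collapse not detected: no qualifying volume drop")
  }
  i <- hit[1] + 1L
  tibble(timestep = volumes$timestep[i], time_hp = volumes$time_hp[i],
         volume_ratio = ratio[hit[1]])
}

#' Fit the normalized-age timescale of an embryo
#'
#' Anchors normalized age (n.a.) at 0 (fertilization or activation) and 1
#' (first blastocoel collapse): `na(t) = t / t_collapse`.
#'
#' @param lineage An `embryo_lineage`.
#' @param drop_threshold Passed to [detect_first_collapse()].
#' @param volumes Optional precomputed [hull_volume_series()] output.
#' @return An `embryo_timescale` object with the collapse anchor and the
#'   embryo's validated observation window in n.a.
#' @export
fit_timescale <- function(lineage, drop_threshold = 0.10, volumes = NULL) {
  stopifnot(inherits(lineage, "embryo_lineage"))
  volumes <- volumes %||% hull_volume_series(lineage)
  collapse <- detect_first_collapse(volumes, drop_threshold = drop_threshold)
  t_c <- collapse$time_hp
  if (!is.finite(t_c) || t_c <= 0) {
    abort_stage("collapse", "collapse time must be positive")
  }
  structure(
    list(
      embryo_id = lineage$embryo_id,
      group = lineage$group,
      t_collapse_hp = t_c,
      collapse_timestep = collapse$timestep,
      window_lo_na = min(volumes$time_hp) / t_c,
      window_hi_na = max(volumes$time_hp) / t_c
    ),
    class = "embryo_timescale"
  )
}

#' Convert hours post fertilization/activation to normalized age
#'
#' @param time_hp Hours post fertilization (or activation), `>= 0`.
#' @param timescale An `embryo_timescale` from [fit_timescale()], or a
#'   positive number taken as the collapse time in hours.
#' @return `time_hp / t_collapse` (n.a.).
#' @export
normalized_age <- function(time_hp, timescale) {
  t_c <- if (inherits(timescale, "embryo_timescale"))
    timescale$t_collapse_hp else as.numeric(timescale)
  stopifnot(t_c > 0)
  if (any(time_hp < 0)) abort("time_hp must be non-negative")
  time_hp / t_c
}

#' @export
print.embryo_timescale <- function(x, ...) {
  cat(sprintf(
    "<embryo_timescale> %s: collapse at %.2f h (timestep %d), window %.3f - %.3f n.a.\n",
    x$embryo_id, x$t_collapse_hp, x$collapse_timestep,
    x$window_lo_na, x$window_hi_na))
  invisible(x)
}

#' @rdname fit_timescale
#' @param x An `embryo_timescale`.
#' @param ... Unused.
#' @export
tidy.embryo_timescale <- function(x, ...) {
  tibble(embryo_id = x$embryo_id, group = x$group,
         t_collapse_hp = x$t_collapse_hp,
         collapse_timestep = x$collapse_timestep,
         window_lo_na = x$window_lo_na, window_hi_na = x$window_hi_na)
}

#' @rdname fit_timescale
#' @export
glance.embryo_timescale <- function(x, ...) tidy(x)

#' Common observation window of a set of embryos
#'
#' Intersection of per-embryo validated windows in normalized age; group
#' comparisons are restricted to this period.
#'
#' @param windows A tibble with columns `window_lo_na` and `window_hi_na`
#'   (e.g. row-bound [tidy()] of timescales), or a list of
#'   `embryo_timescale` objects.
#' @return One-row tibble: `lo_na`, `hi_na`.
#' @export
common_window <- function(windows) {
  if (is.list(windows) && !is.data.frame(windows) &&
      all(vapply(windows, inherits, logical(1), "embryo_timescale"))) {
    windows <- dplyr::bind_rows(lapply(windows, tidy))
  }
  stopifnot(nrow(windows) >= 1)
  lo <- max(windows$window_lo_na)
  hi <- min(windows$window_hi_na)
  if (lo >= hi) abort_stage("rescale", "empty common window across embryos")
  tibble(lo_na = lo, hi_na = hi)
}

#' Linearly resample a series onto a target grid
#'
#' Linear interpolation between bracketing samples; grid points that
#' coincide with samples return them exactly. Extrapolation outside the
#' sampled range is refused.
#'
#' @param series A data frame containing `time_col` and the value columns.
#' @param grid Numeric vector of target times (within the sampled range).
#' @param time_col Name of the time column (default `"time_na"`).
#' @param value_cols Columns to interpolate (default: all numeric columns
#'   except `time_col`).
#' @return A tibble on the target grid.
#' @export
resample_linear <- function(series, grid, time_col = "time_na",
                            value_cols = NULL) {
  stopifnot(time_col %in% names(series))
  t <- series[[time_col]]
  if (min(grid) < min(t) - 1e-12 || max(grid) > max(t) + 1e-12) {
    abort("grid outside the sampled range: refusing to extrapolate")
  }
  value_cols <- value_cols %||%
    setdiff(names(series)[vapply(series, is.numeric, logical(1))], time_col)
  out <- tibble(!!time_col := grid)
  for (col in value_cols) {
    out[[col]] <- approx(t, series[[col]], xout = grid, ties = "ordered")$y
  }
  out
}

#' Per-embryo timescale table
#'
#' @param timescales A list of `embryo_timescale` objects.
#' @return Tibble with one row per embryo (id, collapse anchor, window).
#' @export
timescale_table <- function(timescales) {
  dplyr::bind_rows(lapply(timescales, tidy))
}
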