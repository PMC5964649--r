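#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one object. Inputs are
#' either lineage CSV files (`inputs`: a data frame with columns `path`,
#' `embryo_id`, `group`, and optionally `time_origin`,
#' `fertilization_offset_h`, `frame_interval_min`) or simulation presets
#' (`simulate`: named integer vector, e.g. `c(wt_like = 3, clone_like = 2)`).
#'
#' @param inputs Optional data frame describing input lineage files.
#' @param simulate Optional named integer vector of preset cohort sizes.
#' @param drop_threshold Collapse detection threshold (default 0.10).
#' @param bin_width Division-profile bin size in n.a. (default 0.05).
#' @param shell_tolerance Shell classification tolerance (default 0.5).
#' @param k_neighbors Neighbourhood size for composition statistics.
#' @param conditions In silico conditions to run.
#' @param out_dir Output directory for CSV tables and the manifest
#'   (`NULL`: nothing written).
#' @param seed Master seed for simulation-based runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL,
                            simulate = c(wt_like = 3, clone_like = 2),
                            drop_threshold = 0.10,
                            bin_width = 0.05,
                            shell_tolerance = 0.5,
                            k_neighbors = 8,
                            conditions = c("observed", "outer_symmetrized",
                                           "inner_symmetrized"),
                            out_dir = NULL,
                            seed = 1) {
  stopifnot(drop_threshold > 0, drop_threshold < 1,
            bin_width > 0, shell_tolerance >= 0, k_neighbors >= 1)
  structure(
    list(inputs = inputs, simulate = simulate,
         drop_threshold = drop_threshold, bin_width = bin_width,
         shell_tolerance = shell_tolerance, k_neighbors = k_neighbors,
         conditions = conditions, out_dir = out_dir, seed = seed),
    class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- as_tibble(config$inputs)
    lineages <- purrr::pmap(inp, function(path, embryo_id, group, ...) {
      extra <- list(...)
      read_lineage(
        path, embryo_id = embryo_id, group = group,
        time_origin = extra$time_origin %||%
          if (group == "wild_type") "fertilization" else "activation",
        fertilization_offset_h = extra$fertilization_offset_h %||% 8,
        frame_interval_min = extra$frame_interval_min %||% 15)
    })
    names(lineages) <- inp$embryo_id
    return(list(lineages = lineages, truths = NULL))
  }
  stopifnot(!is.null(config$simulate), length(config$simulate) > 0)
  sims <- purrr::imap(as.list(config$simulate), function(n, preset) {
    simulate_cohort(preset, n_embryos = n,
                    seed = as.integer((config$seed * 7919 +
                                         match(preset, names(config$simulate))) %%
                                        2147483647))
  })
  sims <- purrr::flatten(sims)
  list(lineages = purrr::map(sims, "lineage"),
       truths = purrr::map(sims, "truth"))
}

#' Run the full lineage analysis pipeline
#'
#' Load or simulate lineages, validate, annotate inner/outer identities,
#' fit the normalized-age timescale from the first blastocoel collapse,
#' compute the population statistics, run the in silico symmetrization
#' comparison, and (optionally) write every table plus a run manifest to
#' `config$out_dir`. Outputs are deterministic for identical
#' `(inputs, config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of result tables (also written as CSV
#'   when `out_dir` is set): validation, timescales, counts, pic,
#'   division_profiles, death_ratios, death_ratio_groups, cv,
#'   neighborhood, neighborhood_summary, founders, relative_speed,
#'   insilico_counts, insilico_cv, manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  lineages <- inputs$lineages

  # -- validate --
  reports <- purrr::map(lineages, validate_lineage)
  validation <- purrr::imap_dfr(reports, function(r, id) {
    tibble(embryo_id = id, pass = attr(r, "pass"),
           n_errors = sum(r$severity == "error"),
           n_warnings = sum(r$severity == "warning"))
  })
  if (!all(validation$pass)) {
    abort_stage("validate", paste0(
      "validation failed for: ",
      paste(validation$embryo_id[!validation$pass], collapse = ", ")))
  }

  # -- annotate --
  annotated <- purrr::map(lineages, annotate_lineage,
                          shell_tolerance = config$shell_tolerance)

  # -- rescale --
  volumes <- purrr::map(lineages, hull_volume_series)
  timescales <- purrr::map2(lineages, volumes, function(l, v) {
    fit_timescale(l, drop_threshold = config$drop_threshold, volumes = v)
  })
  ts_table <- timescale_table(timescales)
  window <- common_window(ts_table)
  # common grid: the densest embryo's n.a. grid restricted to the window
  grids <- purrr::map2(volumes, timescales, function(v, ts) {
    g <- normalized_age(v$time_hp, ts)
    g[g >= window$lo_na & g <= window$hi_na]
  })
  grid <- grids[[which.max(purrr::map_int(grids, length))]]

  # -- statistics --
  counts <- purrr::imap_dfr(annotated, function(a, id) {
    counts_by_type(a, timescales[[id]], grid = grid) |>
      mutate(embryo_id = id, group = a$group, .before = 1)
  })
  pic <- counts |>
    proportion_inner() |>
    group_by(.data$group, .data$time_na) |>
    summarise(pic_mean = mean(.data$pic), pic_sd = sd(.data$pic),
              pic_se = sd(.data$pic) / sqrt(dplyr::n()),
              n_embryos = dplyr::n(), .groups = "drop")

  division_profiles <- purrr::map_dfr(c("outer", "inner"), function(mt) {
    purrr::imap_dfr(annotated, function(a, id) {
      divisions_with_na(a$divisions, timescales[[id]]) |>
        mutate(embryo_id = id, group = a$group)
    }) |>
      group_by(.data$group) |>
      dplyr::group_modify(~ asymmetric_division_proportion(
        .x, mother_type = mt, bin_width = config$bin_width,
        window = c(window$lo_na, window$hi_na))) |>
      ungroup()
  })

  death_ratios <- purrr::imap_dfr(annotated, function(a, id) {
    normalized_death_ratio(a, timescales[[id]],
                           window = c(window$lo_na, window$hi_na)) |>
      mutate(embryo_id = id, group = a$group, .before = 1)
  })
  death_ratio_groups <- death_ratios |>
    group_by(.data$group, .data$identity) |>
    dplyr::group_modify(~ group_stat(.x$ratio)) |>
    ungroup()

  groups <- split(names(annotated),
                  purrr::map_chr(annotated, "group"))
  cv <- purrr::imap_dfr(groups, function(ids, grp) {
    if (length(ids) < 2) return(tibble())
    coefficient_of_variation(filter(counts, .data$embryo_id %in% ids)) |>
      mutate(group = grp, .before = 1)
  })

  neighborhood <- purrr::imap_dfr(annotated, function(a, id) {
    neighborhood_composition(a, k = config$k_neighbors) |>
      mutate(embryo_id = id, group = a$group, .before = 1)
  })
  neighborhood_summary <- dplyr::bind_rows(
    neighborhood |>
      group_by(.data$group, .data$division_type) |>
      dplyr::group_modify(~ group_stat(.x$frac_other)) |>
      ungroup() |>
      mutate(stratified_by = "division_type"),
    neighborhood |>
      group_by(.data$group, .data$division_type, .data$mother_identity) |>
      dplyr::group_modify(~ group_stat(.x$frac_other)) |>
      ungroup() |>
      mutate(stratified_by = "division_type_and_mother"))

  founders <- purrr::imap_dfr(annotated, function(a, id) {
    founder_clone_summary(a) |>
      mutate(embryo_id = id, group = a$group, .before = 1)
  })

  wt_ts <- purrr::keep(timescales, ~ .x$group == "wild_type")
  cl_ts <- purrr::keep(timescales, ~ .x$group == "clone")
  relative_speed <- if (length(wt_ts) > 0 && length(cl_ts) > 0) {
    tibble(embryo_id = names(cl_ts),
           slowdown_pct = relative_developmental_speed(cl_ts, wt_ts))
  } else {
    tibble(embryo_id = character(), slowdown_pct = double())
  }

  # -- in silico comparison, per group --
  insilico <- purrr::imap(groups, function(ids, grp) {
    if (length(ids) < 2) return(NULL)
    condition_comparison(annotated[ids], timescales[ids], grid = grid,
                         conditions = config$conditions)
  })
  insilico_counts <- purrr::imap_dfr(insilico, function(x, grp) {
    if (is.null(x)) tibble() else mutate(x$counts, group = grp, .before = 1)
  })
  insilico_cv <- purrr::imap_dfr(insilico, function(x, grp) {
    if (is.null(x)) tibble() else mutate(x$cv, group = grp, .before = 1)
  })

  manifest <- list(
    package = "blastotrace",
    version = as.character(utils::packageVersion("blastotrace")),
    seed = config$seed,
    drop_threshold = config$drop_threshold,
    bin_width = config$bin_width,
    shell_tolerance = config$shell_tolerance,
    k_neighbors = config$k_neighbors,
    conditions = config$conditions,
    simulate = as.list(config$simulate),
    inputs = if (is.null(config$inputs)) NULL else config$inputs$path,
    embryos = names(lineages),
    common_window = c(lo_na = window$lo_na, hi_na = window$hi_na),
    mother_resolution = "curated annotation when present, else geometric shell rule"
  )

  results <- list(
    validation = validation,
    timescales = ts_table,
    common_window = window,
    counts = counts,
    pic = pic,
    division_profiles = division_profiles,
    death_ratios = death_ratios,
    death_ratio_groups = death_ratio_groups,
    cv = cv,
    neighborhood = neighborhood,
    neighborhood_summary = neighborhood_summary,
    founders = founders,
    relative_speed = relative_speed,
    insilico_counts = insilico_counts,
    insilico_cv = insilico_cv,
    manifest = manifest,
    annotated = annotated,
    timescale_objects = timescales
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(results, config$out_dir)
  }
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("validation", "timescales", "common_window", "counts", "pic",
              "division_profiles", "death_ratios", "death_ratio_groups",
              "cv", "neighborhood", "neighborhood_summary", "founders",
              "relative_speed", "insilico_counts", "insilico_cv")
  for (nm in tables) {
    tb <- results[[nm]]
    if (is.data.frame(tb)) {
      readr::write_csv(tb, file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
  }
  for (id in names(results$annotated)) {
    a <- results$annotated[[id]]
    ann_nodes <- a$nodes
    idmap <- setNames(a$tracks$identity, a$tracks$track_id)
    ann_nodes$identity <- unname(idmap[as.character(ann_nodes$track_id)])
    readr::write_csv(ann_nodes[, lineage_columns],
                     file.path(out_dir, paste0("annotated_", id, ".csv")),
                     progress = FALSE)
  }
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
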