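#' Annotate a lineage with inner/outer identities and division types
#'
#' Identity is assigned per track (a cell keeps one identity between
#' divisions). Leaf tracks take their curated `identity` annotation when
#' present, otherwise the geometric classification of their last nucleus
#' within its frame ([classify_positions()]). Identities are then propagated
#' backward: a mother whose daughters agree inherits their identity; a
#' mother whose daughters disagree (an asymmetric division) is resolved from
#' her own curated annotation when present, else from the geometry at her
#' last timestep. Each division is finally classified as symmetric or
#' asymmetric from its daughters' identities, and each death inherits the
#' dying track's identity.
#'
#' @param lineage An `embryo_lineage`.
#' @param shell_tolerance Passed to [classify_positions()].
#' @param use_curated If `TRUE` (default), identity annotations present in
#'   the input take precedence over geometric classification.
#' @return An `annotated_lineage`: the input plus `identity` and
#'   `identity_source` columns on `$tracks`, a `$divisions` table and a
#'   `$deaths` table.
#' @export
annotate_lineage <- function(lineage, shell_tolerance = 0.5,
                             use_curated = TRUE) {
  stopifnot(inherits(lineage, "embryo_lineage"))
  stop_if_invalid(lineage)
  nodes <- lineage$nodes
  tracks <- lineage$tracks
  nt <- nrow(tracks)
  if (nt == 0) abort_stage("annotate", "empty lineage: nothing to annotate")

  # curated annotation of a track = identity on its last node
  last_row <- match(tracks$last_node_id, nodes$node_id)
  curated <- if (use_curated) nodes$identity[last_row] else
    rep(NA_character_, nt)

  # lazily classify whole frames, once each
  frame_cache <- new.env(parent = emptyenv())
  frame_identity <- function(ts, node_id) {
    key <- as.character(ts)
    if (is.null(frame_cache[[key]])) {
      frame <- nodes[nodes$timestep == ts & nodes$validated, ]
      cls <- tryCatch(
        classify_positions(frame, shell_tolerance = shell_tolerance),
        error = function(e) abort_stage("annotate", paste0(
          "cannot classify frame at timestep ", ts, ": ",
          conditionMessage(e))))
      frame_cache[[key]] <- setNames(cls$identity, cls$node_id)
    }
    out <- frame_cache[[key]][as.character(node_id)]
    if (any(is.na(out))) {
      abort_stage("annotate", paste0(
        "no validated position for node ", node_id, " at timestep ", ts))
    }
    unname(out)
  }

  identity <- rep(NA_character_, nt)
  source <- rep(NA_character_, nt)

  leaves <- which(tracks$fate != "divides")
  for (i in leaves) {
    if (!is.na(curated[i])) {
      identity[i] <- curated[i]
      source[i] <- "curated"
    } else {
      identity[i] <- frame_identity(tracks$last_timestep[i],
                                    tracks$last_node_id[i])
      source[i] <- "geometric"
    }
  }

  # leaves-to-roots pass: daughters are always processed before their mother
  daughters_of <- split(tracks$track_id, tracks$mother_track_id)
  mothers <- order(tracks$last_timestep, decreasing = TRUE)
  mothers <- mothers[tracks$fate[mothers] == "divides"]
  for (i in mothers) {
    kids <- daughters_of[[as.character(tracks$track_id[i])]]
    kid_rows <- match(kids, tracks$track_id)
    kid_ids <- identity[kid_rows]
    if (any(is.na(kid_ids))) {
      abort_stage("annotate", paste0(
        "daughter of track ", tracks$track_id[i], " has no identity"))
    }
    if (kid_ids[1] == kid_ids[2]) {
      identity[i] <- kid_ids[1]
      source[i] <- "inherited"
    } else if (!is.na(curated[i])) {
      identity[i] <- curated[i]
      source[i] <- "curated"
    } else {
      identity[i] <- frame_identity(tracks$last_timestep[i],
                                    tracks$last_node_id[i])
      source[i] <- "geometric"
    }
  }

  tracks$identity <- identity
  tracks$identity_source <- source
  out <- lineage
  out$tracks <- tracks
  out$divisions <- division_records(tracks)
  out$deaths <- death_records(tracks)
  attr(out, "shell_tolerance") <- shell_tolerance
  attr(out, "use_curated") <- use_curated
  class(out) <- c("annotated_lineage", "embryo_lineage")
  out
}

division_records <- function(tracks) {
  moms <- filter(tracks, .data$fate == "divides")
  if (nrow(moms) == 0) {
    return(tibble(
      mother_track_id = integer(), timestep = integer(), time_hp = double(),
      mother_identity = character(), daughter1 = integer(),
      daughter2 = integer(), daughter1_identity = character(),
      daughter2_identity = character(), division_type = character()))
  }
  kids <- tracks |>
    filter(!is.na(.data$mother_track_id)) |>
    arrange(.data$mother_track_id, .data$track_id) |>
    group_by(.data$mother_track_id) |>
    summarise(
      daughter1 = .data$track_id[1], daughter2 = .data$track_id[2],
      daughter1_identity = .data$identity[1],
      daughter2_identity = .data$identity[2],
      .groups = "drop")
  moms |>
    select(mother_track_id = "track_id", "timestep" = "last_timestep",
           time_hp = "last_time_hp", mother_identity = "identity") |>
    inner_join(kids, by = "mother_track_id") |>
    mutate(division_type = ifelse(
      .data$daughter1_identity == .data$daughter2_identity,
      "symmetric", "asymmetric")) |>
    arrange(.data$timestep, .data$mother_track_id)
}

death_records <- function(tracks) {
  tracks |>
    filter(.data$fate == "dies") |>
    select("track_id", timestep = "last_timestep", time_hp = "last_time_hp",
           "identity") |>
    arrange(.data$timestep, .data$track_id)
}

#' Division records of an annotated lineage
#'
#' One record per division: mother and daughter identities and the
#' symmetric/asymmetric call (asymmetric iff the daughters' identities
#' differ). The division time is the mother's last timestep, i.e. the frame
#' before the daughters appear; daughters that never divide carry their
#' identity at their last observed timestep, which is what the per-track
#' identity encodes.
#'
#' @param annotated An `annotated_lineage` from [annotate_lineage()].
#' @return A tibble of division records.
#' @export
classify_divisions <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_lineage"))
  division_records(annotated$tracks)
}

#' @export
print.annotated_lineage <- function(x, ...) {
  NextMethod()
  n_asym <- sum(x$divisions$division_type == "asymmetric")
  cat("  identities: ", sum(x$tracks$identity == "inner"), " inner / ",
      sum(x$tracks$identity == "outer"), " outer tracks\n", sep = "")
  cat("  divisions: ", nrow(x$divisions), " (", n_asym, " asymmetric), deaths: ",
      nrow(x$deaths), "\n", sep = "")
  invisible(x)
}

#' @rdname annotate_lineage
#' @param x An `annotated_lineage`.
#' @param ... Unused.
#' @export
tidy.annotated_lineage <- function(x, ...) {
  select(x$tracks, -"node_ids")
}

#' @rdname annotate_lineage
#' @export
glance.annotated_lineage <- function(x, ...) {
  final_ts <- max(x$nodes$timestep)
  tibble(
    embryo_id = x$embryo_id,
    group = x$group,
    n_nodes = nrow(x$nodes),
    n_tracks = nrow(x$tracks),
    n_cells_final = sum(x$nodes$timestep == final_ts & x$nodes$validated),
    n_divisions = nrow(x$divisions),
    n_asymmetric = sum(x$divisions$division_type == "asymmetric"),
    n_deaths = nrow(x$deaths)
  )
}
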