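#' Extract the division program of an annotated lineage
#'
#' The division program is the minimal description needed to replay
#' identities forward through the tree: per division, whether it was
#' asymmetric and which daughter was the off-type one, plus the identities
#' of the root tracks. Replaying the untransformed program reproduces the
#' annotated identities exactly.
#'
#' @param annotated An `annotated_lineage`.
#' @return A `division_program`: list with `$program` (one row per
#'   division) and `$roots` (root track identities).
#' @export
division_program <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_lineage"))
  div <- annotated$divisions
  offtype <- ifelse(
    div$division_type == "asymmetric",
    ifelse(div$daughter1_identity == div$mother_identity,
           div$daughter2, div$daughter1),
    NA_integer_)
  roots <- annotated$tracks |>
    filter(is.na(.data$mother_track_id)) |>
    select("track_id", "identity")
  structure(
    list(
      program = tibble(
        mother_track_id = div$mother_track_id,
        daughter1 = div$daughter1, daughter2 = div$daughter2,
        division_type = div$division_type,
        offtype_daughter = as.integer(offtype)),
      roots = roots),
    class = "division_program")
}

#' Replay identities forward through a division program
#'
#' Roots keep their identities; processing divisions root-to-leaf, both
#' daughters inherit the mother's current identity, except that at a
#' division flagged asymmetric the designated off-type daughter takes the
#' opposite identity.
#'
#' @param annotated An `annotated_lineage` (supplies the tree).
#' @param program A `division_program`; defaults to the lineage's own.
#' @return Tibble `track_id`, `identity` with the replayed identities.
#' @export
replay_identities <- function(annotated, program = division_program(annotated)) {
  replay_engine(annotated, program, target_type = NULL)
}

replay_engine <- function(annotated, program, target_type = NULL,
                          selection = c("replayed", "original")) {
  selection <- match.arg(selection)
  tracks <- annotated$tracks
  prog <- program$program
  dividing <- tracks$track_id[tracks$fate == "divides"]
  uncovered <- setdiff(dividing, prog$mother_track_id)
  if (length(uncovered) > 0) {
    abort(paste0("division program does not cover mother track(s): ",
                 paste(head(uncovered, 5), collapse = ", ")))
  }
  identity <- setNames(rep(NA_character_, nrow(tracks)),
                       tracks$track_id)
  identity[as.character(program$roots$track_id)] <- program$roots$identity
  original <- setNames(tracks$identity, tracks$track_id)
  # root-to-leaf: order divisions by the mother's birth timestep
  ord <- order(tracks$birth_timestep[match(prog$mother_track_id,
                                           tracks$track_id)])
  for (r in ord) {
    mom <- as.character(prog$mother_track_id[r])
    mom_id <- identity[[mom]]
    if (is.na(mom_id)) abort(paste0("mother track ", mom, " has no identity"))
    asym <- prog$division_type[r] == "asymmetric"
    if (asym && !is.null(target_type)) {
      selector_id <- if (selection == "replayed") mom_id else original[[mom]]
      if (identical(selector_id, target_type)) asym <- FALSE
    }
    d1 <- as.character(prog$daughter1[r])
    d2 <- as.character(prog$daughter2[r])
    identity[[d1]] <- mom_id
    identity[[d2]] <- mom_id
    if (asym) {
      off <- as.character(prog$offtype_daughter[r])
      identity[[off]] <- opposite_identity(mom_id)
    }
  }
  if (anyNA(identity)) {
    abort("replay left tracks without identity (disconnected tree?)")
  }
  tibble(track_id = tracks$track_id,
         identity = unname(identity[as.character(tracks$track_id)]))
}

#' Transform asymmetric divisions into symmetric divisions in silico
#'
#' Replays the lineage's division program root-to-leaf, and at each
#' division whose mother currently has the target identity, treats an
#' asymmetric division as symmetric: both daughters inherit the mother's
#' identity. Only identities change; tree topology, timestamps and
#' positions are untouched. By default the mother's identity is evaluated
#' under the transformed dynamics (`selection = "replayed"`), which is the
#' only reading that leaves no target-type asymmetric divisions in the
#' result; `selection = "original"` selects on the observed annotation
#' instead, for sensitivity analysis.
#'
#' @param annotated An `annotated_lineage`.
#' @param target `"outer"` or `"inner"`: which mothers' asymmetric
#'   divisions are symmetrized.
#' @param selection `"replayed"` (default) or `"original"`.
#' @return An `annotated_lineage` with recomputed identities, divisions and
#'   death identities, carrying attributes `condition` and `selection`.
#' @export
symmetrize_divisions <- function(annotated, target = c("outer", "inner"),
                                 selection = c("replayed", "original")) {
  target <- match.arg(target)
  selection <- match.arg(selection)
  prog <- division_program(annotated)
  new_ids <- replay_engine(annotated, prog, target_type = target,
                           selection = selection)
  apply_identities(annotated, new_ids,
                   condition = paste0(target, "_symmetrized"),
                   selection = selection)
}

apply_identities <- function(annotated, new_ids, condition,
                             selection = NULL) {
  out <- annotated
  out$tracks$identity <-
    new_ids$identity[match(out$tracks$track_id, new_ids$track_id)]
  out$divisions <- division_records(out$tracks)
  out$deaths <- death_records(out$tracks)
  attr(out, "condition") <- condition
  attr(out, "selection") <- selection
  out
}

#' Compare population variability across in silico conditions
#'
#' Recomputes inner/outer count series and the across-embryo coefficient
#' of variation for the observed lineages and for their transformed
#' counterparts (outer- and/or inner-symmetrized).
#'
#' @param cohort Named list of `annotated_lineage` objects.
#' @param timescales Named list of matching `embryo_timescale` objects.
#' @param grid Common n.a. grid (within every embryo's window).
#' @param conditions Subset of
#'   `c("observed", "outer_symmetrized", "inner_symmetrized")`.
#' @param selection Passed to [symmetrize_divisions()].
#' @return List with `$counts` (long tibble: condition, embryo, grid
#'   counts) and `$cv` (condition, type, time, cv).
#' @export
condition_comparison <- function(cohort, timescales, grid,
                                 conditions = c("observed",
                                                "outer_symmetrized",
                                                "inner_symmetrized"),
                                 selection = "replayed") {
  stopifnot(length(cohort) >= 1, all(names(cohort) %in% names(timescales)))
  transform_one <- function(ann, condition) {
    switch(condition,
           observed = ann,
           outer_symmetrized = symmetrize_divisions(ann, "outer", selection),
           inner_symmetrized = symmetrize_divisions(ann, "inner", selection))
  }
  counts <- purrr::map_dfr(conditions, function(cond) {
    purrr::imap_dfr(cohort, function(ann, id) {
      transformed <- transform_one(ann, cond)
      counts_by_type(transformed, timescales[[id]], grid = grid) |>
        mutate(embryo_id = id, condition = cond, .before = 1)
    })
  })
  cv <- counts |>
    group_by(.data$condition) |>
    dplyr::group_modify(~ coefficient_of_variation(.x)) |>
    ungroup()
  list(counts = counts, cv = cv)
}
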