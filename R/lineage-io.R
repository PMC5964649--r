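#' Column layout of the lineage table dialect
#'
#' One row per detected nucleus per timestep. `node_id` is unique within a
#' file; `predecessor_id` links a nucleus to the same cell one timestep
#' earlier (empty for roots); `time_hp` is hours post fertilization (wild
#' types) or post activation (clones); positions are micrometres in the
#' microscope frame; `identity` is `"inner"`, `"outer"` or empty; `death`
#' marks the last nucleus of a dying cell.
#'
#' @format A character vector of the ten required column names, in order.
#' @export
lineage_columns <- c(
  "node_id", "predecessor_id", "timestep", "time_hp",
  "x", "y", "z", "validated", "identity", "death"
)

new_lineage <- function(nodes, embryo_id, group, time_origin,
                        fertilization_offset_h, frame_interval_min) {
  nodes <- as_tibble(nodes)[, lineage_columns]
  nodes <- arrange(nodes, .data$timestep, .data$node_id)
  trk <- tryCatch(assign_tracks(nodes), error = function(e) e)
  if (inherits(trk, "error")) {
    structural <- conditionMessage(trk)
    nodes$track_id <- NA_integer_
    tracks <- empty_tracks()
  } else {
    structural <- character()
    nodes <- trk$nodes
    tracks <- trk$tracks
  }
  structure(
    list(
      nodes = nodes, tracks = tracks,
      embryo_id = embryo_id, group = group, time_origin = time_origin,
      fertilization_offset_h = fertilization_offset_h,
      frame_interval_min = frame_interval_min,
      structural_errors = structural
    ),
    class = "embryo_lineage"
  )
}

empty_tracks <- function() {
  tibble(
    track_id = integer(), mother_track_id = integer(),
    birth_timestep = integer(), last_timestep = integer(),
    birth_time_hp = double(), last_time_hp = double(),
    fate = character(), n_nodes = integer(),
    first_node_id = integer(), last_node_id = integer(),
    node_ids = list()
  )
}

#' Read a lineage table
#'
#' Reads the CSV dialect described in [lineage_columns] and assembles the
#' embryo's node graph and cell tracks. Unparseable rows, missing columns,
#' duplicated node ids and predecessor links that do not point one timestep
#' back are format errors and abort the read; softer consistency issues are
#' left to [validate_lineage()].
#'
#' @param path Path to a CSV file in the lineage dialect.
#' @param embryo_id Identifier for the specimen (e.g. `"wt1"`).
#' @param group `"wild_type"` or `"clone"`.
#' @param time_origin `"fertilization"` (wild type) or `"activation"`
#'   (clones); record-keeping only, `time_hp` is always measured from it.
#' @param fertilization_offset_h Hours between coitum and estimated
#'   fertilization (default 8); metadata carried along, not applied.
#' @param frame_interval_min Imaging frame interval in minutes (default 15).
#' @return An `embryo_lineage` object: node table, track table and metadata.
#' @seealso [write_lineage()], [validate_lineage()], [build_tracks()]
#' @export
read_lineage <- function(path, embryo_id = basename(path),
                         group = c("wild_type", "clone"),
                         time_origin = NULL,
                         fertilization_offset_h = 8,
                         frame_interval_min = 15) {
  group <- match.arg(group)
  time_origin <- time_origin %||%
    if (group == "wild_type") "fertilization" else "activation"
  if (!file.exists(path)) abort_stage("format", paste0("file not found: ", path))
  nodes <- readr::read_csv(
    path,
    col_types = readr::cols(
      node_id = readr::col_integer(),
      predecessor_id = readr::col_integer(),
      timestep = readr::col_integer(),
      time_hp = readr::col_double(),
      x = readr::col_double(), y = readr::col_double(), z = readr::col_double(),
      validated = readr::col_logical(),
      identity = readr::col_character(),
      death = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(lineage_columns, names(nodes))
  if (length(missing) > 0) {
    abort_stage("format", paste0(
      "missing required column(s): ", paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(nodes)
  if (nrow(probs) > 0) {
    abort_stage("format", paste0(
      nrow(probs), " unparseable cell(s); first at row ", probs$row[1],
      ", column ", probs$col[1], ": ", probs$expected[1]))
  }
  check_node_format(nodes)
  new_lineage(nodes, embryo_id, group, time_origin,
              fertilization_offset_h, frame_interval_min)
}

check_node_format <- function(nodes) {
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup) > 0) {
    abort_stage("format", paste0(
      "duplicate node_id: ", paste(head(unique(dup), 5), collapse = ", ")))
  }
  bad_identity <- setdiff(unique(nodes$identity[!is.na(nodes$identity)]),
                          c("inner", "outer"))
  if (length(bad_identity) > 0) {
    abort_stage("format", paste0(
      "identity must be 'inner', 'outer' or empty; found: ",
      paste(bad_identity, collapse = ", ")))
  }
  pred_row <- match(nodes$predecessor_id, nodes$node_id)
  has_pred <- !is.na(nodes$predecessor_id) & !is.na(pred_row)
  same_or_later <- has_pred &
    nodes$timestep[pred_row] >= nodes$timestep
  if (any(same_or_later)) {
    abort_stage("format", paste0(
      "predecessor at the same or a later timestep for node_id: ",
      paste(head(nodes$node_id[same_or_later], 5), collapse = ", ")))
  }
  invisible(nodes)
}

#' Write a lineage table
#'
#' Inverse of [read_lineage()]: emits exactly the dialect columns, with
#' missing predecessors and unset identities written as empty fields.
#' `read_lineage(write_lineage(L))` reproduces the node table field for
#' field.
#'
#' @param lineage An `embryo_lineage`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lineage, path) {
  stopifnot(inherits(lineage, "embryo_lineage"))
  readr::write_csv(lineage$nodes[, lineage_columns], path, na = "",
                   progress = FALSE)
  invisible(path)
}

# Partition the node graph into tracks: maximal chains between divisions.
# A new track starts at every root and at every daughter of a division.
assign_tracks <- function(nodes) {
  n <- nrow(nodes)
  if (n == 0) return(list(nodes = mutate(nodes, track_id = integer()),
                          tracks = empty_tracks()))
  pred_row <- match(nodes$predecessor_id, nodes$node_id)
  n_succ <- tabulate(pred_row[!is.na(pred_row)], nbins = n)
  if (any(n_succ > 2)) {
    stop("node with 3 or more successors: node_id ",
         paste(head(nodes$node_id[n_succ > 2], 5), collapse = ", "),
         call. = FALSE)
  }
  is_start <- is.na(pred_row) | n_succ[ifelse(is.na(pred_row), 1L, pred_row)] >= 2
  is_start[is.na(pred_row)] <- TRUE

  # chase chains frame by frame (nodes are sorted by timestep)
  root_row <- seq_len(n)
  steps <- sort(unique(nodes$timestep))
  for (ts in steps) {
    rows <- which(nodes$timestep == ts & !is_start)
    if (length(rows) > 0) root_row[rows] <- root_row[pred_row[rows]]
  }
  track_id <- match(root_row, sort(unique(root_row[is_start])))
  nodes$track_id <- track_id

  by_track <- nodes |>
    group_by(.data$track_id) |>
    summarise(
      birth_timestep = min(.data$timestep),
      last_timestep = max(.data$timestep),
      birth_time_hp = .data$time_hp[which.min(.data$timestep)],
      last_time_hp = .data$time_hp[which.max(.data$timestep)],
      n_nodes = dplyr::n(),
      first_node_id = .data$node_id[which.min(.data$timestep)],
      last_node_id = .data$node_id[which.max(.data$timestep)],
      death_last = .data$death[which.max(.data$timestep)],
      .groups = "drop"
    )
  last_row <- match(by_track$last_node_id, nodes$node_id)
  n_succ_last <- n_succ[last_row]
  first_row <- match(by_track$first_node_id, nodes$node_id)
  mother_row <- pred_row[first_row]
  mother_track <- ifelse(is.na(mother_row), NA_integer_, track_id[mother_row])
  tracks <- by_track |>
    mutate(
      mother_track_id = as.integer(mother_track),
      fate = dplyr::case_when(
        n_succ_last >= 2 ~ "divides",
        .data$death_last ~ "dies",
        TRUE ~ "censored"
      )
    ) |>
    select(-"death_last")
  node_ids <- split(nodes$node_id[order(nodes$track_id, nodes$timestep)],
                    sort(nodes$track_id))
  tracks$node_ids <- unname(node_ids[as.character(tracks$track_id)])
  tracks <- tracks[, names(empty_tracks())]
  list(nodes = nodes, tracks = tracks)
}

#' Build cell tracks from a node table
#'
#' Splits the node graph into maximal division-to-division chains. Every node
#' belongs to exactly one track; a track ends where its last node has two
#' successors (`fate = "divides"`), carries a death flag (`"dies"`) or simply
#' stops (`"censored"`).
#'
#' @param nodes A data frame in the [lineage_columns] layout.
#' @return A tibble with one row per track (`track_id`, `mother_track_id`,
#'   birth/last timestep and time, `fate`, node counts and a `node_ids`
#'   list-column of the ordered member nodes).
#' @export
build_tracks <- function(nodes) {
  assign_tracks(arrange(as_tibble(nodes), .data$timestep, .data$node_id))$tracks
}

#' Validate a lineage
#'
#' Checks the structural invariants that downstream analysis relies on:
#' predecessors exist and sit exactly one timestep back, no node has more
#' than two successors, death-flagged nodes are terminal, and `time_hp` is
#' consistent with `timestep` under a single frame interval and offset.
#'
#' @param lineage An `embryo_lineage`.
#' @param time_tolerance_h Allowed absolute discrepancy (hours) between
#'   `time_hp` and `timestep * frame_interval + offset`.
#' @return A `validation_report`: tibble of issues (severity, code, id,
#'   message) with a logical `pass` attribute (`TRUE` iff no errors).
#' @export
validate_lineage <- function(lineage, time_tolerance_h = 1e-6) {
  stopifnot(inherits(lineage, "embryo_lineage"))
  nodes <- lineage$nodes
  issues <- list()
  add <- function(severity, code, id, message) {
    issues[[length(issues) + 1]] <<- tibble(
      severity = severity, code = code, id = as.integer(id), message = message)
  }
  for (msg in lineage$structural_errors) add("error", "structure", NA, msg)

  dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
  for (d in dup) add("error", "duplicate_node_id", d, "node_id appears more than once")

  pred_row <- match(nodes$predecessor_id, nodes$node_id)
  orphan <- !is.na(nodes$predecessor_id) & is.na(pred_row)
  for (i in which(orphan)) {
    add("error", "missing_predecessor", nodes$node_id[i],
        paste0("predecessor ", nodes$predecessor_id[i], " not in file"))
  }
  has_pred <- !is.na(pred_row)
  gap <- has_pred & (nodes$timestep - nodes$timestep[ifelse(has_pred, pred_row, 1L)] != 1L)
  for (i in which(gap)) {
    add("error", "gap_in_track", nodes$node_id[i],
        "predecessor is not exactly one timestep earlier")
  }
  n <- nrow(nodes)
  n_succ <- tabulate(pred_row[!is.na(pred_row)], nbins = n)
  for (i in which(n_succ > 2)) {
    add("error", "too_many_successors", nodes$node_id[i],
        paste0(n_succ[i], " successors (at most 2 allowed)"))
  }
  dead_with_succ <- which(nodes$death & n_succ > 0)
  for (i in dead_with_succ) {
    add("error", "death_not_terminal", nodes$node_id[i],
        "death node not terminal: death-flagged node has a successor")
  }
  if (n > 0) {
    frame_h <- lineage$frame_interval_min / 60
    offset <- median(nodes$time_hp - nodes$timestep * frame_h)
    resid <- abs(nodes$time_hp - (nodes$timestep * frame_h + offset))
    for (i in which(resid > time_tolerance_h)) {
      add("error", "time_spacing", nodes$node_id[i],
          sprintf("time_hp off the %g-min frame grid by %.4g h",
                  lineage$frame_interval_min, resid[i]))
    }
  }
  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble(severity = character(), code = character(),
           id = integer(), message = character())
  structure(issues,
            pass = !any(issues$severity == "error"),
            embryo_id = lineage$embryo_id,
            class = c("validation_report", class(issues)))
}

#' @export
print.validation_report <- function(x, ...) {
  status <- if (attr(x, "pass")) "PASS" else "FAIL"
  cat("<validation_report> ", attr(x, "embryo_id"), ": ", status,
      " (", sum(x$severity == "error"), " error(s), ",
      sum(x$severity == "warning"), " warning(s))\n", sep = "")
  if (nrow(x) > 0) print(as_tibble(x), ...)
  invisible(x)
}

#' @export
print.embryo_lineage <- function(x, ...) {
  cat("<embryo_lineage> ", x$embryo_id, " [", x$group, "]\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), ", tracks: ", nrow(x$tracks),
      ", timesteps: ", length(unique(x$nodes$timestep)), "\n", sep = "")
  if (nrow(x$nodes) > 0) {
    cat(sprintf("  window: %.2f - %.2f h (frame %g min)\n",
                min(x$nodes$time_hp), max(x$nodes$time_hp),
                x$frame_interval_min))
  }
  if (length(x$structural_errors) > 0) {
    cat("  structural errors: ", paste(x$structural_errors, collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

# Nodes usable for statistics: curated/validated rows only.
validated_nodes <- function(lineage) {
  filter(lineage$nodes, .data$validated)
}

stop_if_invalid <- function(lineage) {
  if (length(lineage$structural_errors) > 0) {
    abort_stage("validate", paste0(
      "lineage has structural errors: ",
      paste(lineage$structural_errors, collapse = "; ")))
  }
  invisible(lineage)
}
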