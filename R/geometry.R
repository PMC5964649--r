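#' 3D convex hull of a point cloud
#'
#' Incremental convex hull of nucleus centers. Returns the enclosed volume,
#' the indices of the points that are hull vertices, and the supporting
#' planes of the triangular facets (outward unit normals `n` with
#' `n . x = offset` on the plane).
#'
#' @param points An `n x 3` numeric matrix or a data frame with columns
#'   `x`, `y`, `z` (micrometres).
#' @return A list with `volume`, `vertices` (integer row indices),
#'   `facets` (`m x 3` vertex indices), `normals` (`m x 3` outward unit
#'   normals) and `offsets` (length `m`).
#' @export
convex_hull_3d <- function(points) {
  pts <- as_point_matrix(points)
  .hull3d_cpp(pts)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- cbind(points$x, points$y, points$z)
  }
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) abort("points must have three coordinates")
  pts
}

# Perpendicular distance from each point to its nearest hull facet plane
# (non-negative inside the hull, 0 for hull vertices).
hull_plane_distance <- function(pts, hull) {
  keep <- !is.na(hull$offsets)
  normals <- hull$normals[keep, , drop = FALSE]
  offsets <- hull$offsets[keep]
  d <- sweep(-(pts %*% t(normals)), 2, offsets, "+") # offset - n.x per facet
  apply(d, 1, min)
}

mean_nn_distance <- function(pts) {
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

#' Classify nuclei of one frame as inner or outer
#'
#' A nucleus is annotated `"outer"` if it is a vertex of the frame's 3D
#' convex hull, or if its perpendicular distance to the nearest hull facet
#' plane is at most `shell_tolerance` times the frame's mean
#' nearest-neighbour distance; otherwise `"inner"`. Distances exactly on the
#' tolerance classify as outer (ties break toward the trophectoderm shell).
#'
#' @param positions Data frame with columns `x`, `y`, `z` (one row per
#'   nucleus of a single timestep); other columns are passed through.
#' @param shell_tolerance Shell thickness as a fraction of the mean
#'   nearest-neighbour distance (default 0.5).
#' @return `positions` with an added `identity` column.
#' @export
classify_positions <- function(positions, shell_tolerance = 0.5) {
  pts <- as_point_matrix(positions)
  if (nrow(pts) < 5) {
    abort("degenerate geometry: need at least 5 nuclei to classify a frame")
  }
  hull <- .hull3d_cpp(pts) # errors on coplanar/collinear input
  dist_facet <- hull_plane_distance(pts, hull)
  shell <- shell_tolerance * mean_nn_distance(pts)
  outer <- seq_len(nrow(pts)) %in% hull$vertices | dist_facet <= shell
  out <- as_tibble(positions)
  out$identity <- ifelse(outer, "outer", "inner")
  out
}
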