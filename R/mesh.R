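#' Triangulated surface mesh
#'
#' Constructs a `tri_mesh`, the geometric substrate for cardiac source and
#' torso surfaces. Coordinates are in millimetres. Triangle indices are
#' 1-based internally (the R convention); on-disk formats convert as needed.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices. Orientation (vertex order) must be consistent across
#'   the surface.
#' @param labels optional character vector of per-vertex region labels,
#'   values in `c("ventricular", "atrial", "cap", "torso", "unlabeled")`.
#' @param validate logical; run [validate_mesh()] on construction.
#' @return an object of class `tri_mesh` with fields `vertices`,
#'   `triangles`, `labels`.
#' @export
tri_mesh <- function(vertices, triangles, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L)
    stop("vertices must have 3 columns")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (nrow(triangles) > 0L && ncol(triangles) != 3L)
    stop("triangles must have 3 columns")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(vertices))
      stop("labels must have one entry per vertex")
    bad <- setdiff(unique(labels), mesh_label_levels())
    if (length(bad))
      stop("unknown region labels: ", paste(bad, collapse = ", "))
  }
  m <- structure(list(vertices = vertices, triangles = triangles,
                      labels = labels),
                 class = "tri_mesh")
  if (validate) validate_mesh(m)
  m
}

mesh_label_levels <- function() {
  c("ventricular", "atrial", "cap", "torso", "unlabeled")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cl <- if (is_closed_mesh(x)) "closed" else "open"
  cat(sprintf("tri_mesh: %d vertices, %d triangles (%s)\n",
              nrow(x$vertices), nrow(x$triangles), cl))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of vertices / triangles
#' @param mesh a [tri_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_triangles <- function(mesh) nrow(mesh$triangles)

# directed edge table: one row per triangle half-edge (from, to)
mesh_half_edges <- function(mesh) {
  tr <- mesh$triangles
  cbind(from = c(tr[, 1], tr[, 2], tr[, 3]),
        to   = c(tr[, 2], tr[, 3], tr[, 1]))
}

# undirected edge key (smaller index first), used for censuses
edge_keys <- function(he) {
  a <- pmin(he[, 1], he[, 2])
  b <- pmax(he[, 1], he[, 2])
  paste(a, b, sep = "-")
}

#' Per-triangle areas
#' @param mesh a [tri_mesh()].
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(numeric(0))
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' Validate a triangulated surface mesh
#'
#' Checks index ranges, distinctness of triangle corners, positive triangle
#' areas, edge manifoldness (no undirected edge used by more than two
#' triangles) and orientation consistency (every interior edge traversed
#' once in each direction). Open meshes are permitted; closure is a
#' separate predicate, [is_closed_mesh()].
#'
#' @param mesh a [tri_mesh()].
#' @param min_area minimum admissible triangle area (mm^2).
#' @return `mesh`, invisibly; errors describe the first violation found.
#' @export
validate_mesh <- function(mesh, min_area = 1e-12) {
  v <- mesh$vertices
  tr <- mesh$triangles
  if (nrow(v) == 0L) stop("mesh has no vertices")
  if (anyNA(v)) stop("mesh has non-finite vertex coordinates")
  if (nrow(tr) > 0L) {
    if (min(tr) < 1L || max(tr) > nrow(v))
      stop("triangle vertex index out of range (valid range 1..",
           nrow(v), ")")
    same <- tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]
    if (any(same))
      stop("triangle ", which(same)[1], " repeats a vertex")
    ar <- triangle_areas(mesh)
    if (any(ar <= min_area))
      stop("triangle ", which(ar <= min_area)[1], " has zero area")
    he <- mesh_half_edges(mesh)
    keys <- edge_keys(he)
    cnt <- table(keys)
    if (any(cnt > 2L))
      stop("non-manifold edge ", names(cnt)[which(cnt > 2L)[1]],
           " used by more than two triangles")
    # orientation: an interior edge must appear once per direction
    dir_keys <- paste(he[, 1], he[, 2], sep = ">")
    if (anyDuplicated(dir_keys))
      stop("inconsistent orientation: directed edge ",
           dir_keys[anyDuplicated(dir_keys)], " appears twice")
  }
  invisible(mesh)
}

#' Closedness and Euler characteristic
#'
#' A mesh is closed when it has no boundary edges; a closed surface of
#' sphere topology additionally has Euler characteristic
#' \eqn{V - E + F = 2}.
#'
#' @param mesh a [tri_mesh()].
#' @return `is_closed_mesh`: logical. `euler_characteristic`: integer.
#' @export
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(FALSE)
  he <- mesh_half_edges(mesh)
  all(table(edge_keys(he)) == 2L)
}

#' @rdname is_closed_mesh
#' @export
euler_characteristic <- function(mesh) {
  he <- mesh_half_edges(mesh)
  n_edges <- length(unique(edge_keys(he)))
  nrow(mesh$vertices) - n_edges + nrow(mesh$triangles)
}

#' Boundary loops of an open mesh
#'
#' Finds boundary edges (undirected edges used by exactly one triangle) and
#' chains them into closed polylines, one per boundary component. Loop
#' orientation follows the half-edge direction of the bordering triangles,
#' so a cap stitched along a loop in reverse order is consistently oriented
#' with the body of the mesh.
#'
#' @param mesh a validated [tri_mesh()].
#' @return a list of integer vectors of vertex indices (each a closed loop;
#'   the first vertex is not repeated at the end). Empty list for a closed
#'   mesh.
#' @export
boundary_loops <- function(mesh) {
  validate_mesh(mesh)
  he <- mesh_half_edges(mesh)
  keys <- edge_keys(he)
  cnt <- table(keys)
  bkeys <- names(cnt)[cnt == 1L]
  if (!length(bkeys)) return(list())
  bhe <- he[keys %in% bkeys, , drop = FALSE]
  # boundary half-edges form disjoint cycles; follow from -> to
  nxt <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(bhe))) {
    k <- as.character(bhe[i, 1])
    if (!is.null(nxt[[k]]))
      stop("non-manifold boundary at vertex ", bhe[i, 1])
    nxt[[k]] <- bhe[i, 2]
  }
  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (i in seq_len(nrow(bhe))) {
    start <- bhe[i, 1]
    if (!is.null(visited[[as.character(start)]])) next
    loop <- integer(0)
    cur <- start
    repeat {
      loop <- c(loop, cur)
      visited[[as.character(cur)]] <- TRUE
      cur <- nxt[[as.character(cur)]]
      if (is.null(cur)) stop("open boundary chain at vertex ", loop[length(loop)])
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Drop vertices referenced by no triangle
#'
#' Compacts the vertex table (reindexing triangles and labels), e.g. after
#' clipping triangles off a mesh. Triangle order is preserved.
#'
#' @param mesh a [tri_mesh()].
#' @return a `tri_mesh` whose vertices are all referenced.
#' @export
drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$triangles)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[mesh$triangles], ncol = 3L),
           labels = if (!is.null(mesh$labels)) mesh$labels[used],
           validate = FALSE)
}

# vertex indices within `rings` edge-hops of the given seed set
vertex_rings <- function(mesh, seed_idx, rings) {
  he <- mesh_half_edges(mesh)
  sel <- rep(FALSE, nrow(mesh$vertices))
  sel[seed_idx] <- TRUE
  for (r in seq_len(rings)) {
    grow <- he[sel[he[, 1]], 2]
    sel[grow] <- TRUE
  }
  which(sel)
}
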