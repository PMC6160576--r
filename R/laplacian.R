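#' Surface Laplacian operator
#'
#' Assembles the sparse symmetric Laplacian of a triangulated surface.
#' Off-diagonal entries are edge weights, diagonals the negated row sums,
#' so every row sums to zero and `L %*% constant = 0`.
#'
#' Two weight schemes:
#' \describe{
#'   \item{`cotangent`}{half-sum of the cotangents of the angles opposite
#'     each edge. Linear precision on planar meshes (the default); weights
#'     can be negative on obtuse triangles, so the discrete maximum
#'     principle is not guaranteed.}
#'   \item{`inverse_distance`}{\eqn{w_{ij} = 1/|x_i - x_j|}, strictly
#'     positive, in the spirit of the distance-weighted Laplacian used in
#'     classical surface-potential interpolation; guarantees the maximum
#'     principle.}
#' }
#' Degenerate triangles (area below `1e-12`) would make the cotangent
#' weights blow up; such triangles fall back to inverse-distance weights
#' and are counted in the `"fallback_count"` attribute.
#'
#' @param mesh a validated [tri_mesh()], open or closed.
#' @param scheme `"cotangent"` or `"inverse_distance"`.
#' @return an object of class `surface_laplacian`: fields `L` (sparse
#'   `dgCMatrix`), `scheme`, `n`.
#' @export
build_laplacian <- function(mesh, scheme = c("cotangent",
                                             "inverse_distance")) {
  scheme <- match.arg(scheme)
  validate_mesh(mesh)
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  fallback <- 0L
  edge_len <- function(i, j) sqrt(rowSums((v[i, , drop = FALSE] -
                                             v[j, , drop = FALSE])^2))
  if (scheme == "inverse_distance") {
    he <- mesh_half_edges(mesh)
    keys <- edge_keys(he)
    und <- he[!duplicated(keys), , drop = FALSE]
    w <- 1 / edge_len(und[, 1], und[, 2])
    ii <- c(und[, 1], und[, 2]); jj <- c(und[, 2], und[, 1]); ww <- c(w, w)
  } else {
    ar <- triangle_areas(mesh)
    for (corner in 1:3) {
      k <- tr[, corner]
      i <- tr[, corner %% 3 + 1]
      j <- tr[, (corner + 1) %% 3 + 1]
      a <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
      b <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
      cosk <- rowSums(a * b)
      cx <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                  a[, 3] * b[, 1] - a[, 1] * b[, 3],
                  a[, 1] * b[, 2] - a[, 2] * b[, 1])
      sink <- sqrt(rowSums(cx^2))
      bad <- ar <= 1e-12
      fallback <- fallback + sum(bad) # counted once per corner visit
      w <- ifelse(bad, 1 / edge_len(i, j), 0.5 * cosk / sink)
      ii <- c(ii, i, j); jj <- c(jj, j, i); ww <- c(ww, w, w)
    }
    fallback <- fallback %/% 3L
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  out <- structure(list(L = methods::as(L, "CsparseMatrix"),
                        scheme = scheme, n = n),
                   class = "surface_laplacian")
  attr(out, "fallback_count") <- as.integer(fallback)
  out
}

#' @export
print.surface_laplacian <- function(x, ...) {
  cat(sprintf("surface_laplacian (%s) on %d vertices, %d nonzeros\n",
              x$scheme, x$n, Matrix::nnzero(x$L)))
  invisible(x)
}

#' Laplacian interpolation of partially known surface potentials
#'
#' Estimates potentials at unsampled vertices from sampled ones by forcing
#' the interpolant to be discretely harmonic on the unknown set: with the
#' Laplacian partitioned into known (k) and unknown (u) blocks, solves
#' \eqn{L_{uu} \Phi_u = -L_{uk} \Phi_k} by a direct sparse factorisation.
#' Known values are returned untouched, so interpolating a fully known
#' field is the identity. Multiple time frames (columns) are solved against
#' one factorisation.
#'
#' @param laplacian a [build_laplacian()] operator.
#' @param known_idx integer indices of measured vertices (non-empty).
#' @param known_vals numeric vector, or matrix with one column per frame,
#'   of measured potentials ordered as `known_idx`.
#' @return a full-length vector (or `n x frames` matrix) of potentials.
#' @export
interpolate_potentials <- function(laplacian, known_idx, known_vals) {
  n <- laplacian$n
  known_idx <- as.integer(known_idx)
  if (!length(known_idx)) stop("known_idx must be non-empty")
  if (anyDuplicated(known_idx) || min(known_idx) < 1 || max(known_idx) > n)
    stop("known_idx must be distinct indices in 1..", n)
  vec_in <- is.null(dim(known_vals))
  known_vals <- as.matrix(known_vals)
  if (nrow(known_vals) != length(known_idx))
    stop("known_vals must have one row per known index")
  unk <- setdiff(seq_len(n), known_idx)
  out <- matrix(NA_real_, n, ncol(known_vals))
  out[known_idx, ] <- known_vals
  if (length(unk)) {
    L <- laplacian$L
    check_unknown_connectivity(L, unk, known_idx)
    Luu <- L[unk, unk, drop = FALSE]
    rhs <- -L[unk, known_idx, drop = FALSE] %*% known_vals
    sol <- Matrix::solve(Luu, rhs)
    out[unk, ] <- as.matrix(sol)
  }
  if (vec_in) as.vector(out) else out
}

# every connected component of the unknown subgraph must touch a known
# vertex, else L_uu is singular there
check_unknown_connectivity <- function(L, unk, known_idx) {
  n <- nrow(L)
  is_unk <- rep(FALSE, n); is_unk[unk] <- TRUE
  Lp <- methods::as(L, "TsparseMatrix")
  ei <- Lp@i + 1L; ej <- Lp@j + 1L
  off <- ei != ej
  ei <- ei[off]; ej <- ej[off]
  comp <- rep(NA_integer_, n)
  # adjacency restricted to unknowns
  adj <- split(ej[is_unk[ei] & is_unk[ej]], ei[is_unk[ei] & is_unk[ej]])
  touches <- split(!is_unk[ej], ei)
  cid <- 0L
  for (s in unk) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    has_known <- FALSE
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      tk <- touches[[as.character(x)]]
      if (!is.null(tk) && any(tk)) has_known <- TRUE
      nb <- adj[[as.character(x)]]
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
    if (!has_known)
      stop("unknown component ", cid,
           " has no measured neighbour; interpolation is singular")
  }
  invisible(TRUE)
}

#' Interpolate every frame of a frame set
#'
#' Frame-wise application of [interpolate_potentials()] sharing one
#' factorisation; equals per-frame solves to solver tolerance.
#'
#' @param laplacian a [build_laplacian()] operator on the frame set's mesh.
#' @param known_idx measured vertex indices.
#' @param fs a [frame_set()] (only rows `known_idx` are consulted).
#' @return a `frame_set` with all rows filled.
#' @export
interpolate_frames <- function(laplacian, known_idx, fs) {
  vals <- interpolate_potentials(laplacian, known_idx,
                                 fs$values[known_idx, , drop = FALSE])
  frame_set(vals, fs$mesh_id, fs$frame_ms, fs$units)
}
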