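#' Least-squares ellipsoid fit
#'
#' Fits a general quadric to a point cloud by linear least squares (the
#' algebraic fit: smallest right singular vector of the design matrix under
#' a unit-norm coefficient constraint) and extracts the ellipsoid centre,
#' semi-axes and principal frame. Input points are centred and scaled
#' before fitting for conditioning; the result is mapped back.
#'
#' @param points numeric matrix (n x 3) of sample points (mm).
#' @return a list with `center` (3-vector), `radii` (semi-axes, mm,
#'   decreasing), `axes` (3 x 3 rotation matrix, columns are principal
#'   directions).
#' @export
fit_ellipsoid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 9L)
    stop("need at least 9 points to fit an ellipsoid")
  c0 <- colMeans(points)
  P <- sweep(points, 2, c0)
  s <- mean(sqrt(rowSums(P^2)))
  if (s <= 0) stop("degenerate point cloud")
  P <- P / s
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * y * z, 2 * x * z, 2 * x * y,
             2 * x, 2 * y, 2 * z, 1)
  v <- svd(D, nu = 0)$v[, 10]
  Q <- matrix(c(v[1], v[6], v[5],
                v[6], v[2], v[4],
                v[5], v[4], v[3]), 3, 3)
  b <- v[7:9]
  ctr <- tryCatch(solve(Q, -b), error = function(e)
    stop("quadric fit is degenerate (no centre)"))
  k <- v[10] + sum(b * ctr)
  eig <- eigen(Q, symmetric = TRUE)
  r2 <- -k / eig$values
  if (any(!is.finite(r2)) || any(r2 <= 0))
    stop("algebraic fit is not an ellipsoid for these points")
  ord <- order(r2, decreasing = TRUE)
  radii <- sqrt(r2)[ord]
  axes <- eig$vectors[, ord, drop = FALSE]
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  list(center = c0 + s * ctr, radii = s * radii, axes = axes)
}

# spherical linear interpolation between unit vectors
slerp <- function(u, v, t) {
  d <- max(-1, min(1, sum(u * v)))
  w <- acos(d)
  if (w < 1e-9) return((1 - t) * u + t * v)
  (sin((1 - t) * w) * u + sin(t * w) * v) / sin(w)
}

#' Close an open mesh with an ellipsoidal cap
#'
#' Emulates closing a sock-like open surface: an ellipsoid is fitted to the
#' vertices near the single boundary loop, the opening is covered by rings
#' of new vertices lying on the fitted ellipsoid (great-circle
#' interpolation between the boundary loop and the apex over the opening,
#' in the ellipsoid's unit-sphere parameterisation), and the rings are
#' stitched with quads split along their shorter diagonal (ties broken by
#' lowest vertex index). New vertices are labelled `"cap"`.
#'
#' @param mesh an open [tri_mesh()] with exactly one boundary loop.
#' @param cap_resolution number of vertex rings between the boundary loop
#'   and the cap apex (>= 1; the apex itself is one extra vertex).
#' @param collar_rings how many edge-rings of interior vertices adjacent to
#'   the boundary participate in the ellipsoid fit. The boundary loop alone
#'   is a (near-)planar curve and does not determine a quadric; the collar
#'   makes the fit well-posed.
#' @return a closed [tri_mesh()] (Euler characteristic 2).
#' @export
cap_open_mesh <- function(mesh, cap_resolution = 3L, collar_rings = 2L) {
  cap_resolution <- as.integer(cap_resolution)
  if (cap_resolution < 1L) stop("cap_resolution must be >= 1")
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    stop("mesh is closed: nothing to cap")
  if (length(loops) > 1L)
    stop("mesh has ", length(loops), " boundary loops; cap_open_mesh ",
         "requires exactly one")
  loop <- loops[[1]]
  nb <- length(loop)
  if (nb < 3L) stop("boundary loop too short")

  fit_idx <- vertex_rings(mesh, loop, collar_rings)
  ell <- fit_ellipsoid(mesh$vertices[fit_idx, , drop = FALSE])

  to_unit <- function(X) {
    U <- sweep(X, 2, ell$center) %*% ell$axes
    U <- sweep(U, 2, ell$radii, "/")
    U / sqrt(rowSums(U^2))
  }
  from_unit <- function(U) {
    X <- sweep(U, 2, ell$radii, "*") %*% t(ell$axes)
    sweep(X, 2, ell$center, "+")
  }

  u_loop <- to_unit(mesh$vertices[loop, , drop = FALSE])
  body_dir <- colMeans(to_unit(mesh$vertices))
  body_dir <- body_dir / sqrt(sum(body_dir^2))
  pole <- -body_dir                       # opening faces away from the body

  nv0 <- nrow(mesh$vertices)
  new_u <- list()
  ring_idx <- list()
  ring_idx[[1]] <- loop                   # ring 0: the boundary loop itself
  nxt <- nv0
  for (j in seq_len(cap_resolution - 1L)) {
    t <- j / cap_resolution
    U <- t(vapply(seq_len(nb),
                  function(i) slerp(u_loop[i, ], pole, t), numeric(3)))
    new_u[[length(new_u) + 1L]] <- U
    ring_idx[[j + 1L]] <- nxt + seq_len(nb)
    nxt <- nxt + nb
  }
  apex_idx <- nxt + 1L
  new_u[[length(new_u) + 1L]] <- matrix(pole, 1, 3)

  new_v <- from_unit(do.call(rbind, new_u))
  verts <- rbind(mesh$vertices, new_v)

  tris <- list()
  # quad strips between consecutive rings (loop traversed in reverse so the
  # cap opposes the body's boundary half-edges)
  dist2 <- function(i, j) sum((verts[i, ] - verts[j, ])^2)
  for (j in seq_len(cap_resolution - 1L)) {
    a <- ring_idx[[j]]; b <- ring_idx[[j + 1L]]
    for (i in seq_len(nb)) {
      i2 <- i %% nb + 1L
      d1 <- dist2(a[i2], b[i])           # diagonal a_{i+1} -- b_i
      d2 <- dist2(a[i], b[i2])           # diagonal a_i -- b_{i+1}
      use1 <- if (abs(d1 - d2) > 1e-12 * (d1 + d2)) d1 < d2 else
        min(a[i2], b[i]) < min(a[i], b[i2])
      if (use1) {
        tris[[length(tris) + 1L]] <- c(a[i2], a[i], b[i])
        tris[[length(tris) + 1L]] <- c(a[i2], b[i], b[i2])
      } else {
        tris[[length(tris) + 1L]] <- c(a[i2], a[i], b[i2])
        tris[[length(tris) + 1L]] <- c(a[i], b[i], b[i2])
      }
    }
  }
  top <- ring_idx[[cap_resolution]]
  for (i in seq_len(nb)) {
    i2 <- i %% nb + 1L
    tris[[length(tris) + 1L]] <- c(top[i2], top[i], apex_idx)
  }

  labels <- mesh$labels
  if (is.null(labels)) labels <- rep("unlabeled", nv0)
  labels <- c(labels, rep("cap", nrow(new_v)))

  all_tris <- rbind(mesh$triangles, do.call(rbind, tris))
  out <- tri_mesh(verts, all_tris, labels = labels)
  # chi is checked on the compacted copy so that isolated vertices left
  # over from upstream clipping do not spoil the count
  if (!is_closed_mesh(out) ||
      euler_characteristic(drop_unused_vertices(out)) != 2L)
    stop("internal error: cap did not close the surface")
  out
}
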