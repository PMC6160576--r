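#' Icosphere generator
#'
#' Subdivides a regular icosahedron and projects vertices to the sphere.
#' Deterministic: vertex order depends only on `subdivisions`. Face count is
#' `20 * 4^subdivisions`.
#'
#' @param radius sphere radius (mm), > 0.
#' @param subdivisions non-negative integer subdivision depth.
#' @param center 3-vector sphere centre (mm).
#' @return a closed [tri_mesh()].
#' @export
make_icosphere <- function(radius = 1, subdivisions = 0L, center = c(0, 0, 0)) {
  if (radius <= 0) stop("radius must be positive")
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(parent = emptyenv())
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    k <- 0L
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_env[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_env[[key]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[k + 1L, ] <- c(a, ab, ca)
      nf[k + 2L, ] <- c(b, bc, ab)
      nf[k + 3L, ] <- c(cc, ca, bc)
      nf[k + 4L, ] <- c(ab, bc, ca)
      k <- k + 4L
    }
    f <- nf
  }
  tri_mesh(sweep(v * radius, 2, center, "+"), f)
}

#' Latitude-longitude ellipsoid mesh with a target vertex count
#'
#' Builds a UV-sphere (pole fans plus quad strips split into triangles)
#' scaled to the given semi-axes. Used by the scene presets because its
#' vertex count `n_rings * n_segments + 2` can hit arbitrary targets, which
#' icospheres cannot.
#'
#' @param semi_axes 3-vector of ellipsoid semi-axes (mm).
#' @param nodes_target desired vertex count (>= 6); the realised count is
#'   the closest achievable `r*s + 2`.
#' @param center 3-vector centre (mm).
#' @return a closed [tri_mesh()].
#' @export
make_ellipsoid_mesh <- function(semi_axes, nodes_target, center = c(0, 0, 0)) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  nodes_target <- as.integer(nodes_target)
  if (nodes_target < 6L) stop("nodes_target must be >= 6")
  n <- nodes_target - 2L
  # pick rings r and segments s with r*s ~ n and s ~ 1.6 r (rounder facets)
  r <- max(2L, as.integer(round(sqrt(n / 1.6))))
  best <- NULL
  for (rr in max(2L, r - 3L):(r + 3L)) {
    ss <- max(3L, as.integer(round(n / rr)))
    err <- abs(rr * ss + 2L - nodes_target)
    if (is.null(best) || err < best$err) best <- list(r = rr, s = ss, err = err)
  }
  r <- best$r; s <- best$s
  theta <- pi * seq_len(r) / (r + 1)     # colatitude of rings
  phi <- 2 * pi * (seq_len(s) - 1) / s
  v <- matrix(0, r * s + 2L, 3L)
  v[1L, ] <- c(0, 0, 1)                  # north pole
  for (i in seq_len(r))
    for (j in seq_len(s))
      v[1L + (i - 1L) * s + j, ] <-
        c(sin(theta[i]) * cos(phi[j]), sin(theta[i]) * sin(phi[j]),
          cos(theta[i]))
  v[r * s + 2L, ] <- c(0, 0, -1)         # south pole
  idx <- function(i, j) 1L + (i - 1L) * s + ((j - 1L) %% s) + 1L
  tris <- list()
  for (j in seq_len(s))                  # north fan
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(r - 1L)) {
    for (j in seq_len(s)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, cc, b)
      tris[[length(tris) + 1L]] <- c(b, cc, d)
    }
  }
  south <- r * s + 2L
  for (j in seq_len(s))                  # south fan
    tris[[length(tris) + 1L]] <- c(south, idx(r, j + 1L), idx(r, j))
  v <- sweep(v, 2, semi_axes, "*")
  tri_mesh(sweep(v, 2, center, "+"), do.call(rbind, tris))
}

#' Capped-cylinder mesh (cage-like source surface)
#'
#' A cylinder of the given radius and height with flat triangulated end
#' caps, emulating a rigid recording cage around an isolated heart.
#'
#' @param radius cylinder radius (mm).
#' @param height cylinder height (mm); the axis is z, centred on `center`.
#' @param nodes_target approximate vertex count.
#' @param center 3-vector centre (mm).
#' @return a closed [tri_mesh()].
#' @export
make_cylinder_mesh <- function(radius, height, nodes_target,
                               center = c(0, 0, 0)) {
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  n <- max(18L, as.integer(nodes_target))
  # side rings dominate; cap centres add 2 vertices
  s <- max(6L, as.integer(round(sqrt(n * 2 * pi * radius / height))))
  r <- max(2L, as.integer(round((n - 2L) / s)))
  z <- seq(-height / 2, height / 2, length.out = r)
  phi <- 2 * pi * (seq_len(s) - 1) / s
  v <- matrix(0, r * s + 2L, 3L)
  for (i in seq_len(r))
    for (j in seq_len(s))
      v[(i - 1L) * s + j, ] <- c(radius * cos(phi[j]), radius * sin(phi[j]),
                                 z[i])
  top_ctr <- r * s + 1L
  bot_ctr <- r * s + 2L
  v[top_ctr, ] <- c(0, 0, height / 2)
  v[bot_ctr, ] <- c(0, 0, -height / 2)
  idx <- function(i, j) (i - 1L) * s + ((j - 1L) %% s) + 1L
  tris <- list()
  for (i in seq_len(r - 1L)) {
    for (j in seq_len(s)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, b, cc)
      tris[[length(tris) + 1L]] <- c(b, d, cc)
    }
  }
  for (j in seq_len(s)) {
    tris[[length(tris) + 1L]] <- c(top_ctr, idx(r, j), idx(r, j + 1L))
    tris[[length(tris) + 1L]] <- c(bot_ctr, idx(1L, j + 1L), idx(1L, j))
  }
  tri_mesh(sweep(v, 2, center, "+"), do.call(rbind, tris))
}

#' Planar uniform grid patch
#'
#' An open rectangular grid of right triangles in the z = 0 plane; the
#' standard substrate for checking the linear precision of cotangent
#' Laplacian weights.
#'
#' @param nx,ny number of vertices along x and y (>= 2).
#' @param spacing grid spacing (mm).
#' @return an open [tri_mesh()].
#' @export
make_grid_patch <- function(nx = 10L, ny = 10L, spacing = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  g <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, b, cc)
      tris[[length(tris) + 1L]] <- c(b, d, cc)
    }
  }
  tri_mesh(v, do.call(rbind, tris))
}

# interior (non-boundary) vertex indices of an open mesh
interior_vertices <- function(mesh) {
  he <- mesh_half_edges(mesh)
  keys <- edge_keys(he)
  cnt <- table(keys)
  bkeys <- names(cnt)[cnt == 1L]
  bverts <- unique(as.vector(he[keys %in% bkeys, ]))
  setdiff(seq_len(nrow(mesh$vertices)), bverts)
}
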