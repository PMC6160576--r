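# Shared fixtures, built in code. Everything is deterministic.

# smallest closed mesh: regular tetrahedron, outward orientation
make_tetra <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    edge / (2 * sqrt(2))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_mesh(v, f)
}

# icosphere with triangles whose centroid z >= zcut removed (open mesh),
# unused vertices dropped
make_clipped_sphere <- function(subdiv = 3, zcut = 0.45, radius = 1) {
  ico <- make_icosphere(radius, subdiv)
  ctr <- (ico$vertices[ico$triangles[, 1], ] +
            ico$vertices[ico$triangles[, 2], ] +
            ico$vertices[ico$triangles[, 3], ]) / 3
  drop_unused_vertices(tri_mesh(ico$vertices,
                                ico$triangles[ctr[, 3] < zcut * radius, ]))
}

# deterministic small random-ish mesh: jittered clipped sphere
make_random_mesh <- function(seed) {
  set.seed(seed)
  m <- make_clipped_sphere(2, runif(1, 0.2, 0.8))
  m$vertices <- m$vertices + matrix(rnorm(length(m$vertices), sd = 0.02),
                                    ncol = 3)
  validate_mesh(m)
  m
}

# memoised default scene + transfer matrix (expensive; shared within a
# test file)
.fixture_env <- new.env(parent = emptyenv())
default_scene <- function() {
  if (is.null(.fixture_env$scene)) .fixture_env$scene <- make_scene()
  .fixture_env$scene
}
default_transfer <- function() {
  if (is.null(.fixture_env$transfer))
    .fixture_env$transfer <- assemble_transfer(default_scene())
  .fixture_env$transfer
}

# brute-force census of boundary edges (independent of boundary_loops)
count_boundary_edges <- function(mesh) {
  tr <- mesh$triangles
  he <- cbind(c(tr[, 1], tr[, 2], tr[, 3]), c(tr[, 2], tr[, 3], tr[, 1]))
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  sum(table(key) == 1L)
}
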