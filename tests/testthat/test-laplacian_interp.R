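test_that("inverse-distance Laplacian on a tetrahedron matches hand assembly", {
  tet <- make_tetra(edge = 2)
  lap <- build_laplacian(tet, "inverse_distance")
  L <- as.matrix(lap$L)
  w <- 1 / 2                       # all six edges have length 2
  off <- L[upper.tri(L)]
  expect_equal(off, rep(w, 6), tolerance = 1e-12)
  expect_equal(diag(L), rep(-3 * w, 4), tolerance = 1e-12)
  expect_equal(L, t(L), tolerance = 1e-14)
})

test_that("Laplacian rows sum to zero and match edge adjacency", {
  for (mesh in list(make_icosphere(1, 2), default_scene()$heart,
                    make_grid_patch(7, 5))) {
    for (scheme in c("cotangent", "inverse_distance")) {
      lap <- build_laplacian(mesh, scheme)
      expect_lt(max(abs(Matrix::rowSums(lap$L))), 1e-12)
      expect_equal(as.matrix(lap$L), t(as.matrix(lap$L)),
                   tolerance = 1e-14)
      if (scheme == "inverse_distance") {
        offd <- as.matrix(lap$L)
        diag(offd) <- 0
        expect_true(all(offd[offd != 0] > 0))
      }
    }
  }
})

test_that("cotangent weights have linear precision on a planar patch", {
  patch <- make_grid_patch(9, 9, spacing = 0.7)
  lap <- build_laplacian(patch, "cotangent")
  lin <- 2 * patch$vertices[, 1] + 3 * patch$vertices[, 2] + 1
  resid <- as.vector(lap$L %*% lin)
  interior <- ecgfwd:::interior_vertices(patch)
  expect_lt(max(abs(resid[interior])), 1e-10)
})

test_that("interpolation is exact on known nodes and idempotent", {
  mesh <- make_icosphere(1, 2)
  lap <- build_laplacian(mesh)
  vals <- sin(mesh$vertices[, 1]) + mesh$vertices[, 3]^2
  expect_identical(interpolate_potentials(lap, seq_len(lap$n), vals), vals)
  known <- seq(1, lap$n, by = 3)
  out <- interpolate_potentials(lap, known, vals[known])
  expect_identical(out[known], vals[known])
})

test_that("a single unknown node gets the weighted mean of its neighbours", {
  mesh <- make_icosphere(1, 1)
  lap <- build_laplacian(mesh, "inverse_distance")
  unknown <- 7L
  known <- setdiff(seq_len(lap$n), unknown)
  vals <- cos(mesh$vertices[, 2]) + mesh$vertices[, 1]
  out <- interpolate_potentials(lap, known, vals[known])
  # one-row solve by hand: L_uu phi_u = -L_uk phi_k
  L <- as.matrix(lap$L)
  expected <- -sum(L[unknown, known] * vals[known]) / L[unknown, unknown]
  expect_equal(out[unknown], expected, tolerance = 1e-12)
  # equivalently, the inverse-distance-weighted mean of the neighbours
  w <- L[unknown, known]
  expect_equal(out[unknown], sum(w * vals[known]) / sum(w),
               tolerance = 1e-12)
})

test_that("harmonic interpolation recovers a linear field from the boundary", {
  patch <- make_grid_patch(9, 9, spacing = 1)
  lap <- build_laplacian(patch, "cotangent")
  f <- 2 * patch$vertices[, 1] + 3 * patch$vertices[, 2]
  interior <- ecgfwd:::interior_vertices(patch)
  known <- setdiff(seq_len(lap$n), interior)
  out <- interpolate_potentials(lap, known, f[known])
  expect_lt(max(abs(out[interior] - f[interior])), 1e-9)
})

test_that("inverse-distance interpolation obeys the maximum principle", {
  mesh <- make_icosphere(1, 2)
  lap <- build_laplacian(mesh, "inverse_distance")
  set.seed(42)
  for (rep in 1:100) {
    known <- sample(lap$n, sample(5:(lap$n - 5), 1))
    vals <- rnorm(length(known))
    out <- interpolate_potentials(lap, known, vals)
    expect_true(all(out >= min(vals) - 1e-10 & out <= max(vals) + 1e-10))
  }
})

test_that("frame-wise interpolation equals per-frame solves", {
  sc <- default_scene()
  lap <- build_laplacian(sc$heart)
  fs <- generate_frames(sc, n_frames = 5, seed = 2)
  known <- sort(ventricular_indices(sc))
  all_at_once <- interpolate_frames(lap, known, fs)
  for (f in seq_len(5)) {
    single <- interpolate_potentials(lap, known, fs$values[known, f])
    expect_equal(all_at_once$values[, f], single, tolerance = 1e-10)
  }
})

test_that("degenerate known sets are rejected with useful errors", {
  mesh <- make_icosphere(1, 1)
  lap <- build_laplacian(mesh)
  expect_error(interpolate_potentials(lap, integer(0), numeric(0)),
               "non-empty")
  # two disconnected triangles; knowns only touch the first component
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 5, 5), c(6, 5, 5), c(5, 6, 5))
  m2 <- tri_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  lap2 <- build_laplacian(m2, "inverse_distance")
  expect_error(interpolate_potentials(lap2, c(1L, 2L), c(0, 1)),
               "no measured neighbour")
})
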