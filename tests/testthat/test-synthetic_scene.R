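test_that("icosphere has the predicted combinatorics and geometry", {
  ico0 <- make_icosphere(1, 0)
  expect_identical(n_vertices(ico0), 12L)
  expect_identical(n_triangles(ico0), 20L)
  ico2 <- make_icosphere(2, 2)
  expect_identical(n_triangles(ico2), 320L)          # 20 * 4^2
  expect_identical(euler_characteristic(ico2), 2L)
  expect_true(is_closed_mesh(ico2))
  expect_lt(max(abs(sqrt(rowSums(ico2$vertices^2)) - 2)), 1e-9)
  ico3 <- make_icosphere(10, 3)
  expect_lt(abs(sum(triangle_areas(ico3)) - 4 * pi * 100) / (4 * pi * 100),
            0.03)
  expect_error(make_icosphere(-1, 2), "positive")
})

test_that("scene presets meet their size, label and containment contracts", {
  sc <- default_scene()
  expect_lt(abs(n_vertices(sc$heart) - 500) / 500, 0.10)
  expect_lt(abs(n_vertices(sc$torso) - 770) / 770, 0.10)
  frac <- mean(sc$heart$labels == "atrial")
  expect_true(abs(frac - 0.25) < 0.05)
  # labels partition the heart vertices
  expect_setequal(union(atrial_indices(sc), ventricular_indices(sc)),
                  seq_len(n_vertices(sc$heart)))
  # every heart vertex strictly inside the ellipsoidal torso
  q <- sweep(sc$heart$vertices, 2, c(180, 110, 200), "/")
  expect_true(all(rowSums(q^2) < 1))
  # atrial nodes all sit above the AV plane, ventricular at or below
  expect_true(all(sc$heart$vertices[atrial_indices(sc), 3] >
                    sc$av_plane_z))
  expect_true(all(sc$heart$vertices[ventricular_indices(sc), 3] <=
                    sc$av_plane_z))
  cage <- make_scene("cage_like", 600, 770)
  expect_true(is_closed_mesh(cage$heart))
  expect_identical(euler_characteristic(cage$heart), 2L)
  expect_error(make_scene(heart_nodes_target = 20), ">= 50")
})

test_that("dipole potential matches the closed form and is linear", {
  # unit moment along z, field point (0,0,1), sigma = 1: 1/(4*pi)
  expect_equal(dipole_potential(c(0, 0, 0), c(0, 0, 1),
                                c(0, 0, 1), conductivity = 1),
               1 / (4 * pi), tolerance = 1e-12)
  # any point in the z = 0 plane is on the dipole's null plane
  pts <- cbind(rnorm(20), rnorm(20), 0)
  expect_lt(max(abs(dipole_potential(c(0, 0, 0), c(0, 0, 1), pts))), 1e-12)
  pts2 <- matrix(rnorm(30), ncol = 3) + 2
  expect_equal(dipole_potential(c(0, 0, 0), c(2, -4, 6), pts2),
               2 * dipole_potential(c(0, 0, 0), c(1, -2, 3), pts2),
               tolerance = 1e-12)
  expect_error(dipole_potential(c(1, 1, 1), c(0, 0, 1), c(1, 1, 1)),
               "coincides")
})

test_that("generate_frames is seed-deterministic and dipole-consistent", {
  sc <- default_scene()
  f1 <- generate_frames(sc, n_frames = 6, seed = 11)
  f2 <- generate_frames(sc, n_frames = 6, seed = 11)
  expect_identical(f1$values, f2$values)
  f3 <- generate_frames(sc, n_frames = 6, seed = 12)
  expect_false(identical(f1$values, f3$values))
  expect_equal(max(abs(f1$values)), 30, tolerance = 1e-9)
  # brute-force oracle: re-evaluate the declared dipole sum per vertex
  dips <- attr(f1, "dipoles")
  for (f in c(1L, 4L, 6L)) {
    ref <- rowSums(vapply(dips[[f]], function(d)
      dipole_potential(d$position, d$moment, sc$heart$vertices,
                       sc$conductivity),
      numeric(n_vertices(sc$heart))))
    expect_equal(f1$values[, f], ref, tolerance = 1e-12)
  }
  expect_error(generate_frames(sc, n_frames = 1), ">= 2")
})

test_that("frame sets round-trip through the delimited format", {
  sc <- default_scene()
  fs <- generate_frames(sc, n_frames = 4, seed = 3)
  path <- file.path(withr::local_tempdir(), "frames.csv")
  save_frames(fs, path)
  back <- load_frames(path)
  expect_equal(back$values, fs$values, tolerance = 1e-12)
  expect_identical(back$mesh_id, fs$mesh_id)
  expect_identical(back$units, "mV")
})

test_that("shell solution satisfies both boundary conditions", {
  s0 <- shell_solution(0, 0, 50, 100)
  expect_equal(s0$A, 1, tolerance = 1e-14)
  expect_equal(s0$B, 0, tolerance = 1e-14)
  # l=1: independent check of the stated 2x2 system by direct substitution
  s1 <- shell_solution(1, 0, 1, 2)
  expect_equal(s1$A * 1 + s1$B * 1, 1, tolerance = 1e-12)
  expect_equal(1 * s1$A * 2^0 - 2 * s1$B * 2^-3, 0, tolerance = 1e-12)
  set.seed(5)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (l in 0:3) {
    for (m in c(-l, 0, l)) {
      sol <- shell_solution(l, m, 50, 100)
      ylm <- real_sph_harm(l, m, dirs)
      # Dirichlet at R1
      expect_lt(max(abs(eval_shell(sol, dirs * 50) - ylm)), 1e-12)
      # insulated outer boundary: radial derivative at R2 ~ 0 (central
      # difference as the independent oracle)
      h <- 1e-4
      dr <- (eval_shell(sol, dirs * (100 + h)) -
               eval_shell(sol, dirs * (100 - h))) / (2 * h)
      expect_lt(max(abs(dr)), 1e-10)
    }
  }
  expect_error(shell_solution(1, 0, 100, 50), "R1 < R2")
})

test_that("real spherical harmonics are orthonormal on the sphere", {
  # Monte-Carlo inner products as an independent sanity check
  set.seed(9)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  basis <- list(c(1, 0), c(1, 1), c(2, -1), c(3, 2))
  for (i in seq_along(basis)) {
    yi <- real_sph_harm(basis[[i]][1], basis[[i]][2], u)
    expect_equal(mean(yi^2) * 4 * pi, 1, tolerance = 0.05)
    for (j in seq_len(i - 1)) {
      yj <- real_sph_harm(basis[[j]][1], basis[[j]][2], u)
      expect_lt(abs(mean(yi * yj) * 4 * pi), 0.05)
    }
  }
})
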