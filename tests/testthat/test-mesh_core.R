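test_that("tetrahedron round-trips through every format with labels", {
  tet <- make_tetra()
  tet$labels <- c("ventricular", "ventricular", "atrial", "cap")
  expect_true(is_closed_mesh(tet))
  expect_identical(euler_characteristic(tet), 2L)
  for (fmt in c("ptsfac", "off", "ply")) {
    stem <- file.path(withr::local_tempdir(), paste0("tet_", fmt))
    path <- switch(fmt, ptsfac = paste0(stem, ".pts"),
                   paste0(stem, ".", fmt))
    save_mesh(tet, path, fmt)
    back <- load_mesh(path, fmt)
    expect_identical(back$triangles, tet$triangles, info = fmt)
    expect_lt(max(abs(back$vertices - tet$vertices)), 1e-8)
    expect_identical(back$labels, tet$labels, info = fmt)
  }
})

test_that("load/save round trip is the identity on random small meshes", {
  for (seed in 1:4) {
    m <- make_random_mesh(seed)
    for (fmt in c("ptsfac", "off", "ply")) {
      path <- file.path(withr::local_tempdir(),
                        switch(fmt, ptsfac = "m.pts", paste0("m.", fmt)))
      save_mesh(m, path, fmt)
      back <- load_mesh(path, fmt)
      expect_identical(back$triangles, m$triangles)
      expect_lt(max(abs(back$vertices - m$vertices)),
                1e-8 * max(abs(m$vertices)))
    }
  }
})

test_that("loader rejects malformed input with located errors", {
  d <- withr::local_tempdir()
  # 4-vertex .pts, .fac referencing vertex 5
  writeLines(c("0 0 0", "1 0 0", "0 1 0", "0 0 1"),
             file.path(d, "bad.pts"))
  writeLines(c("1 2 3", "1 2 5"), file.path(d, "bad.fac"))
  expect_error(load_mesh(file.path(d, "bad.pts")), "index out of range")
  writeLines(c("OFF", "2 1 0", "0 0 0", "1 oops 0", "3 0 1 2"),
             file.path(d, "bad.off"))
  expect_error(load_mesh(file.path(d, "bad.off")), "bad.off:4")
  expect_error(load_mesh(file.path(d, "absent.ply")), "not found")
  empty <- tri_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 3))
  expect_error(save_mesh(empty, file.path(d, "e.off")), "empty")
})

test_that("mesh validation catches the contract violations", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(tri_mesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "repeats a vertex")
  expect_error(tri_mesh(rbind(v, c(2, 0, 0)),
                        rbind(c(1, 2, 3), c(1, 2, 5))),
               "zero area|orientation")
  # same winding on a shared edge -> inconsistent orientation
  expect_error(tri_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4))),
               "orientation")
  # an edge used by three triangles -> non-manifold
  v5 <- rbind(v, c(1, 1, 1))
  expect_error(tri_mesh(v5, rbind(c(1, 2, 3), c(2, 1, 4), c(1, 2, 5))),
               "orientation|non-manifold")
})

test_that("boundary loop census matches a brute-force edge count", {
  expect_identical(boundary_loops(make_icosphere(1, 2)), list())
  clipped <- make_clipped_sphere(3, 0.45)
  loops <- boundary_loops(clipped)
  expect_length(loops, 1L)
  # every loop vertex sits within an edge length of the cut plane
  edge_len <- max(sqrt(rowSums((clipped$vertices[clipped$triangles[, 1], ] -
                  clipped$vertices[clipped$triangles[, 2], ])^2)))
  expect_true(all(abs(clipped$vertices[loops[[1]], 3] - 0.45) < edge_len))
  # loop vertex count equals the boundary edge census
  expect_identical(length(loops[[1]]), count_boundary_edges(clipped))
  # two holes -> two loops, total loop vertices = boundary edges
  ico <- make_icosphere(1, 3)
  ctr <- (ico$vertices[ico$triangles[, 1], ] +
            ico$vertices[ico$triangles[, 2], ] +
            ico$vertices[ico$triangles[, 3], ]) / 3
  two <- drop_unused_vertices(
    tri_mesh(ico$vertices, ico$triangles[abs(ctr[, 3]) < 0.6, ]))
  loops2 <- boundary_loops(two)
  expect_length(loops2, 2L)
  expect_identical(sum(lengths(loops2)), count_boundary_edges(two))
  # consecutive loop vertices share a boundary edge by construction
  l1 <- loops2[[1]]
  pairs <- cbind(l1, c(l1[-1], l1[1]))
  keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  he <- mesh_half_edges <- cbind(c(two$triangles[, 1], two$triangles[, 2],
                                   two$triangles[, 3]),
                                 c(two$triangles[, 2], two$triangles[, 3],
                                   two$triangles[, 1]))
  all_keys <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  expect_true(all(keys %in% names(which(table(all_keys) == 1L))))
})

test_that("ellipsoidal cap closes a hemisphere onto the unit sphere", {
  hemi <- make_clipped_sphere(3, 0.45)
  capped <- cap_open_mesh(hemi, cap_resolution = 3)
  expect_true(is_closed_mesh(capped))
  expect_identical(euler_characteristic(capped), 2L)
  expect_identical(boundary_loops(capped), list())
  cap_idx <- which(capped$labels == "cap")
  expect_gt(length(cap_idx), 0L)
  radii <- sqrt(rowSums(capped$vertices[cap_idx, , drop = FALSE]^2))
  expect_true(all(abs(radii - 1) < 0.05))   # on the recovered sphere
  # capping a closed mesh is a precondition error
  expect_error(cap_open_mesh(make_icosphere(1, 1)), "closed")
  # two boundary loops is a precondition error
  ico <- make_icosphere(1, 3)
  ctr <- (ico$vertices[ico$triangles[, 1], ] +
            ico$vertices[ico$triangles[, 2], ] +
            ico$vertices[ico$triangles[, 3], ]) / 3
  two <- drop_unused_vertices(
    tri_mesh(ico$vertices, ico$triangles[abs(ctr[, 3]) < 0.6, ]))
  expect_error(cap_open_mesh(two), "2 boundary loops")
})

test_that("cap output passes the closed-mesh validator at any resolution", {
  for (res in c(1L, 2L, 5L)) {
    capped <- cap_open_mesh(make_clipped_sphere(2, 0.3), res)
    expect_true(is_closed_mesh(capped))
    expect_identical(euler_characteristic(capped), 2L)
  }
})

test_that("ellipsoid fit recovers known ellipsoids", {
  set.seed(7)
  radii <- c(30, 22, 41)
  u <- matrix(rnorm(600), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u, 2, radii, "*")
  pts <- sweep(pts, 2, c(5, -3, 10), "+")
  fit <- fit_ellipsoid(pts)
  expect_lt(max(abs(fit$center - c(5, -3, 10))), 1e-6)
  expect_lt(max(abs(sort(fit$radii) - sort(radii))), 1e-6)
})
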