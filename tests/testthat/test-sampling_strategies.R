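plans_of <- function(scene, n_it = 7L, seed = 1L) {
  list(av_first = plan_av_first(scene, n_it),
       roof_first = plan_roof_first(scene, n_it),
       combined = plan_combined(scene, n_it),
       uniform = plan_uniform(scene, n_it, seed),
       random = plan_random(scene, n_it, seed))
}

test_that("additive plans share endpoints, nest, and balance their bands", {
  sc <- default_scene()
  vent <- sort(ventricular_indices(sc))
  full <- seq_len(n_vertices(sc$heart))
  for (p in plans_of(sc)) {
    expect_identical(p$iterations[[1]], vent)
    expect_identical(p$iterations[[length(p$iterations)]], full)
    sizes <- diff(lengths(p$iterations))
    expect_lte(max(sizes) - min(sizes), 1L)
    for (i in seq_len(length(p$iterations) - 1L))
      expect_true(all(p$iterations[[i]] %in% p$iterations[[i + 1L]]),
                  info = p$strategy)
  }
})

test_that("av_first and roof_first order bands along the long axis", {
  sc <- default_scene()
  z <- as.vector(sc$heart$vertices %*% sc$long_axis)
  av <- plan_av_first(sc, 5)
  added_first <- setdiff(av$iterations[[2]], av$iterations[[1]])
  added_last <- setdiff(av$iterations[[6]], av$iterations[[5]])
  expect_lte(max(z[added_first]), min(z[added_last]))
  roof <- plan_roof_first(sc, 5)
  r1 <- setdiff(roof$iterations[[2]], roof$iterations[[1]])
  atr <- atrial_indices(sc)
  expect_true(atr[which.max(z[atr])] %in% r1)   # global roof node first
  # reversal duality when band sizes divide evenly
  n_atr <- length(atr)
  div <- max(which(n_atr %% seq_len(6) == 0))
  if (div >= 2) {
    a <- plan_av_first(sc, div)
    r <- plan_roof_first(sc, div)
    for (k in seq_len(div)) {
      band_a <- setdiff(a$iterations[[k + 1]], a$iterations[[k]])
      band_r <- setdiff(r$iterations[[div - k + 2]],
                        r$iterations[[div - k + 1]])
      expect_setequal(band_a, band_r)
    }
  }
})

test_that("combined draws half from each end of the av_first ordering", {
  sc <- default_scene()
  z <- as.vector(sc$heart$vertices %*% sc$long_axis)
  atr <- atrial_indices(sc)
  av_order <- atr[order(z[atr], atr)]
  comb <- plan_combined(sc, 4)
  sz <- length(setdiff(comb$iterations[[2]], comb$iterations[[1]]))
  from_av <- ceiling(sz / 2)
  expected <- c(av_order[seq_len(from_av)],
                rev(av_order)[seq_len(sz - from_av)])
  expect_setequal(setdiff(comb$iterations[[2]], comb$iterations[[1]]),
                  expected)
})

test_that("uniform plan is farthest-point sampling", {
  sc <- default_scene()
  atr <- atrial_indices(sc)
  P <- sc$heart$vertices[atr, , drop = FALSE]
  u <- plan_uniform(sc, 7)
  ord <- match(attr(u, "atrial_order"), atr)   # FPS selection order
  # seed point: atrial node nearest the atrial centroid (brute force)
  ctr <- colMeans(P)
  expect_identical(ord[1], which.min(rowSums(sweep(P, 2, ctr)^2)))
  # second selected point is the farthest from the first (brute force)
  d_from_first <- sqrt(rowSums(sweep(P, 2, P[ord[1], ])^2))
  expect_equal(d_from_first[ord[2]], max(d_from_first), tolerance = 1e-12)
  expect_identical(plan_uniform(sc, 7)$iterations, u$iterations)
  # min pairwise distance among first k selections is non-increasing
  mind <- sapply(2:15, function(k) min(dist(P[ord[seq_len(k)], ])))
  expect_true(all(diff(mind) <= 1e-12))
})

test_that("random plans are seeded permutations of the atria", {
  sc <- default_scene()
  atr <- atrial_indices(sc)
  p1 <- plan_random(sc, 7, seed = 4)
  expect_identical(plan_random(sc, 7, seed = 4)$iterations, p1$iterations)
  others <- vapply(5:9, function(s)
    identical(plan_random(sc, 7, seed = s)$iterations, p1$iterations),
    logical(1))
  expect_false(any(others))
  added <- setdiff(p1$iterations[[8]], p1$iterations[[1]])
  expect_setequal(added, atr)
})

test_that("plaque clusters match an exhaustive distance sort", {
  sc <- default_scene()
  atr <- atrial_indices(sc)
  ctr <- colMeans(sc$heart$vertices[atr, , drop = FALSE])
  expect_length(plaque_cluster(sc, ctr, 1), 1L)
  expect_setequal(plaque_cluster(sc, ctr, length(atr)), atr)
  k <- 12
  got <- plaque_cluster(sc, ctr, k)
  d <- sqrt(rowSums(sweep(sc$heart$vertices[atr, , drop = FALSE], 2,
                          ctr)^2))
  expect_setequal(got, atr[order(d, atr)][seq_len(k)])
  expect_error(plaque_cluster(sc, ctr, 0), "k must be")
  expect_error(plaque_cluster(sc, ctr, length(atr) + 1), "k must be")
})

test_that("basal removal peels the ventricular base in nested bands", {
  sc <- default_scene()
  vent <- ventricular_indices(sc)
  z <- as.vector(sc$heart$vertices %*% sc$long_axis)
  p <- plan_basal_removal(sc, 6)
  expect_identical(p$iterations[[1]], sort(vent))
  removed1 <- setdiff(p$iterations[[1]], p$iterations[[2]])
  expect_true(vent[which.max(z[vent])] %in% removed1)
  sizes <- -diff(lengths(p$iterations))
  expect_true(all(sizes > 0))
  expect_lte(max(sizes) - min(sizes), 1L)
  for (i in seq_len(6))
    expect_true(all(p$iterations[[i + 1]] %in% p$iterations[[i]]))
  # with atria included, iteration 0 is the full surface
  pa <- plan_basal_removal(sc, 3, include_atria = TRUE)
  expect_identical(pa$iterations[[1]], seq_len(n_vertices(sc$heart)))
})

test_that("plans serialize to JSON and back", {
  sc <- default_scene()
  p <- plan_combined(sc, 5)
  path <- file.path(withr::local_tempdir(), "plan.json")
  save_plan(p, path)
  back <- load_plan(path)
  expect_identical(back$iterations, p$iterations)
  expect_identical(back$strategy, p$strategy)
})
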