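#' Incremental cardiac source sampling plans
#'
#' A `sampling_plan` is an ordered list of cumulative measured-node index
#' sets over the source surface. The five additive strategies all start
#' from the ventricle-only baseline (iteration 0, emulating a sock
#' electrode array that leaves the atria unsampled) and add atrial nodes in
#' `n_iterations` near-equal bands until the whole surface is measured, so
#' every additive plan shares both endpoints. The basal-removal plan runs
#' the other way: it starts from full ventricular sampling and removes
#' ventricular bands from the base downward.
#'
#' Strategies:
#' \describe{
#'   \item{`av_first`}{atrial bands ordered by increasing long-axis
#'     distance from the AV plane (AV plane outward to the roof).}
#'   \item{`roof_first`}{the reverse: from the atrial roof down to the AV
#'     plane.}
#'   \item{`combined`}{each iteration draws half its quota from the
#'     AV-plane end and half from the roof end (odd quota: the extra node
#'     goes to the AV end).}
#'   \item{`uniform`}{farthest-point sampling over Euclidean distance,
#'     seeded at the atrial node nearest the atrial centroid - the standard
#'     deterministic realisation of "uniformly distributed" sites.}
#'   \item{`random`}{a seeded uniform random permutation of the atrial
#'     nodes, chunked into bands.}
#' }
#' Ties are always broken by lowest vertex index.
#'
#' @param scene a [make_scene()] object with atrial labels.
#' @param n_iterations number of atrial additions (>= 1); the plan has
#'   `n_iterations + 1` entries including the baseline.
#' @param seed integer seed (used by `plan_random`; accepted and recorded
#'   by `plan_uniform` for interface symmetry, whose construction is
#'   deterministic).
#' @return an object of class `sampling_plan`: fields `strategy`,
#'   `iterations` (list of integer vectors, cumulative), `seed`,
#'   `source_mesh_id`.
#' @name sampling_plans
NULL

new_plan <- function(strategy, iterations, scene, seed = NA_integer_) {
  structure(list(strategy = strategy, iterations = iterations,
                 seed = seed,
                 source_mesh_id = mesh_id_of(scene$heart, "heart")),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  sizes <- vapply(x$iterations, length, integer(1))
  cat(sprintf("sampling_plan '%s': %d iterations, measured set sizes %s\n",
              x$strategy, length(x$iterations) - 1L,
              paste(sizes, collapse = " -> ")))
  invisible(x)
}

# split n items into k bands whose sizes differ by at most one
band_sizes <- function(n, k) {
  sz <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sz[seq_len(r)] <- sz[seq_len(r)] + 1L
  sz
}

additive_plan <- function(strategy, scene, ordered_atrial, n_iterations,
                          seed = NA_integer_) {
  vent <- ventricular_indices(scene)
  sz <- band_sizes(length(ordered_atrial), n_iterations)
  iters <- vector("list", n_iterations + 1L)
  iters[[1]] <- sort(vent)
  taken <- integer(0)
  pos <- 0L
  for (i in seq_len(n_iterations)) {
    taken <- c(taken, ordered_atrial[pos + seq_len(sz[i])])
    pos <- pos + sz[i]
    iters[[i + 1L]] <- sort(c(vent, taken))
  }
  out <- new_plan(strategy, iters, scene, seed)
  attr(out, "atrial_order") <- ordered_atrial
  out
}

check_atria <- function(scene, n_iterations) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (!length(atrial_indices(scene)))
    stop("scene has no atrial nodes")
}

#' @rdname sampling_plans
#' @export
plan_av_first <- function(scene, n_iterations = 7L) {
  check_atria(scene, n_iterations)
  atr <- atrial_indices(scene)
  z <- long_axis_coord(scene, atr)
  additive_plan("av_first", scene, atr[order(z, atr)], n_iterations)
}

#' @rdname sampling_plans
#' @export
plan_roof_first <- function(scene, n_iterations = 7L) {
  check_atria(scene, n_iterations)
  atr <- atrial_indices(scene)
  z <- long_axis_coord(scene, atr)
  # exact reverse of the av_first ordering, so the two plans are duals
  # band-for-band whenever the band sizes divide evenly
  additive_plan("roof_first", scene, rev(atr[order(z, atr)]), n_iterations)
}

#' @rdname sampling_plans
#' @export
plan_combined <- function(scene, n_iterations = 7L) {
  check_atria(scene, n_iterations)
  atr <- atrial_indices(scene)
  z <- long_axis_coord(scene, atr)
  av_order <- atr[order(z, atr)]
  sz <- band_sizes(length(atr), n_iterations)
  lo <- 1L; hi <- length(av_order)
  ordered <- integer(0)
  for (i in seq_len(n_iterations)) {
    from_av <- ceiling(sz[i] / 2)
    from_roof <- sz[i] - from_av
    if (from_av > 0) {
      ordered <- c(ordered, av_order[lo:(lo + from_av - 1L)])
      lo <- lo + from_av
    }
    if (from_roof > 0) {
      ordered <- c(ordered, av_order[hi:(hi - from_roof + 1L)])
      hi <- hi - from_roof
    }
  }
  additive_plan("combined", scene, ordered, n_iterations)
}

# farthest-point sampling order over Euclidean distance, ties by index
fps_order <- function(pts, start) {
  n <- nrow(pts)
  sel <- integer(n)
  sel[1] <- start
  mind <- sqrt(rowSums(sweep(pts, 2, pts[start, ])^2))
  for (k in 2:n) {
    nxt <- which.max(mind)          # which.max takes the lowest tied index
    sel[k] <- nxt
    d <- sqrt(rowSums(sweep(pts, 2, pts[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  sel
}

#' @rdname sampling_plans
#' @export
plan_uniform <- function(scene, n_iterations = 7L, seed = 1L) {
  check_atria(scene, n_iterations)
  atr <- atrial_indices(scene)
  P <- scene$heart$vertices[atr, , drop = FALSE]
  ctr <- colMeans(P)
  start <- which.min(rowSums(sweep(P, 2, ctr)^2))
  ord <- fps_order(P, start)
  additive_plan("uniform", scene, atr[ord], n_iterations, seed)
}

#' @rdname sampling_plans
#' @export
plan_random <- function(scene, n_iterations = 7L, seed = 1L) {
  check_atria(scene, n_iterations)
  atr <- atrial_indices(scene)
  perm <- local({
    set.seed(as.integer(seed))
    sample(atr, length(atr))
  })
  additive_plan("random", scene, perm, n_iterations, seed)
}

#' Plaque electrode cluster
#'
#' The `k` atrial nodes nearest (Euclidean) to a centre point, emulating a
#' small rigid plaque electrode array pressed onto an accessible atrial
#' region. Ties are broken by lowest vertex index.
#'
#' @param scene a [make_scene()] object.
#' @param center 3-vector (mm), on or near the atrial surface.
#' @param k cluster size, `1 <= k <=` number of atrial nodes.
#' @return integer vector of source vertex indices (sorted).
#' @export
plaque_cluster <- function(scene, center, k) {
  atr <- atrial_indices(scene)
  k <- as.integer(k)
  if (k < 1L || k > length(atr))
    stop("k must be in 1..", length(atr))
  d <- sqrt(rowSums(sweep(scene$heart$vertices[atr, , drop = FALSE], 2,
                          center)^2))
  sort(atr[order(d, atr)][seq_len(k)])
}

#' Incremental basal-ventricular removal plan
#'
#' Starts from full ventricular sampling (iteration 0) and removes
#' ventricular nodes in `n_iterations` near-equal bands of decreasing
#' long-axis coordinate (the base of the ventricles first), down to a
#' total removal of `removal_fraction` of the ventricular nodes. The
#' atria are unmeasured by default (sock-like) or fully measured with
#' `include_atria = TRUE`.
#'
#' @param scene a [make_scene()] object.
#' @param n_iterations number of removal steps (>= 1).
#' @param removal_fraction fraction of ventricular nodes removed in total.
#' @param include_atria keep the atrial set measured throughout.
#' @return a `sampling_plan` with strictly decreasing measured sets.
#' @export
plan_basal_removal <- function(scene, n_iterations = 6L,
                               removal_fraction = 0.45,
                               include_atria = FALSE) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  vent <- ventricular_indices(scene)
  if (!length(vent)) stop("scene has no ventricular nodes")
  z <- long_axis_coord(scene, vent)
  basal_order <- vent[order(-z, vent)]          # base first
  n_remove <- floor(removal_fraction * length(vent))
  sz <- band_sizes(n_remove, n_iterations)
  base_set <- if (include_atria) sort(c(vent, atrial_indices(scene)))
              else sort(vent)
  iters <- vector("list", n_iterations + 1L)
  iters[[1]] <- base_set
  removed <- integer(0)
  pos <- 0L
  for (i in seq_len(n_iterations)) {
    removed <- c(removed, basal_order[pos + seq_len(sz[i])])
    pos <- pos + sz[i]
    iters[[i + 1L]] <- setdiff(base_set, removed)
  }
  new_plan("basal_removal", iters, scene)
}

#' Serialize / load a sampling plan as JSON
#' @param plan a `sampling_plan`.
#' @param path file path.
#' @return `save_plan`: `path` invisibly; `load_plan`: a `sampling_plan`.
#' @export
save_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_plan
#' @export
load_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$iterations <- lapply(x$iterations, as.integer)
  structure(x[c("strategy", "iterations", "seed", "source_mesh_id")],
            class = "sampling_plan")
}
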