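`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment configuration
#'
#' Bundles every knob of the sampling-ablation experiment so a run is a
#' pure function of its configuration. Seeds are split by role: the frame
#' seed drives the dipole sources, the strategy seed the random sampling
#' order; scene geometry is deterministic given the preset and sizes.
#'
#' @param preset scene preset, `"sock_like"` or `"cage_like"`.
#' @param heart_nodes,torso_nodes target vertex counts.
#' @param strategies character vector of strategy tags among `av_first`,
#'   `roof_first`, `combined`, `uniform`, `random`, `basal_removal`.
#' @param n_iterations atrial additions per additive plan (removal steps
#'   for `basal_removal`).
#' @param n_frames activation frames (1 ms apart).
#' @param frame_seed,strategy_seed integer seeds.
#' @param scheme Laplacian weight scheme for interpolation.
#' @param convention RMS convention for reports.
#' @param window summary frame window (`NULL` = all frames).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a classed list, `run_config`.
#' @export
run_config <- function(preset = "sock_like", heart_nodes = 500L,
                       torso_nodes = 770L,
                       strategies = c("av_first", "roof_first", "combined",
                                      "uniform", "random"),
                       n_iterations = 7L, n_frames = 20L,
                       frame_seed = 1L, strategy_seed = 1L,
                       scheme = "cotangent", convention = "sqrt_n",
                       window = NULL, out_dir = NULL) {
  known <- c("av_first", "roof_first", "combined", "uniform", "random",
             "basal_removal")
  if (!length(strategies) || !all(strategies %in% known))
    stop("strategies must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  structure(list(preset = preset, heart_nodes = as.integer(heart_nodes),
                 torso_nodes = as.integer(torso_nodes),
                 strategies = strategies,
                 n_iterations = as.integer(n_iterations),
                 n_frames = as.integer(n_frames),
                 frame_seed = as.integer(frame_seed),
                 strategy_seed = as.integer(strategy_seed),
                 scheme = scheme, convention = convention,
                 window = window, out_dir = out_dir),
            class = "run_config")
}

build_plan <- function(strategy, scene, config) {
  switch(strategy,
         av_first = plan_av_first(scene, config$n_iterations),
         roof_first = plan_roof_first(scene, config$n_iterations),
         combined = plan_combined(scene, config$n_iterations),
         uniform = plan_uniform(scene, config$n_iterations,
                                config$strategy_seed),
         random = plan_random(scene, config$n_iterations,
                              config$strategy_seed),
         basal_removal = plan_basal_removal(scene, config$n_iterations),
         stop("unknown strategy ", strategy))
}

score_iteration <- function(measured, lap, frames, transfer, gt, config,
                            ctx) {
  full <- length(measured) == nrow(frames$values)
  est <- if (full) frames else
    tryCatch(interpolate_frames(lap, measured, frames),
             error = function(e)
               stop(ctx, ": ", conditionMessage(e)))
  bsp <- forward_solve(transfer, est)
  es <- error_series(gt, bsp, config$convention)
  summarize_errors(es, config$window)
}

#' Run the sampling-ablation experiment
#'
#' The full pipeline: ground truth is the forward solution at full source
#' sampling; each (strategy, iteration) restricts the source frames to the
#' measured set, fills the rest by Laplacian interpolation, forward-solves
#' and scores against the ground truth. Because ground truth comes from the
#' same BEM operator, the reported error is pure sampling error: the final
#' iteration of every additive strategy scores ~0.
#'
#' @param config a [run_config()].
#' @param transfer optional precomputed [assemble_transfer()] for the
#'   config's scene (assembled here when `NULL`).
#' @return an object of class `ablation_report`: fields `table` (one row
#'   per strategy x iteration with electrode counts and metric summaries),
#'   `config`. When `config$out_dir` is set, writes `ablation.csv` and
#'   `provenance.json` there.
#' @export
run_ablation <- function(config, transfer = NULL) {
  scene <- make_scene(config$preset, config$heart_nodes,
                      config$torso_nodes)
  frames <- generate_frames(scene, config$n_frames, config$frame_seed)
  transfer <- transfer %||% assemble_transfer(scene)
  gt <- forward_solve(transfer, frames)
  lap <- build_laplacian(scene$heart, config$scheme)
  rows <- list()
  for (strategy in config$strategies) {
    plan <- build_plan(strategy, scene, config)
    for (it in seq_along(plan$iterations)) {
      measured <- plan$iterations[[it]]
      ctx <- sprintf("strategy %s, iteration %d", strategy, it - 1L)
      s <- score_iteration(measured, lap, frames, transfer, gt, config,
                           ctx)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(strategy = strategy, iteration = it - 1L,
                         n_electrodes = length(measured),
                         stringsAsFactors = FALSE), s)
    }
  }
  report <- structure(list(table = do.call(rbind, rows), config = config),
                      class = "ablation_report")
  maybe_write_report(report, "ablation")
  report
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("ablation_report:\n")
  print(x$table, digits = 4)
  invisible(x)
}

maybe_write_report <- function(report, stem) {
  out <- report$config$out_dir
  if (is.null(out)) return(invisible(NULL))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(out, paste0(stem, ".csv")),
                   row.names = FALSE)
  prov <- list(config = report$config[setdiff(names(report$config),
                                              "out_dir")],
               package = "ecgfwd",
               package_version =
                 as.character(utils::packageVersion("ecgfwd")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out, paste0(stem,
                                                   "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Rank sampling strategies from an ablation report
#'
#' Scores each strategy by (a) the trapezoidal area under its
#' `(n_electrodes, mean rRMSE)` curve and (b) the smallest electrode count
#' whose mean rRMSE is within 10% of the full-sampling value. Lower is
#' better on both. With the shared-operator ground truth the full-sampling
#' rRMSE is ~0, so the threshold column typically saturates at the full
#' electrode count; the area is the informative ranking.
#'
#' @param report an [run_ablation()] result covering >= 2 additive
#'   strategies on identical electrode grids.
#' @return a `data.frame` with one row per strategy: `strategy`, `auc`,
#'   `electrodes_to_threshold`.
#' @export
compare_strategies <- function(report) {
  tab <- report$table[report$table$strategy != "basal_removal", ]
  strategies <- unique(tab$strategy)
  if (length(strategies) < 2L)
    stop("need at least two additive strategies to compare")
  grids <- lapply(strategies, function(s)
    tab$n_electrodes[tab$strategy == s])
  for (g in grids[-1])
    if (!identical(g, grids[[1]]))
      stop("strategies were run on mismatched electrode grids")
  rows <- lapply(strategies, function(s) {
    sub <- tab[tab$strategy == s, ]
    sub <- sub[order(sub$n_electrodes), ]
    x <- sub$n_electrodes; y <- sub$mean_rrmse
    auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    full_val <- y[length(y)]
    hit <- x[y <= 1.1 * full_val]
    data.frame(strategy = s, auc = auc,
               electrodes_to_threshold =
                 if (length(hit)) min(hit) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plaque-cluster study
#'
#' One row per plaque centre: the measured set is the full ventricular
#' sampling plus the `k`-node plaque cluster nearest the centre, scored
#' exactly as in [run_ablation()]. A ventricle-only baseline row
#' (`center_id = 0`) is always included; `k = 0` rows equal it.
#'
#' @param config a [run_config()].
#' @param centers list (or n x 3 matrix) of plaque centre points (mm).
#' @param k plaque size in electrodes (>= 0).
#' @param transfer optional precomputed transfer matrix.
#' @return an `ablation_report` whose table has `center_id` instead of
#'   `iteration`.
#' @export
run_plaque_study <- function(config, centers, k, transfer = NULL) {
  if (is.matrix(centers))
    centers <- lapply(seq_len(nrow(centers)), function(i) centers[i, ])
  scene <- make_scene(config$preset, config$heart_nodes,
                      config$torso_nodes)
  frames <- generate_frames(scene, config$n_frames, config$frame_seed)
  transfer <- transfer %||% assemble_transfer(scene)
  gt <- forward_solve(transfer, frames)
  lap <- build_laplacian(scene$heart, config$scheme)
  vent <- sort(ventricular_indices(scene))
  rows <- list()
  add_row <- function(id, measured, ctx) {
    s <- score_iteration(measured, lap, frames, transfer, gt, config, ctx)
    rows[[length(rows) + 1L]] <<-
      cbind(data.frame(strategy = "plaque", center_id = id,
                       n_electrodes = length(measured),
                       stringsAsFactors = FALSE), s)
  }
  add_row(0L, vent, "plaque baseline")
  for (i in seq_along(centers)) {
    measured <- if (k == 0) vent else
      sort(union(vent, plaque_cluster(scene, centers[[i]], k)))
    add_row(i, measured, sprintf("plaque center %d", i))
  }
  report <- structure(list(table = do.call(rbind, rows), config = config),
                      class = "ablation_report")
  maybe_write_report(report, "plaque")
  report
}

#' Default plaque centres for a scene
#'
#' Evenly spread atrial locations: the first `n` farthest-point-sampled
#' atrial nodes, returned as coordinates, give reproducible plaque centres
#' covering the atrial surface.
#'
#' @param scene a [make_scene()] object.
#' @param n number of centres.
#' @return an `n x 3` matrix of points (mm).
#' @export
default_plaque_centers <- function(scene, n = 6L) {
  atr <- atrial_indices(scene)
  P <- scene$heart$vertices[atr, , drop = FALSE]
  ctr <- colMeans(P)
  start <- which.min(rowSums(sweep(P, 2, ctr)^2))
  ord <- fps_order(P, start)
  P[ord[seq_len(min(n, length(ord)))], , drop = FALSE]
}
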