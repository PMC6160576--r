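#' Infinite-medium current dipole potential
#'
#' Evaluates \eqn{\Phi(r) = p \cdot (r - r_0) / (4 \pi \sigma |r - r_0|^3)}
#' for a current dipole at `position` with moment `moment` in an unbounded
#' homogeneous conductor. Used as an analytic stand-in for propagating
#' myocardial sources: any smooth field works as Dirichlet data for the
#' forward operator, and the dipole is exactly reproducible.
#'
#' @param position 3-vector dipole location (mm).
#' @param moment 3-vector dipole moment (only ratios of potentials matter).
#' @param points n x 3 matrix of field points (mm).
#' @param conductivity scalar conductivity (S/m).
#' @return numeric vector of potentials (mV, up to the moment's scaling).
#' @export
dipole_potential <- function(position, moment, points, conductivity = 0.2) {
  points <- rbind(points)   # accept a bare 3-vector
  d <- sweep(points, 2, position)
  r3 <- rowSums(d^2)^1.5
  if (any(r3 < 1e-30))
    stop("field point coincides with the dipole position")
  unname(as.vector(d %*% moment) / (4 * pi * conductivity * r3))
}

#' Potential frame set
#'
#' A node x frame matrix of potentials bound to a mesh; the container for
#' ground-truth and subsampled cardiac or torso potentials.
#'
#' @param values numeric matrix, nodes x frames (mV).
#' @param mesh_id character identifier of the mesh the rows refer to.
#' @param frame_ms frame interval in milliseconds.
#' @param units unit string.
#' @return an object of class `frame_set`.
#' @export
frame_set <- function(values, mesh_id, frame_ms = 1, units = "mV") {
  values <- as.matrix(values)
  structure(list(values = values, mesh_id = mesh_id,
                 frame_ms = frame_ms, units = units),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d nodes x %d frames on '%s' (%s, %g ms/frame)\n",
              nrow(x$values), ncol(x$values), x$mesh_id, x$units,
              x$frame_ms))
  invisible(x)
}

#' Generate dipole-driven source potentials on the heart surface
#'
#' Emulates a ventricular activation window: `n_dipoles` current dipoles
#' sweep from the apex toward the base of the heart over the frames, with
#' moments rotating by 90 degrees over the window. Atrial activation is not
#' simulated; atrial-surface potentials are the passive far field of the
#' ventricular dipoles. Potentials are scaled so the peak magnitude over
#' the window is `peak_mv` (epicardial-magnitude realism); the scaling is
#' folded into the dipole moments, so each stored value equals the dipole
#' sum exactly.
#'
#' @param scene a [make_scene()] object.
#' @param n_frames number of time frames (>= 2), 1 ms apart.
#' @param seed integer seed; the generator is a pure function of
#'   `(scene, n_frames, seed)`.
#' @param n_dipoles number of moving dipoles (default 3).
#' @param peak_mv target peak |potential| on the source surface (mV).
#' @return a `frame_set` on the heart surface, with attribute `"dipoles"`:
#'   a list (one per frame) of lists with `position` and `moment`.
#' @export
generate_frames <- function(scene, n_frames = 20L, seed = 1L,
                            n_dipoles = 3L, peak_mv = 30) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  hv <- scene$heart$vertices
  zc <- long_axis_coord(scene)
  ctr <- colMeans(hv)
  z_lo <- stats::quantile(zc, 0.1) - ctr[3]
  z_hi <- stats::quantile(zc, 0.8) - ctr[3]
  # deterministic per-dipole jitter from the seed
  rng <- local({
    set.seed(as.integer(seed))
    list(off = matrix(stats::rnorm(3L * n_dipoles, sd = 4), n_dipoles, 3L),
         phase = stats::runif(n_dipoles, 0, 2 * pi))
  })
  tgrid <- seq(0, 1, length.out = n_frames)
  frames_dip <- vector("list", n_frames)
  vals <- matrix(0, nrow(hv), n_frames)
  for (f in seq_len(n_frames)) {
    t <- tgrid[f]
    dips <- vector("list", n_dipoles)
    for (k in seq_len(n_dipoles)) {
      zk <- z_lo + (z_hi - z_lo) * t
      ang <- 2 * pi * (k - 1) / n_dipoles + rng$phase[k]
      pos <- ctr + c(8 * cos(ang), 8 * sin(ang), zk) + rng$off[k, ] * 0.5
      rot <- pi / 2 * t                      # moment rotates 90 deg
      mom <- c(cos(ang + rot), sin(ang + rot), 0.6)
      dips[[k]] <- list(position = pos, moment = mom)
      vals[, f] <- vals[, f] +
        dipole_potential(pos, mom, hv, scene$conductivity)
    }
    frames_dip[[f]] <- dips
  }
  sc <- peak_mv / max(abs(vals))
  vals <- vals * sc
  for (f in seq_len(n_frames))
    for (k in seq_len(n_dipoles))
      frames_dip[[f]][[k]]$moment <- frames_dip[[f]][[k]]$moment * sc
  fs <- frame_set(vals, mesh_id = mesh_id_of(scene$heart, "heart"))
  attr(fs, "dipoles") <- frames_dip
  fs
}

#' Write / read a frame set as a delimited matrix with a JSON header
#'
#' The matrix (nodes x frames) is written as comma-separated text; a
#' sidecar `<path>.json` records the mesh id, units and frame interval.
#'
#' @param fs a [frame_set()].
#' @param path output path for the matrix.
#' @return `save_frames`: `path` invisibly; `load_frames`: a `frame_set`.
#' @export
save_frames <- function(fs, path) {
  utils::write.table(fs$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(mesh_id = fs$mesh_id, units = fs$units,
                            frame_ms = fs$frame_ms,
                            n_nodes = nrow(fs$values),
                            n_frames = ncol(fs$values)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_frames
#' @export
load_frames <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  if (nrow(vals) != hdr$n_nodes || ncol(vals) != hdr$n_frames)
    stop("frame matrix shape does not match its JSON header")
  frame_set(vals, hdr$mesh_id, hdr$frame_ms, hdr$units)
}
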