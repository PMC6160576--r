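#' Synthetic heart-in-torso scene
#'
#' Builds the geometry used throughout the sampling experiments: a closed
#' cardiac source surface with ventricular/atrial labels split by an
#' atrioventricular (AV) plane, inside a closed torso surface, with a
#' homogeneous conductivity.
#'
#' Presets:
#' \describe{
#'   \item{`sock_like`}{prolate-ellipsoid heart of ~60 x 60 x 70 mm
#'     (emulating a capped ventricular sock mesh) inside an ellipsoidal
#'     torso of ~360 x 220 x 400 mm.}
#'   \item{`cage_like`}{capped cylinder of ~100 x 100 x 150 mm (emulating a
#'     rigid recording cage) inside the same torso.}
#' }
#' The long axis is +z; the AV plane is the axial coordinate above which
#' approximately `atrial_fraction` of the source vertices lie, and those
#' vertices are labelled atrial.
#'
#' @param preset `"sock_like"` or `"cage_like"`.
#' @param heart_nodes_target target vertex count for the source surface
#'   (>= 50).
#' @param torso_nodes_target target vertex count for the torso (>= 50).
#' @param atrial_fraction fraction of source vertices to label atrial.
#' @param conductivity homogeneous torso conductivity (S/m). Cancels in all
#'   error metrics; carried for dimensional bookkeeping.
#' @return an object of class `scene`: fields `heart`, `torso`
#'   ([tri_mesh()]), `conductivity`, `av_plane_z` (mm), `long_axis`
#'   (unit 3-vector), `preset`.
#' @export
make_scene <- function(preset = c("sock_like", "cage_like"),
                       heart_nodes_target = 500L,
                       torso_nodes_target = 770L,
                       atrial_fraction = 0.25,
                       conductivity = 0.2) {
  preset <- match.arg(preset)
  if (heart_nodes_target < 50L || torso_nodes_target < 50L)
    stop("node targets must be >= 50")
  torso_semi <- c(180, 110, 200)        # ~36 x 22 x 40 cm stored as mm
  heart <- switch(preset,
    sock_like = make_ellipsoid_mesh(c(30, 30, 35), heart_nodes_target),
    cage_like = make_cylinder_mesh(50, 150, heart_nodes_target))
  torso <- make_ellipsoid_mesh(torso_semi, torso_nodes_target)
  # containment check (ellipsoidal torso: implicit form)
  q <- sweep(heart$vertices, 2, torso_semi, "/")
  if (any(rowSums(q^2) >= 1))
    stop("torso does not enclose the source surface")
  long_axis <- c(0, 0, 1)
  zc <- as.vector(heart$vertices %*% long_axis)
  # candidate AV-plane cuts sit between distinct axial levels (mesh rings
  # share a level); pick the cut whose atrial fraction is nearest target
  zu <- sort(unique(zc), decreasing = TRUE)
  cuts <- (utils::head(zu, -1) + utils::tail(zu, -1)) / 2
  frac <- vapply(cuts, function(cz) mean(zc > cz), numeric(1))
  av_plane_z <- cuts[which.min(abs(frac - atrial_fraction))]
  labels <- ifelse(zc > av_plane_z, "atrial", "ventricular")
  heart$labels <- as.vector(labels)
  torso$labels <- rep("torso", nrow(torso$vertices))
  structure(list(heart = heart, torso = torso,
                 conductivity = conductivity,
                 av_plane_z = av_plane_z, long_axis = long_axis,
                 preset = preset),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene (%s): heart %d nodes (%d atrial), torso %d nodes\n",
              x$preset, nrow(x$heart$vertices),
              sum(x$heart$labels == "atrial"), nrow(x$torso$vertices)))
  cat(sprintf("  AV plane at z = %.1f mm, conductivity %.2f S/m\n",
              x$av_plane_z, x$conductivity))
  invisible(x)
}

#' Atrial / ventricular vertex indices of a scene
#' @param scene a [make_scene()] object.
#' @return integer vector of source-surface vertex indices.
#' @export
atrial_indices <- function(scene) which(scene$heart$labels == "atrial")

#' @rdname atrial_indices
#' @export
ventricular_indices <- function(scene) {
  which(scene$heart$labels == "ventricular")
}

# long-axis coordinate of source vertices (mm)
long_axis_coord <- function(scene, idx = NULL) {
  z <- as.vector(scene$heart$vertices %*% scene$long_axis)
  if (is.null(idx)) z else z[idx]
}
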