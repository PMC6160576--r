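#' Assemble the pericardial-to-torso BEM transfer matrix
#'
#' Discretises the quasi-static forward problem for a homogeneous volume
#' conductor bounded internally by the cardiac source surface (Dirichlet
#' data) and externally by an insulated torso (zero normal current):
#' Green's representation collocated at the vertices of both surfaces, with
#' linear shape functions on plane triangles and fully analytic element
#' integrals (shape-weighted solid angles for the double layer, Wilton-type
#' closed forms for the single layer). Diagonal contributions come from the
#' auto-solid-angle identity (row sums of the double-layer blocks under a
#' constant field), so no interior angle is ever estimated geometrically.
#'
#' Eliminating the unknown normal gradient on the source surface yields the
#' dense transfer matrix `T` with `phi_torso = T %*% phi_heart`. The
#' eliminated system is uniquely solvable as assembled: the Dirichlet data
#' couples in through the single-layer block, which removes the constant
#' nullspace of the insulated double-layer block; `T %*% 1 = 1` holds to
#' roundoff. A Lynn-Timlake style rank-one deflation of the torso block is
#' available (`deflate = TRUE`) for near-singular geometries, in which case
#' outputs are re-referenced to zero mean over the torso nodes.
#'
#' @param scene a [make_scene()] object, or a list with closed `heart` and
#'   `torso` [tri_mesh()] surfaces (heart strictly inside torso).
#' @param deflate apply the rank-one deflation (default `FALSE`; see
#'   Details).
#' @return an object of class `transfer_matrix`: fields `T` (dense
#'   `n_torso x n_heart`), `source_mesh_id`, `torso_mesh_id`, `deflated`.
#' @export
assemble_transfer <- function(scene, deflate = FALSE) {
  heart <- scene$heart; torso <- scene$torso
  if (!is_closed_mesh(heart) || !is_closed_mesh(torso))
    stop("both surfaces must be closed")
  Hv <- heart$vertices; Ht <- heart$triangles - 1L
  Tv <- torso$vertices; Tt <- torso$triangles - 1L

  tt <- .bem_collocation(Tv, Tv, Tt, FALSE)      # torso pts vs torso surface
  th <- .bem_collocation(Tv, Hv, Ht, TRUE)       # torso pts vs heart surface
  ht <- .bem_collocation(Hv, Tv, Tt, FALSE)      # heart pts vs torso surface
  hh <- .bem_collocation(Hv, Hv, Ht, TRUE)       # heart pts vs heart surface

  # containment diagnostics via total solid angles
  if (any(abs(rowSums(ht$W) - 4 * pi) > 0.5))
    stop("geometry error: source surface vertices are not strictly ",
         "inside the torso")
  if (any(abs(rowSums(th$W)) > 0.5))
    stop("geometry error: torso vertices lie inside or on the source ",
         "surface")

  fourpi_cT <- rowSums(tt$W) - rowSums(th$W)     # auto solid angle, torso rows
  fourpi_cH <- rowSums(ht$W) - rowSums(hh$W)     # auto solid angle, heart rows

  # eliminate the heart normal-gradient unknown through the single layer
  X <- tryCatch(solve(hh$S, cbind(ht$W, diag(fourpi_cH) + hh$W)),
                error = function(e)
                  stop("numerical error: heart single-layer block is ",
                       "singular (", conditionMessage(e), ")"))
  nT <- nrow(Tv); nH <- nrow(Hv)
  XW <- X[, seq_len(nT), drop = FALSE]
  XC <- X[, nT + seq_len(nH), drop = FALSE]
  A <- diag(fourpi_cT) - tt$W + th$S %*% XW
  B <- -th$W + th$S %*% XC
  if (deflate)
    A <- A + (4 * pi / nT) * matrix(1, nT, nT)
  Tm <- tryCatch(solve(A, B), error = function(e) {
    stop("numerical error solving the torso system; reciprocal condition ",
         "estimate ", format(rcond(A), digits = 3))
  })
  if (deflate)
    Tm <- Tm - matrix(colMeans(Tm), nT, nH, byrow = TRUE)
  structure(list(T = Tm,
                 source_mesh_id = mesh_id_of(heart, "heart"),
                 torso_mesh_id = mesh_id_of(torso, "torso"),
                 deflated = deflate),
            class = "transfer_matrix")
}

# stable id for binding frame sets to meshes: type + vertex/triangle counts
mesh_id_of <- function(mesh, type) {
  sprintf("%s:V%d:F%d", type, nrow(mesh$vertices), nrow(mesh$triangles))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d torso x %d source nodes (%s -> %s)%s\n",
              nrow(x$T), ncol(x$T), x$source_mesh_id, x$torso_mesh_id,
              if (x$deflated) ", deflated" else ""))
  invisible(x)
}

#' Apply a transfer matrix to source-surface potential frames
#'
#' Frame-independent (quasi-static) matrix products; the output frame set
#' carries the torso mesh id and the input frame timing.
#'
#' @param transfer a [assemble_transfer()] result.
#' @param fs a [frame_set()] on the transfer matrix's source mesh.
#' @return a `frame_set` of body-surface potentials.
#' @export
forward_solve <- function(transfer, fs) {
  if (!identical(fs$mesh_id, transfer$source_mesh_id))
    stop("frame set is bound to '", fs$mesh_id,
         "' but the transfer matrix expects '", transfer$source_mesh_id,
         "'")
  frame_set(transfer$T %*% fs$values, transfer$torso_mesh_id,
            fs$frame_ms, fs$units)
}

#' Serialize / load a transfer matrix
#'
#' Writes the dense matrix as comma-separated text plus a JSON header
#' carrying the mesh ids and an md5 checksum of the matrix file.
#'
#' @param transfer a `transfer_matrix`.
#' @param path output path for the matrix file.
#' @return `save_transfer`: `path` invisibly; `load_transfer`: a
#'   `transfer_matrix` (checksum verified).
#' @export
save_transfer <- function(transfer, path) {
  utils::write.table(transfer$T, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(source_mesh_id = transfer$source_mesh_id,
                            torso_mesh_id = transfer$torso_mesh_id,
                            deflated = transfer$deflated,
                            n_torso = nrow(transfer$T),
                            n_source = ncol(transfer$T),
                            md5 = unname(tools::md5sum(path))),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_transfer
#' @export
load_transfer <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(unname(tools::md5sum(path)), hdr$md5))
    stop("transfer matrix file does not match its checksum")
  Tm <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(Tm) <- NULL
  structure(list(T = Tm, source_mesh_id = hdr$source_mesh_id,
                 torso_mesh_id = hdr$torso_mesh_id,
                 deflated = hdr$deflated),
            class = "transfer_matrix")
}
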