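#' Read a triangulated surface mesh
#'
#' Supports three plain-text dialects:
#' \describe{
#'   \item{`ptsfac`}{SCIRun-style pair of files: a `.pts` file with one
#'     `x y z` line per vertex and a `.fac` file with one `i j k` line per
#'     triangle, indices 1-based on disk. `path` may name either file or
#'     the common stem.}
#'   \item{`off`}{ASCII OFF, 0-based face indices.}
#'   \item{`ply`}{ASCII PLY 1.0, `vertex` and `face` elements.}
#' }
#' A sidecar label file (`<stem>.labels`, one token per vertex line) is
#' read when present and attached as per-vertex region labels.
#'
#' @param path file path (see above for `ptsfac` stems).
#' @param format one of `"ptsfac"`, `"off"`, `"ply"`; default guessed from
#'   the file extension.
#' @return a validated [tri_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "ptsfac", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  m <- switch(format,
              ptsfac = read_ptsfac(path),
              off = read_off(path),
              ply = read_ply(path))
  lp <- paste0(mesh_stem(path, format), ".labels")
  if (file.exists(lp)) {
    labels <- scan(lp, what = character(), quiet = TRUE)
    if (length(labels) != nrow(m$vertices))
      stop("label sidecar ", lp, " has ", length(labels),
           " entries for ", nrow(m$vertices), " vertices")
    m$labels <- labels
  }
  validate_mesh(m)
  m
}

#' Write a triangulated surface mesh
#'
#' Inverse of [load_mesh()]; coordinates are written with 9 significant
#' digits so that a round trip preserves geometry to better than 1e-8
#' relative. When the mesh carries region labels a `<stem>.labels` sidecar
#' is written alongside.
#'
#' @param mesh a validated [tri_mesh()].
#' @param path output path (for `ptsfac`, the stem or either file name).
#' @param format one of `"ptsfac"`, `"off"`, `"ply"`.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "ptsfac", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  validate_mesh(mesh)
  if (nrow(mesh$triangles) == 0L) stop("refusing to write an empty mesh")
  switch(format,
         ptsfac = write_ptsfac(mesh, path),
         off = write_off(mesh, path),
         ply = write_ply(mesh, path))
  if (!is.null(mesh$labels))
    writeLines(mesh$labels, paste0(mesh_stem(path, format), ".labels"))
  invisible(path)
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pts = "ptsfac", fac = "ptsfac",
         off = "off", ply = "ply",
         stop("cannot guess mesh format from extension '", ext,
              "'; pass format= explicitly"))
}

mesh_stem <- function(path, format) {
  if (format == "ptsfac" && tolower(tools::file_ext(path)) %in% c("pts", "fac"))
    return(tools::file_path_sans_ext(path))
  path
}

parse_num_table <- function(lines, ncol, what, path, offset = 0L) {
  out <- matrix(NA_real_, length(lines), ncol)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t,]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < ncol || anyNA(vals[seq_len(ncol)]))
      stop(path, ":", i + offset, ": cannot parse ", what, " line '",
           lines[i], "'")
    out[i, ] <- vals[seq_len(ncol)]
  }
  out
}

read_ptsfac <- function(path) {
  stem <- mesh_stem(path, "ptsfac")
  pts_path <- paste0(stem, ".pts")
  fac_path <- paste0(stem, ".fac")
  for (p in c(pts_path, fac_path))
    if (!file.exists(p)) stop("file not found: ", p)
  pl <- readLines(pts_path)
  pl <- pl[nzchar(trimws(pl))]
  fl <- readLines(fac_path)
  fl <- fl[nzchar(trimws(fl))]
  v <- parse_num_table(pl, 3L, "vertex", pts_path)
  tr <- parse_num_table(fl, 3L, "face", fac_path)
  if (nrow(tr) && (min(tr) < 1 || max(tr) > nrow(v)))
    stop(fac_path, ": index out of range (1-based indices 1..", nrow(v), ")")
  tri_mesh(v, tr, validate = FALSE)   # caller validates (after labels)
}

write_ptsfac <- function(mesh, path) {
  stem <- mesh_stem(path, "ptsfac")
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), paste0(stem, ".pts"))
  writeLines(apply(mesh$triangles, 1, paste, collapse = " "),
             paste0(stem, ".fac"))
}

read_off <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !grepl("^#", trimws(ln))]
  if (toupper(trimws(ln[1])) != "OFF") stop(path, ":1: missing OFF header")
  hdr <- parse_num_table(ln[2], 3L, "count", path, offset = 1L)
  nv <- hdr[1]; nf <- hdr[2]
  if (length(ln) < 2 + nv + nf)
    stop(path, ": truncated file (expected ", nv, " vertices and ", nf,
         " faces)")
  v <- parse_num_table(ln[3:(2 + nv)], 3L, "vertex", path, offset = 2L)
  f <- parse_num_table(ln[(3 + nv):(2 + nv + nf)], 4L, "face", path,
                       offset = 2L + nv)
  if (any(f[, 1] != 3)) stop(path, ": non-triangular face")
  tr <- f[, 2:4] + 1
  if (nrow(tr) && (min(tr) < 1 || max(tr) > nrow(v)))
    stop(path, ": index out of range")
  tri_mesh(v, tr, validate = FALSE)
}

write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
             con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

read_ply <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  if (trimws(ln[1]) != "ply") stop(path, ":1: not a PLY file")
  endh <- which(trimws(ln) == "end_header")[1]
  if (is.na(endh)) stop(path, ": missing end_header")
  hdr <- trimws(ln[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop(path, ": only ASCII PLY is supported")
  el <- grep("^element\\s", hdr, value = TRUE)
  counts <- list()
  for (e in el) {
    toks <- strsplit(e, "\\s+")[[1]]
    counts[[toks[2]]] <- as.integer(toks[3])
  }
  if (is.null(counts$vertex) || is.null(counts$face))
    stop(path, ": PLY needs vertex and face elements")
  body <- ln[(endh + 1):length(ln)]
  body <- body[nzchar(trimws(body))]
  nv <- counts$vertex; nf <- counts$face
  if (length(body) < nv + nf) stop(path, ": truncated body")
  v <- parse_num_table(body[seq_len(nv)], 3L, "vertex", path, offset = endh)
  f <- parse_num_table(body[nv + seq_len(nf)], 4L, "face", path,
                       offset = endh + nv)
  if (any(f[, 1] != 3)) stop(path, ": non-triangular face")
  tr <- f[, 2:4] + 1
  if (nrow(tr) && (min(tr) < 1 || max(tr) > nrow(v)))
    stop(path, ": index out of range")
  tri_mesh(v, tr, validate = FALSE)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
}
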