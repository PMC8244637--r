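#' Read a landmarked face surface from disk
#'
#' Reads an ASCII OBJ or PLY triangle mesh together with a plain-text landmark
#' file (`name x y z` per line, whitespace- or comma-delimited) and returns a
#' validated [face_surface()]. Landmark names are checked against the
#' canonical 22-name scheme unless `scheme = NULL`.
#'
#' @param mesh_path Path to an `.obj` or `.ply` (ascii) mesh.
#' @param landmark_path Path to the landmark text file.
#' @param subject_id Subject identifier; defaults to the mesh file stem.
#' @param scheme Landmark scheme to validate against; `NULL` to accept any.
#' @return A `face_surface`.
#' @export
read_face <- function(mesh_path, landmark_path,
                      subject_id = sub("\\.[^.]+$", "", basename(mesh_path)),
                      scheme = canonical_landmark_names()) {
  mesh <- read_mesh(mesh_path)
  lms <- read_landmarks(landmark_path, scheme = scheme)
  face_surface(subject_id, mesh$vertices, mesh$triangles, lms)
}

read_mesh <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    abort(glue::glue("unsupported mesh format '.{ext}' (expected .obj or .ply)"))
  )
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0) {
    abort(glue::glue("'{path}' is not a valid OBJ mesh (no vertices or faces)"))
  }
  v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  fidx <- vapply(strsplit(sub("^f ", "", fl), "\\s+"), function(tok) {
    as.integer(sub("/.*", "", tok[1:3]))
  }, integer(3))
  list(vertices = v, triangles = t(fidx))
}

write_obj <- function(mesh, path, digits = 8) {
  v <- mesh$vertices
  tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(paste0("v %.", digits, "f %.", digits, "f %.", digits, "f"),
                     v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply") abort(glue::glue("'{path}' is not a PLY file"))
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) abort(glue::glue("'{path}': PLY header has no end_header"))
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) abort(glue::glue("'{path}': only ascii PLY supported"))
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vtok, function(x) as.numeric(x[1:3]), numeric(3)))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  tr <- t(vapply(ftok, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  list(vertices = v, triangles = tr)
}

# vertex_colors: optional n x 3 matrix of 0-255 integers (for heat-map export)
write_ply <- function(mesh, path, vertex_colors = NULL, digits = 8) {
  v <- mesh$vertices
  tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (!is.null(vertex_colors)) {
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(tr)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  fmt <- paste0("%.", digits, "f")
  vline <- sprintf(paste(fmt, fmt, fmt), v[, 1], v[, 2], v[, 3])
  if (!is.null(vertex_colors)) {
    vline <- paste(vline, sprintf("%d %d %d", vertex_colors[, 1],
                                  vertex_colors[, 2], vertex_colors[, 3]))
  }
  writeLines(vline, con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  invisible(path)
}

#' Read a landmark text file
#'
#' Format: one landmark per line, `name x y z`, whitespace or comma
#' delimited; `#` comments allowed.
#'
#' @inheritParams read_face
#' @param path Path to the landmark file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, scheme = canonical_landmark_names()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "[,\\s]+", perl = TRUE)
  bad <- lengths(tok) != 4
  if (any(bad)) {
    abort(glue::glue("'{path}': malformed landmark line(s): ",
                     "{paste(lines[bad], collapse = '; ')}"))
  }
  nm <- vapply(tok, `[`, "", 1)
  pts <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3)))
  rownames(pts) <- nm
  landmark_set(pts, scheme = scheme)
}

#' Write a landmark set to a text file
#' @param lms A [landmark_set()].
#' @param path Output path.
#' @export
write_landmarks <- function(lms, path) {
  writeLines(sprintf("%s %.8f %.8f %.8f", rownames(lms),
                     lms[, 1], lms[, 2], lms[, 3]), path)
  invisible(path)
}

#' Write a face surface to disk
#'
#' @param face A [face_surface()].
#' @param mesh_path Output mesh path (`.obj` or `.ply`).
#' @param landmark_path Optional landmark file path.
#' @export
write_face <- function(face, mesh_path, landmark_path = NULL) {
  ext <- tolower(sub(".*\\.", "", mesh_path))
  switch(ext,
    obj = write_obj(face, mesh_path),
    ply = write_ply(face, mesh_path),
    abort(glue::glue("unsupported mesh format '.{ext}'"))
  )
  if (!is.null(landmark_path)) write_landmarks(face$landmarks, landmark_path)
  invisible(mesh_path)
}
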