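#' Construct a face surface
#'
#' The raw unit of face data: a triangulated surface in mm coordinates
#' (x lateral, y vertical, z depth) with a named anatomical landmark set.
#'
#' @param subject_id Subject identifier.
#' @param vertices Numeric matrix, n x 3, columns x/y/z in mm.
#' @param triangles Integer matrix, t x 3, 1-based vertex indices.
#' @param landmarks A [landmark_set()].
#' @param min_vertices Minimum admissible vertex count (default 100).
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `face_surface`.
#' @export
face_surface <- function(subject_id, vertices, triangles, landmarks,
                         min_vertices = 100, validate = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y", "z")
  fs <- structure(
    list(subject_id = as.character(subject_id), vertices = vertices,
         triangles = triangles, landmarks = landmarks),
    class = "face_surface"
  )
  if (validate) validate_face_surface(fs, min_vertices = min_vertices)
  fs
}

validate_face_surface <- function(fs, min_vertices = 100) {
  v <- fs$vertices
  tr <- fs$triangles
  if (!all(is.finite(v))) abort("face surface has non-finite vertex coordinates")
  if (nrow(v) < min_vertices) {
    abort(glue::glue("face surface needs >= {min_vertices} vertices, got {nrow(v)}"))
  }
  if (ncol(v) != 3 || ncol(tr) != 3) abort("vertices and triangles must have 3 columns")
  if (min(tr) < 1 || max(tr) > nrow(v)) abort("triangle indexes a nonexistent vertex")
  lms <- fs$landmarks
  lo <- apply(v, 2, min) - 1e-6
  hi <- apply(v, 2, max) + 1e-6
  inside <- sweep(unclass(lms), 2, lo, ">=") & sweep(unclass(lms), 2, hi, "<=")
  if (!all(inside)) {
    bad <- rownames(lms)[!apply(inside, 1, all)]
    abort(glue::glue("landmark(s) outside mesh bounding box: ",
                     "{paste(bad, collapse = ', ')}"))
  }
  invisible(fs)
}

#' @export
print.face_surface <- function(x, ...) {
  cat("<face_surface> ", x$subject_id, ": ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ", nrow(x$landmarks), " landmarks\n", sep = "")
  invisible(x)
}

#' Reflect a face surface in a vertical plane
#'
#' Negates the lateral (x) coordinate about the plane `x = plane`, flips
#' triangle winding so outward normals are preserved, and relabels landmarks
#' through the left/right pairing involution, so the result is again an
#' anatomically labelled face (the mirror face).
#'
#' @param face A [face_surface()].
#' @param plane Position of the reflection plane on the x axis (default 0).
#' @return The mirrored `face_surface`.
#' @export
reflect_surface <- function(face, plane = 0) {
  v <- face$vertices
  v[, 1] <- 2 * plane - v[, 1]
  tr <- face$triangles[, c(1, 3, 2), drop = FALSE]
  face_surface(face$subject_id, v, tr,
               reflect_landmarks(face$landmarks, plane_x = plane),
               min_vertices = 1, validate = FALSE)
}

#' Rigid landmark alignment (Kabsch, no scaling)
#'
#' Rigidly aligns each face (rotation + translation, no scaling, so absolute
#' mm lengths survive for anthropometry) to a reference landmark
#' configuration by least squares over the shared landmark scheme.
#'
#' @param faces A list of [face_surface()] objects (or a single one).
#' @param reference A [landmark_set()] giving the target configuration.
#' @return A list of aligned `face_surface` objects; each carries attributes
#'   `rotation`, `translation` and `residual` (root-mean-square landmark
#'   residual in mm).
#' @export
procrustes_align <- function(faces, reference) {
  single <- inherits(faces, "face_surface")
  if (single) faces <- list(faces)
  ref <- unclass(reference)[rownames(reference), , drop = FALSE]
  out <- lapply(faces, function(f) {
    src <- unclass(f$landmarks)[rownames(reference), , drop = FALSE]
    fit <- kabsch(src, ref)
    v <- sweep(f$vertices %*% fit$R, 2, fit$t, "+")
    lm_new <- sweep(src %*% fit$R, 2, fit$t, "+")
    lms <- landmark_set(lm_new, pairing = attr(f$landmarks, "pairing"), scheme = NULL)
    g <- face_surface(f$subject_id, v, f$triangles, lms,
                      min_vertices = 1, validate = FALSE)
    attr(g, "rotation") <- fit$R
    attr(g, "translation") <- fit$t
    attr(g, "residual") <- fit$rmsd
    g
  })
  if (single) out[[1]] else out
}

# Least-squares rigid transform mapping src onto dst (row-vector convention:
# aligned = src %*% R + t). Proper rotation enforced via the determinant sign.
kabsch <- function(src, dst) {
  if (qr(scale(src, scale = FALSE))$rank < 3 - 1e-9) {
    if (qr(scale(src, scale = FALSE))$rank < 2) {
      abort("degenerate landmark configuration: rank < 2, alignment undefined")
    }
  }
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  if (qr(H)$rank < 3) abort("degenerate landmark configuration (rank < 3)")
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- cd - cs %*% R
  aligned <- sweep(src %*% R, 2, t_vec, "+")
  list(R = R, t = drop(t_vec), rmsd = sqrt(mean(rowSums((aligned - dst)^2))))
}

# area-weighted vertex normals of a triangle mesh
vertex_normals <- function(vertices, triangles) {
  n <- matrix(0, nrow(vertices), 3)
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  fn <- cross3(b - a, c_ - a) # length = 2 * area, so area weighting is built in
  for (k in 1:3) {
    idx <- triangles[, k]
    for (j in 1:3) n[, j] <- n[, j] + tabulate_sum(idx, fn[, j], nrow(vertices))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

tabulate_sum <- function(index, values, n) {
  out <- numeric(n)
  s <- rowsum(values, group = index)
  out[as.integer(rownames(s))] <- s
  out
}

median_edge_length <- function(vertices, triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  median(sqrt(rowSums((vertices[e[, 1], ] - vertices[e[, 2], ])^2)))
}
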