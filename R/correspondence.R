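#' Dense correspondence of a target face against a base mesh
#'
#' Places the base mesh vertices in anatomical correspondence with a target
#' surface: the base vertices are warped by a thin-plate-spline interpolant
#' anchored at the 22 shared landmarks, then projected to the exact closest
#' point on the target triangle mesh. The result is a `corresponded_surface`:
#' M points, index-aligned with the base mesh, so point i denotes the same
#' anatomical location on every corresponded face.
#'
#' Warped points farther from the target surface than `cap` (default 10x the
#' target's median edge length) keep their warped, unprojected position and
#' are flagged; more than `max_fail_frac` such points is a quality error.
#'
#' @param base A `base_mesh` (see [make_template()]) or any `face_surface`
#'   used as the common reference topology.
#' @param target A [face_surface()] aligned to the same landmark frame.
#' @param cap Projection distance cap in mm; `NULL` for 10x the target's
#'   median edge length.
#' @param max_fail_frac Maximum tolerated fraction of unprojected points.
#' @param mirrored Logical flag stored on the result.
#' @return A `corresponded_surface`: list with `subject_id`, `mirrored`,
#'   `points` (M x 3), `unprojected` (logical M).
#' @export
densify <- function(base, target, cap = NULL, max_fail_frac = 0.05,
                    mirrored = FALSE) {
  src <- unclass(base$landmarks)
  dst <- unclass(target$landmarks)[rownames(base$landmarks), , drop = FALSE]
  warp <- tps_fit(src, dst)
  warped <- tps_apply(warp, base$vertices)
  proj <- cpp_project_to_mesh(warped, target$vertices, target$triangles)
  if (is.null(cap)) cap <- 10 * median_edge_length(target$vertices, target$triangles)
  unproj <- proj$dist > cap
  pts <- proj$points
  pts[unproj, ] <- warped[unproj, , drop = FALSE]
  if (mean(unproj) > max_fail_frac) {
    abort(glue::glue(
      "correspondence quality failure for '{target$subject_id}': ",
      "{sum(unproj)}/{length(unproj)} points beyond the projection cap"))
  }
  colnames(pts) <- c("x", "y", "z")
  structure(
    list(subject_id = target$subject_id, mirrored = mirrored,
         points = pts, unprojected = unproj),
    class = "corresponded_surface"
  )
}

#' @export
print.corresponded_surface <- function(x, ...) {
  cat("<corresponded_surface> ", x$subject_id,
      if (x$mirrored) " (mirrored)", ": M = ", nrow(x$points), "\n", sep = "")
  invisible(x)
}

#' Correspond a cohort of faces (optionally with their mirror images)
#'
#' Each face — and, if `include_mirrors`, its reflection — is placed in dense
#' correspondence with the base mesh. Mirrored faces are reflected and
#' landmark-relabelled *before* correspondence, so index i is anatomically
#' consistent between a face and its mirror (a prerequisite for raw-asymmetry
#' fields).
#'
#' @inheritParams densify
#' @param faces List of aligned [face_surface()] objects.
#' @param include_mirrors Also correspond the mirror image of every face.
#' @param plane Reflection plane used for the mirrors (x = `plane`).
#' @return List of `corresponded_surface` objects (originals first, then
#'   mirrors, both in input order).
#' @export
correspond_cohort <- function(base, faces, include_mirrors = TRUE, plane = 0,
                              cap = NULL, max_fail_frac = 0.05) {
  densify_safe <- function(f, mirrored) {
    tryCatch(densify(base, f, cap = cap, max_fail_frac = max_fail_frac,
                     mirrored = mirrored),
             error = function(e) {
               abort(glue::glue("correspondence failed for subject ",
                                "'{f$subject_id}': {conditionMessage(e)}"))
             })
  }
  orig <- lapply(faces, densify_safe, mirrored = FALSE)
  if (!include_mirrors) return(orig)
  mirr <- lapply(faces, function(f) {
    densify_safe(reflect_surface(f, plane = plane), mirrored = TRUE)
  })
  c(orig, mirr)
}

# --- thin-plate spline interpolation in R^3 ------------------------------
# Exact interpolant f(x) = A x + b + sum_i w_i * |x - p_i| (polyharmonic
# kernel U(r) = r, the standard 3D TPS kernel), with the usual side
# conditions sum w = 0, sum w p = 0 absorbed by the bordered system.
tps_fit <- function(src, dst) {
  n <- nrow(src)
  K <- as.matrix(stats::dist(src, diag = TRUE, upper = TRUE))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    abort("thin-plate spline system is singular (coincident landmarks?)")
  })
  list(src = src, w = coefs[seq_len(n), , drop = FALSE],
       affine = coefs[n + 1:4, , drop = FALSE])
}

tps_apply <- function(warp, x) {
  x <- as.matrix(x)
  # |x_i - p_j| for all query x points against anchor points
  d2 <- outer(rowSums(x^2), rep(1, nrow(warp$src))) +
    outer(rep(1, nrow(x)), rowSums(warp$src^2)) - 2 * x %*% t(warp$src)
  U <- sqrt(pmax(d2, 0))
  cbind(1, x) %*% warp$affine + U %*% warp$w
}

#' Stack corresponded surfaces into a shape data matrix
#'
#' @param surfaces List of `corresponded_surface` objects with identical M.
#' @return Numeric matrix, one row per surface (xyz interleaved per point,
#'   length 3M), with a `manifest` attribute (tibble: subject_id, mirrored).
#' @export
shape_matrix <- function(surfaces) {
  M <- unique(vapply(surfaces, function(s) nrow(s$points), 0L))
  if (length(M) != 1) abort("surfaces have differing point counts M")
  X <- t(vapply(surfaces, function(s) as.vector(t(s$points)), numeric(3 * M)))
  attr(X, "manifest") <- tibble(
    subject_id = vapply(surfaces, `[[`, "", "subject_id"),
    mirrored = vapply(surfaces, `[[`, TRUE, "mirrored")
  )
  attr(X, "M") <- M
  X
}
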