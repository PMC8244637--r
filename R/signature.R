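#' Build an age/gender-matched control reference
#'
#' Selects control subjects of the subject's gender within an age window
#' (widened stepwise until at least `min_n` controls match) and summarizes
#' their per-point fields by mean and standard deviation. The field can be
#' corresponded surface coordinates (for face signatures) or raw-asymmetry
#' displacement fields (for the SAI).
#'
#' @param subject One cohort record: list or one-row data frame with `age`
#'   and `gender`.
#' @param controls Cohort table of the control subjects (columns
#'   `subject_id`, `age`, `gender`).
#' @param control_fields Named list (by subject_id) of M x 3 numeric matrices,
#'   one per control.
#' @param age_window Initial half-width of the age window in years.
#' @param widen_step Step (years) by which the window grows when too few
#'   controls match.
#' @param min_n Minimum number of matched controls.
#' @param sd_floor Lower bound (mm) applied to every per-point SD so
#'   normalized differences stay finite on low-variance points.
#' @return A `control_reference`: list with `matched_ids`, `point_mean`,
#'   `point_sd` (both M x 3), `age_window_used`.
#' @export
matched_controls <- function(subject, controls, control_fields,
                             age_window = 10, widen_step = 5, min_n = 20,
                             sd_floor = 0.01) {
  controls <- dplyr::filter(controls, .data$subject_id %in% names(control_fields))
  same_gender <- dplyr::filter(controls, .data$gender == subject$gender)
  max_span <- if (nrow(same_gender)) max(abs(same_gender$age - subject$age)) else Inf
  w <- age_window
  repeat {
    matched <- dplyr::filter(same_gender, abs(.data$age - subject$age) <= w)
    if (nrow(matched) >= min_n || w >= max_span) break
    w <- w + widen_step
  }
  if (nrow(matched) < min_n) {
    abort(glue::glue(
      "only {nrow(matched)} matched control(s) for subject aged ",
      "{subject$age} ({subject$gender}); need {min_n} even at maximal window"))
  }
  fields <- control_fields[matched$subject_id]
  Fm <- vapply(fields, as.vector, numeric(length(fields[[1]]))) # 3M x n
  mu <- rowMeans(Fm)
  s <- sqrt(rowSums((Fm - mu)^2) / (ncol(Fm) - 1))
  dm <- dim(fields[[1]])
  point_mean <- matrix(mu, dm[1], dm[2])
  point_sd <- pmax(matrix(s, dm[1], dm[2]), sd_floor)
  structure(
    list(matched_ids = matched$subject_id, point_mean = point_mean,
         point_sd = point_sd, age_window_used = w),
    class = "control_reference"
  )
}

#' @export
print.control_reference <- function(x, ...) {
  cat("<control_reference> ", length(x$matched_ids), " matched controls, ",
      "age window +/-", x$age_window_used, " y\n", sep = "")
  invisible(x)
}

#' Face signature against a matched-control reference
#'
#' The signature is the field of per-point, per-axis differences from the
#' matched-control mean, normalized by the control standard deviation (i.e.
#' coordinate z-scores). Its weight — the square root of the sum of all
#' squared normalized differences — is a scalar summary of dysmorphism.
#'
#' @param surface A `corresponded_surface` or M x 3 matrix.
#' @param ref A [matched_controls()] reference with matching M.
#' @return A `signature`: list with `subject_id`, `z` (M x 3, unitless) and
#'   `weight`.
#' @export
compute_signature <- function(surface, ref) {
  P <- if (inherits(surface, "corresponded_surface")) surface$points else as.matrix(surface)
  if (!all(dim(P) == dim(ref$point_mean))) {
    abort(glue::glue("dimension mismatch: surface is {nrow(P)} x {ncol(P)}, ",
                     "reference is {nrow(ref$point_mean)} x {ncol(ref$point_mean)}"))
  }
  z <- (P - ref$point_mean) / ref$point_sd
  structure(
    list(subject_id = if (inherits(surface, "corresponded_surface")) surface$subject_id else NA_character_,
         z = z, weight = sqrt(sum(z^2))),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat("<signature> ", x$subject_id, ": M = ", nrow(x$z),
      ", weight = ", format(x$weight), "\n", sep = "")
  invisible(x)
}

#' Signature heat map: per-vertex scalar field with diverging colors
#'
#' Visualizes localized significance of a signature: for `axis` x/y/z the
#' scalar is the per-vertex z-score on that axis (lateral x shows e.g.
#' hypertelorism, vertical y nose-length anomalies, depth z mid-facial
#' hypoplasia); for `axis = "normal"` it is the signed projection of the
#' z-vector onto the base-mesh vertex normal (inward/outward displacement).
#' Colors follow a symmetric blue-green-red diverging map, green at 0 and
#' saturating at `clip` z-score units.
#'
#' @param sig A [compute_signature()] result.
#' @param axis One of "normal", "x", "y", "z".
#' @param base Base mesh (needed for vertex normals when `axis = "normal"`).
#' @param clip Color saturation point in z-score units (default 3).
#' @return A `heat_map`: list with `scalars` (length M), `colors`
#'   (M x 3 integer, 0-255) and `axis`.
#' @export
heat_map <- function(sig, axis = c("normal", "x", "y", "z"), base = NULL,
                     clip = 3) {
  axis <- tryCatch(match.arg(axis), error = function(e) {
    abort(glue::glue("unknown heat-map axis '{axis[1]}'"))
  })
  scalars <- switch(axis,
    x = sig$z[, 1], y = sig$z[, 2], z = sig$z[, 3],
    normal = {
      if (is.null(base)) abort("axis = 'normal' requires the base mesh for vertex normals")
      nrm <- vertex_normals(base$vertices, base$triangles)
      rowSums(sig$z * nrm)
    })
  structure(list(scalars = scalars, colors = diverging_colors(scalars, clip),
                 axis = axis, clip = clip, subject_id = sig$subject_id),
            class = "heat_map")
}

# blue (-clip) -> green (0) -> red (+clip), 0-255 RGB rows
diverging_colors <- function(s, clip = 3) {
  t <- pmin(pmax(s / clip, -1), 1)
  r <- ifelse(t > 0, t, 0)
  b <- ifelse(t < 0, -t, 0)
  g <- 1 - abs(t)
  cbind(red = as.integer(round(255 * r)),
        green = as.integer(round(255 * g)),
        blue = as.integer(round(255 * b)))
}

#' Export a heat map as per-vertex scalar CSV or colored PLY
#'
#' @param hm A [heat_map()].
#' @param base Base mesh providing the geometry.
#' @param path Output path; `.csv` writes `vertex,scalar,red,green,blue`,
#'   `.ply` writes the base mesh with vertex colors.
#' @export
write_heat_map <- function(hm, base, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    write.csv(data.frame(vertex = seq_along(hm$scalars), scalar = hm$scalars,
                         red = hm$colors[, 1], green = hm$colors[, 2],
                         blue = hm$colors[, 3]),
              path, row.names = FALSE)
  } else if (ext == "ply") {
    write_ply(list(vertices = base$vertices, triangles = base$triangles),
              path, vertex_colors = hm$colors)
  } else {
    abort(glue::glue("unsupported heat-map export format '.{ext}'"))
  }
  invisible(path)
}
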