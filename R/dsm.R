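#' Fit a dense surface model (PCA shape model)
#'
#' Principal component analysis of corresponded surface point displacement:
#' the centred 3M-dimensional shape vectors are decomposed by SVD; modes are
#' ordered by decreasing variance and the smallest leading set covering
#' `coverage` of total shape variance is retained. When asymmetry analyses
#' are intended the training set should contain both original faces and
#' their mirrored forms, which makes the model mean symmetric.
#'
#' @param surfaces List of `corresponded_surface` objects (identical M), or a
#'   shape matrix from [shape_matrix()].
#' @param coverage Fraction of total shape variance the retained modes must
#'   cover (default 0.99).
#' @return A `dsm_model`: list with `mean_shape` (3M), `modes` (3M x rank,
#'   orthonormal columns), `variances` (per mode, mm^2, non-increasing),
#'   `retained`, `coverage_target`, `M`, `manifest`.
#' @export
fit_dsm <- function(surfaces, coverage = 0.99) {
  X <- if (is.matrix(surfaces)) surfaces else shape_matrix(surfaces)
  n <- nrow(X)
  if (n < 3) abort("need at least 3 surfaces to fit a shape model")
  if (coverage <= 0 || coverage > 1) abort("coverage must be in (0, 1]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  tol <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tol)
  if (rank == 0) abort("zero total shape variance: all surfaces identical")
  d <- sv$d[seq_len(rank)]
  V <- sv$v[, seq_len(rank), drop = FALSE]
  # sign convention: largest-magnitude coordinate of each mode is positive
  flip <- vapply(seq_len(rank), function(j) {
    v <- V[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  V <- sweep(V, 2, flip, "*")
  variances <- d^2 / (n - 1)
  cumfrac <- cumsum(variances) / sum(variances)
  retained <- which(cumfrac >= coverage - 1e-12)[1]
  structure(
    list(mean_shape = mu, modes = V, variances = variances,
         retained = retained, coverage_target = coverage,
         M = ncol(X) / 3, n_train = n,
         manifest = attr(X, "manifest")),
    class = "dsm_model"
  )
}

#' @export
print.dsm_model <- function(x, ...) {
  cat("<dsm_model> M = ", x$M, ", trained on ", x$n_train, " surfaces; ",
      length(x$variances), " modes, ", x$retained, " retained (",
      sprintf("%.1f%%", 100 * x$coverage_target), " variance target)\n", sep = "")
  invisible(x)
}

as_shape_vector <- function(model, surface) {
  v <- if (inherits(surface, "corresponded_surface")) {
    as.vector(t(surface$points))
  } else {
    as.vector(surface)
  }
  if (length(v) != length(model$mean_shape)) {
    abort(glue::glue("dimension mismatch: surface has {length(v)/3} points, ",
                     "model expects {model$M}"))
  }
  v
}

#' Project a corresponded surface into DSM score space
#'
#' Scores are inner products of the centred shape vector with the retained
#' orthonormal modes (the "DSM representation" of the face).
#'
#' @param model A [fit_dsm()] model.
#' @param surface A `corresponded_surface` (or raw 3M shape vector).
#' @param n_modes Number of leading modes to use (default: retained count).
#' @return A `pc_scores` object: numeric score vector with `subject_id` and
#'   `mirrored` attributes.
#' @export
dsm_project <- function(model, surface, n_modes = model$retained) {
  v <- as_shape_vector(model, surface)
  scores <- drop(crossprod(model$modes[, seq_len(n_modes), drop = FALSE],
                           v - model$mean_shape))
  structure(scores,
            subject_id = if (inherits(surface, "corresponded_surface")) surface$subject_id else NA_character_,
            mirrored = if (inherits(surface, "corresponded_surface")) surface$mirrored else NA,
            class = "pc_scores")
}

#' Reconstruct a surface from DSM scores
#'
#' Inverse of [dsm_project()]: mean shape plus the score-weighted mode sum,
#' reshaped to M points. Used for raw-asymmetry surfaces and for exporting
#' mode animations (scores swept between -3 and +3 standard deviations).
#'
#' @inheritParams dsm_project
#' @param scores Numeric score vector (length <= number of modes).
#' @return M x 3 point matrix.
#' @export
dsm_reconstruct <- function(model, scores) {
  k <- length(scores)
  if (k > ncol(model$modes)) {
    abort(glue::glue("score vector longer ({k}) than available modes ",
                     "({ncol(model$modes)})"))
  }
  v <- model$mean_shape + drop(model$modes[, seq_len(k), drop = FALSE] %*% as.numeric(scores))
  matrix(v, ncol = 3, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
}

#' Project a whole cohort of corresponded surfaces
#'
#' @inheritParams dsm_project
#' @param surfaces List of `corresponded_surface` objects.
#' @return Tibble: subject_id, mirrored, one `PC<k>` column per retained mode.
#' @export
dsm_project_cohort <- function(model, surfaces, n_modes = model$retained) {
  S <- t(vapply(surfaces, function(s) as.numeric(dsm_project(model, s, n_modes)),
                numeric(n_modes)))
  colnames(S) <- paste0("PC", seq_len(n_modes))
  dplyr::bind_cols(
    tibble(subject_id = vapply(surfaces, `[[`, "", "subject_id"),
           mirrored = vapply(surfaces, `[[`, TRUE, "mirrored")),
    as_tibble(S)
  )
}

#' Mode animation frames at +/- k standard deviations
#'
#' @inheritParams dsm_project
#' @param mode Mode index.
#' @param sd_range Score sweep in units of the mode's standard deviation
#'   (default -3..3, the conventional animation range).
#' @param n_frames Number of frames.
#' @return List of M x 3 point matrices.
#' @export
dsm_mode_sweep <- function(model, mode, sd_range = c(-3, 3), n_frames = 7) {
  s <- sqrt(model$variances[mode])
  lapply(seq(sd_range[1], sd_range[2], length.out = n_frames), function(a) {
    sc <- numeric(mode)
    sc[mode] <- a * s
    dsm_reconstruct(model, sc)
  })
}
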