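#' Run the full synthetic asymmetry study end-to-end
#'
#' Simulate a landmarked face cohort, rigidly align it to the template
#' landmark frame, compute dense correspondences for originals and mirrors,
#' fit the dense surface model, compute per-subject SAI against matched
#' controls, detect asymmetry-encoding PCs, run the cohort statistics,
#' simulate a matching regional brain table, adjust/QC it, build the BASI
#' table, and run the repeated LASSO protocol predicting SAI from BASI.
#' Optionally writes every tabular artifact to `out_dir`.
#'
#' @param face_cfg A [face_sim_config()].
#' @param brain_cfg A [brain_sim_config()].
#' @param coverage DSM variance coverage (default 0.99).
#' @param lasso_reps Repetitions of the LASSO protocol.
#' @param lasso_features Clinical features appended to the BASI matrix
#'   (default lesion laterality + epilepsy type); `NULL` for BASI only.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param min_controls Minimum matched controls per SAI reference.
#' @return A `facesym_study` list with every intermediate result.
#' @export
run_study <- function(face_cfg = face_sim_config(),
                      brain_cfg = brain_sim_config(seed = face_cfg$seed + 1),
                      coverage = 0.99, lasso_reps = 200,
                      lasso_features = c("lesion_laterality", "epilepsy_type"),
                      out_dir = NULL, min_controls = 15) {
  sim <- simulate_faces(face_cfg)
  base <- sim$template
  aligned <- procrustes_align(sim$faces, base$landmarks)
  surfaces <- correspond_cohort(base, aligned, include_mirrors = TRUE)
  model <- fit_dsm(surfaces, coverage = coverage)
  scores <- dsm_project_cohort(model, surfaces)
  sai_tab <- sai_cohort(model, surfaces, sim$cohort, min_n = min_controls)
  apcs <- asymmetry_pcs(model, scores)
  group_tests <- compare_sai_groups(sai_tab)
  regression <- sai_regression(sai_tab)

  # brain arm: subjects with epilepsy and a defined SAI (emulating the MRI subset)
  mri <- dplyr::filter(sai_tab, !is.na(.data$sai), .data$group != "CTRL")
  brain <- simulate_brain(brain_cfg, mri$sai, mri)
  adjusted <- adjust_measures(brain$measures, brain$covariates)
  qc <- qc_outliers(adjusted)
  basi <- basi_table(adjusted, qc = qc, manifest = brain_cfg$manifest)
  dur_cor <- duration_correlations(basi, mri)

  feat_cols <- attr(basi, "regions")
  Xraw <- as.matrix(basi[, feat_cols, drop = FALSE])
  rownames(Xraw) <- basi$subject_id
  keep <- complete.cases(Xraw)
  Xraw <- Xraw[keep, , drop = FALSE]
  y <- mri$sai[match(rownames(Xraw), mri$subject_id)]
  X <- normalize_features(Xraw)
  if (!is.null(lasso_features)) {
    X <- augment_features(X, mri[match(rownames(Xraw), mri$subject_id), ],
                          add = lasso_features)
  }
  lasso <- run_protocol(X, y, n_rep = lasso_reps, seed = face_cfg$seed + 2)

  study <- structure(
    list(cohort = sim$cohort, template = base, model = model, scores = scores,
         sai = sai_tab, asymmetry_pcs = apcs, group_tests = group_tests,
         regression = regression, brain = brain, basi = basi,
         qc = qc, duration_correlations = dur_cor, lasso = lasso,
         config = list(face = face_cfg, brain = brain_cfg,
                       coverage = coverage, lasso_reps = lasso_reps)),
    class = "facesym_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.facesym_study <- function(x, ...) {
  cat("<facesym_study> ", nrow(x$cohort), " subjects; DSM: ", x$model$retained,
      " retained modes; ", sum(x$asymmetry_pcs$is_asymmetry_pc),
      " asymmetry PC(s)\n", sep = "")
  invisible(x)
}

#' Write all tabular study artifacts
#'
#' @param study A [run_study()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write.csv(study$cohort, p("cohort.csv"), row.names = FALSE)
  write.csv(dplyr::select(study$sai, -dplyr::any_of("raw_diffs")),
            p("sai.csv"), row.names = FALSE)
  write.csv(study$scores, p("pc_scores.csv"), row.names = FALSE)
  write.csv(study$asymmetry_pcs, p("asymmetry_pcs.csv"), row.names = FALSE)
  write.csv(study$group_tests, p("sai_group_tests.csv"), row.names = FALSE)
  write.csv(study$regression$coefficients, p("sai_regression.csv"), row.names = FALSE)
  write.csv(study$basi, p("basi.csv"), row.names = FALSE)
  write.csv(study$qc, p("qc_flags.csv"), row.names = FALSE)
  write.csv(study$duration_correlations, p("duration_correlations.csv"),
            row.names = FALSE)
  write_protocol_result(study$lasso, json_path = p("lasso_result.json"),
                        csv_path = p("lasso_frequencies.csv"))
  invisible(list.files(out_dir, full.names = TRUE))
}
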