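#' Raw asymmetry field of a face
#'
#' The per-point difference (mm) between the DSM representations of a face
#' and of its mirrored, landmark-relabelled form: both surfaces are projected
#' onto the retained modes and reconstructed, and the reconstructions are
#' subtracted. For a perfectly symmetric face the field is zero.
#'
#' @param model A [fit_dsm()] model trained on originals + mirrors.
#' @param orig,mirr `corresponded_surface` objects for the same subject
#'   (mirr flagged `mirrored`).
#' @return M x 3 displacement matrix (mm).
#' @export
raw_asymmetry <- function(model, orig, mirr) {
  if (!identical(orig$subject_id, mirr$subject_id)) {
    abort(glue::glue("subject mismatch: original '{orig$subject_id}' vs ",
                     "mirror '{mirr$subject_id}'"))
  }
  ro <- dsm_reconstruct(model, dsm_project(model, orig))
  rm_ <- dsm_reconstruct(model, dsm_project(model, mirr))
  ro - rm_
}

#' Signature asymmetry index (SAI) of one subject
#'
#' The raw-asymmetry field is scored as a signature against the
#' raw-asymmetry fields of the subject's age/gender-matched controls: the
#' asymmetry weight is the signature weight of the field, and the SAI is its
#' natural logarithm (on which all cohort statistics run, since the log
#' weight is approximately normal).
#'
#' @param raw_diff M x 3 raw-asymmetry field from [raw_asymmetry()].
#' @param ref A [matched_controls()] reference built from control
#'   raw-asymmetry fields.
#' @param subject_id Subject identifier carried into the record.
#' @return A one-row tibble: `subject_id`, `asym_weight`, `sai`, `flagged`
#'   (`TRUE` when the weight is exactly zero and the SAI undefined).
#' @export
compute_sai <- function(raw_diff, ref, subject_id = NA_character_) {
  sig <- compute_signature(raw_diff, ref)
  w <- sig$weight
  tibble(subject_id = subject_id, asym_weight = w,
         sai = ifelse(w > 0, log(w), NA_real_), flagged = w == 0)
}

#' SAI for a whole cohort
#'
#' Pairs each subject's original and mirrored corresponded surfaces, forms
#' raw-asymmetry fields, builds a matched-control raw-asymmetry reference per
#' subject (controls are the cohort's `CTRL` group; a control subject is
#' never matched against itself), and returns one SAI record per subject
#' joined to the cohort table.
#'
#' @param model A [fit_dsm()] model.
#' @param surfaces List of `corresponded_surface` objects containing, for
#'   every subject, one original and one mirrored surface.
#' @param cohort Cohort tibble with `subject_id`, `age`, `gender`, `group`.
#' @inheritParams matched_controls
#' @return Tibble: cohort columns plus `asym_weight`, `sai`, `flagged`.
#' @export
sai_cohort <- function(model, surfaces, cohort, age_window = 10,
                       widen_step = 5, min_n = 20, sd_floor = 0.01) {
  ids <- vapply(surfaces, `[[`, "", "subject_id")
  mir <- vapply(surfaces, `[[`, TRUE, "mirrored")
  orig_idx <- setNames(which(!mir), ids[!mir])
  mirr_idx <- setNames(which(mir), ids[mir])
  subjects <- intersect(cohort$subject_id, intersect(names(orig_idx), names(mirr_idx)))
  raw_diffs <- lapply(setNames(subjects, subjects), function(sid) {
    raw_asymmetry(model, surfaces[[orig_idx[[sid]]]], surfaces[[mirr_idx[[sid]]]])
  })
  controls <- dplyr::filter(cohort, .data$group == "CTRL",
                            .data$subject_id %in% subjects)
  recs <- lapply(subjects, function(sid) {
    rec <- dplyr::filter(cohort, .data$subject_id == sid)
    ctrl <- dplyr::filter(controls, .data$subject_id != sid)
    ref <- matched_controls(rec, ctrl, raw_diffs[ctrl$subject_id],
                            age_window = age_window, widen_step = widen_step,
                            min_n = min_n, sd_floor = sd_floor)
    compute_sai(raw_diffs[[sid]], ref, subject_id = sid)
  })
  out <- dplyr::left_join(cohort, dplyr::bind_rows(recs), by = "subject_id")
  attr(out, "raw_diffs") <- raw_diffs
  out
}

#' League table of asymmetry-encoding principal components
#'
#' A mode that encodes a common asymmetry has scores that invert sign when
#' the face is reflected, so across subjects the correlation between
#' original-face and reflected-face scores is strongly negative. Each
#' retained PC's Pearson correlation is computed over the chosen subjects and
#' the table is sorted ascending (most negative, i.e. most asymmetric,
#' first); PCs with correlation below `threshold` are flagged as asymmetry
#' PCs. Zero-variance (degenerate) PCs have undefined correlation and are
#' excluded from the league table.
#'
#' @param model A [fit_dsm()] model.
#' @param score_table Tibble from [dsm_project_cohort()] covering originals
#'   and their mirrored forms.
#' @param subjects Optional character vector restricting to a subgroup.
#' @param threshold Flagging threshold on the correlation (default -0.9).
#' @return Tibble: `pc_index`, `orig_reflected_correlation`,
#'   `variance_fraction`, `is_asymmetry_pc`, sorted ascending by correlation.
#' @export
asymmetry_pcs <- function(model, score_table, subjects = NULL, threshold = -0.9) {
  tab <- score_table
  if (!is.null(subjects)) tab <- dplyr::filter(tab, .data$subject_id %in% subjects)
  pc_cols <- grep("^PC", names(tab), value = TRUE)
  orig <- dplyr::arrange(dplyr::filter(tab, !.data$mirrored), .data$subject_id)
  refl <- dplyr::arrange(dplyr::filter(tab, .data$mirrored), .data$subject_id)
  common <- intersect(orig$subject_id, refl$subject_id)
  if (length(common) < 3) {
    abort(glue::glue("need >= 3 subjects with both original and reflected ",
                     "scores; got {length(common)}"))
  }
  orig <- dplyr::filter(orig, .data$subject_id %in% common)
  refl <- dplyr::filter(refl, .data$subject_id %in% common)
  vfrac <- model$variances / sum(model$variances)
  rows <- purrr::map_dfr(seq_along(pc_cols), function(k) {
    o <- orig[[pc_cols[k]]]
    r <- refl[[pc_cols[k]]]
    rho <- if (sd(o) < 1e-12 || sd(r) < 1e-12) NA_real_ else cor(o, r)
    tibble(pc_index = k, orig_reflected_correlation = rho,
           variance_fraction = vfrac[k])
  })
  rows <- dplyr::filter(rows, !is.na(.data$orig_reflected_correlation))
  rows <- dplyr::arrange(rows, .data$orig_reflected_correlation)
  dplyr::mutate(rows, is_asymmetry_pc = .data$orig_reflected_correlation < threshold)
}

#' Lateral asymmetry of a paired left/right length
#'
#' `(R - L) / (R + L)`: unitless, in (-1, 1) for positive lengths, zero for
#' perfect symmetry, antisymmetric in its arguments.
#'
#' @param R,L Right- and left-sided measures (mm), vectorized.
#' @return Unitless asymmetry value(s).
#' @export
#' @examples
#' lateral_asymmetry(3, 1) # 0.5
lateral_asymmetry <- function(R, L) {
  if (any(R + L <= 0)) abort("lateral asymmetry requires R + L > 0")
  (R - L) / (R + L)
}

#' Anthropometric asymmetry measures for asymmetry-PC constructs
#'
#' Computes the paired left/right landmark distances that characterize the
#' main asymmetry-encoding PCs and their `(R - L)/(R + L)` measures:
#' * `nose_deflection` — subnasale to left/right exocanthion (lateral nose
#'   tip deflection),
#' * `nose_mouth` — pronasale to left/right cheilion (nose-mouth rotation),
#' * `eye_depth` — left/right endocanthion to nasion,
#' * `orbit_mouth` — per-side exocanthion-to-cheilion distance (vertical
#'   orbit/mouth displacement).
#'
#' @param lms A [landmark_set()] with the canonical scheme.
#' @param pc_kind One of `"nose_deflection"`, `"nose_mouth"`, `"eye_depth"`,
#'   `"orbit_mouth"`, or a vector of them (default: all four).
#' @return Tibble: `pc_kind`, `L`, `R` (mm), `asymmetry`.
#' @export
pc_asymmetry_measures <- function(lms, pc_kind = c("nose_deflection", "nose_mouth",
                                                   "eye_depth", "orbit_mouth")) {
  defs <- list(
    nose_deflection = list(L = c("subnasale", "exocanthion_L"),
                           R = c("subnasale", "exocanthion_R")),
    nose_mouth = list(L = c("pronasale", "cheilion_L"),
                      R = c("pronasale", "cheilion_R")),
    eye_depth = list(L = c("endocanthion_L", "nasion"),
                     R = c("endocanthion_R", "nasion")),
    orbit_mouth = list(L = c("exocanthion_L", "cheilion_L"),
                       R = c("exocanthion_R", "cheilion_R"))
  )
  unknown <- setdiff(pc_kind, names(defs))
  if (length(unknown) > 0) {
    abort(glue::glue("unknown pc_kind: {paste(unknown, collapse = ', ')}"))
  }
  purrr::map_dfr(pc_kind, function(kind) {
    d <- defs[[kind]]
    L <- landmark_distance(lms, d$L[1], d$L[2])
    R <- landmark_distance(lms, d$R[1], d$R[2])
    tibble(pc_kind = kind, L = L, R = R, asymmetry = lateral_asymmetry(R, L))
  })
}

#' Standard anthropometric lengths
#'
#' Palpebral fissure length (exocanthion-endocanthion, averaged over sides)
#' and nose length (nasion-subnasale), the measures used in case/control
#' anthropometric comparisons.
#'
#' @param lms A [landmark_set()].
#' @return Tibble: `measure`, `value` (mm).
#' @export
anthropometric_lengths <- function(lms) {
  pf <- mean(c(landmark_distance(lms, "exocanthion_L", "endocanthion_L"),
               landmark_distance(lms, "exocanthion_R", "endocanthion_R")))
  nl <- landmark_distance(lms, "nasion", "subnasale")
  tibble(measure = c("palpebral_fissure_length", "nose_length"),
         value = c(pf, nl))
}
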