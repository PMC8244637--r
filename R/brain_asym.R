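#' The packaged 51-region BASI manifest
#'
#' One row per paired left/right brain region contributing a BASI feature:
#' 31 Desikan-Killiany cortical regions (thickness), 8 subcortical volumes
#' and 12 hippocampal-subfield volumes. The atlas literature does not fix a
#' unique 51-pair composition, so this manifest is a documented package
#' choice and every function taking a manifest accepts a user override.
#'
#' @return Tibble: `region`, `measure`, `class`.
#' @export
basi_region_manifest <- function() {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal"
  )
  subcortical <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
                   "amygdala", "accumbens", "ventraldc")
  subfields <- c("CA1", "CA3", "CA4", "GC_ML_DG", "HATA", "fimbria",
                 "hippocampal_fissure", "hippocampal_tail",
                 "molecular_layer_HP", "parasubiculum", "presubiculum",
                 "subiculum")
  dplyr::bind_rows(
    tibble(region = cortical, measure = "thickness", class = "cortical"),
    tibble(region = subcortical, measure = "volume", class = "subcortical"),
    tibble(region = subfields, measure = "volume", class = "hippocampal_subfield")
  )
}

check_measure_table <- function(measures) {
  need <- c("subject_id", "region", "hemisphere", "measure", "value")
  miss <- setdiff(need, names(measures))
  if (length(miss) > 0) {
    abort(glue::glue("measure table missing column(s): {paste(miss, collapse = ', ')}"))
  }
  bad <- setdiff(unique(measures$hemisphere), c("left", "right"))
  if (length(bad) > 0) {
    abort(glue::glue("hemisphere must be 'left'/'right'; found: {paste(bad, collapse = ', ')}"))
  }
  invisible(measures)
}

#' Adjust regional brain measures for covariates
#'
#' For every (region, hemisphere, measure) cell, fits
#' `value ~ icv + age + sex + scanner` by ordinary least squares and replaces
#' the value with its residual re-centred at the covariate means (fitted
#' value at the mean design row), which keeps the adjusted values on the
#' original positive scale so downstream asymmetry-index denominators remain
#' meaningful. Aliased (rank-deficient) dummy columns are dropped with a
#' warning.
#'
#' @param measures Long tibble: `subject_id`, `region`, `hemisphere`
#'   (left/right), `measure` (thickness/area/volume), `value`.
#' @param covariates Tibble: `subject_id`, `icv`, `age`, `sex`, `scanner`.
#' @return The measure table with `value` replaced by the adjusted value.
#' @export
adjust_measures <- function(measures, covariates) {
  check_measure_table(measures)
  miss <- setdiff(unique(measures$subject_id), covariates$subject_id)
  if (length(miss) > 0) {
    abort(glue::glue("covariates missing for subject(s): ",
                     "{paste(head(miss, 5), collapse = ', ')}"))
  }
  covariates <- dplyr::mutate(covariates,
                              sex = factor(.data$sex),
                              scanner = factor(.data$scanner))
  df <- dplyr::left_join(measures, covariates, by = "subject_id")
  dplyr::mutate(
    dplyr::group_by(df, .data$region, .data$hemisphere, .data$measure),
    value = adjust_cell(.data$value, .data$icv, .data$age, .data$sex, .data$scanner),
    .keep = "all"
  ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(measures)))
}

adjust_cell <- function(value, icv, age, sex, scanner) {
  dat <- data.frame(icv = icv, age = age,
                    sex = droplevels(factor(sex)),
                    scanner = droplevels(factor(scanner)))
  keep <- c("icv", "age",
            if (nlevels(dat$sex) > 1) "sex",
            if (nlevels(dat$scanner) > 1) "scanner")
  X <- model.matrix(stats::reformulate(c("1", keep)), dat)
  fit <- stats::lm.fit(X, value)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warn(glue::glue("dropping aliased covariate column(s): ",
                    "{paste(names(beta)[is.na(beta)], collapse = ', ')}"))
    beta[is.na(beta)] <- 0
  }
  fitted_at_mean <- drop(colMeans(X) %*% beta)
  unname(value - drop(X %*% beta) + fitted_at_mean)
}

#' Flag regional-measure outliers by cohort z-score
#'
#' ENIGMA-style automated quality control: within every (region, hemisphere,
#' measure) cell, values with |z| at or beyond `z_threshold` (default 4.7,
#' either direction, boundary inclusive) are flagged for manual review and
#' downstream exclusion. Cells with zero dispersion yield no flags (with a
#' warning).
#'
#' @inheritParams adjust_measures
#' @param z_threshold Inclusive |z| flagging threshold (default 4.7).
#' @return Tibble: measure-table keys plus `z` and `flagged`.
#' @export
qc_outliers <- function(measures, z_threshold = 4.7) {
  check_measure_table(measures)
  n_min <- min(dplyr::count(dplyr::group_by(
    measures, .data$region, .data$hemisphere, .data$measure))$n)
  if (n_min < 10) {
    warn(glue::glue("fewer than 10 subjects in some region cells (min {n_min}); ",
                    "z-scores may be unstable"))
  }
  out <- dplyr::mutate(
    dplyr::group_by(measures, .data$region, .data$hemisphere, .data$measure),
    z = {
      s <- sd(.data$value)
      if (is.na(s) || s == 0) rep(NA_real_, length(.data$value))
      else (.data$value - mean(.data$value)) / s
    }
  ) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = !is.na(.data$z) & abs(.data$z) >= z_threshold)
  if (anyNA(out$z)) warn("zero-dispersion region cell(s): no QC flags assigned there")
  dplyr::select(out, dplyr::all_of(c("subject_id", "region", "hemisphere",
                                     "measure", "z", "flagged")))
}

#' Brain asymmetry index of a left/right measure pair
#'
#' `(left - right) / ((left + right)/2)`: unitless, in \[-2, 2\] for positive
#' measures, antisymmetric under hemisphere swap, invariant to common
#' rescaling of both hemispheres.
#'
#' @param left,right Regional measures (vectorized); their average must be
#'   positive.
#' @return Unitless BASI value(s).
#' @export
#' @examples
#' compute_basi(3, 1) # 1
compute_basi <- function(left, right) {
  avg <- (left + right) / 2
  if (any(avg <= 0, na.rm = TRUE)) {
    abort("BASI undefined: non-positive left/right average")
  }
  (left - right) / avg
}

#' Subject-by-region BASI table
#'
#' Computes one BASI per paired region per subject from covariate-adjusted
#' measures, excluding QC-flagged cells (a flagged hemisphere makes that
#' subject-region BASI missing, never imputed). Two cohort-level summary
#' columns are added when hemispheric summary rows are present (or derivable
#' from regional thickness): the BASI of hemispheric average cortical
#' thickness and of hemispheric total surface area; the mean of regional
#' thickness BASIs is exposed alongside as an alternative summary.
#'
#' @param adjusted Adjusted measure table from [adjust_measures()].
#' @param qc Optional QC table from [qc_outliers()]; flagged cells excluded.
#' @param manifest Region manifest (default [basi_region_manifest()]).
#' @param summary_regions Named character vector locating hemispheric summary
#'   rows in the measure table (`thickness` and `area` entries).
#' @return A `basi_table`: tibble with `subject_id`, one column per manifest
#'   region, plus `total_thickness_basi`, `total_area_basi`,
#'   `mean_regional_thickness_basi`.
#' @export
basi_table <- function(adjusted, qc = NULL,
                       manifest = basi_region_manifest(),
                       summary_regions = c(thickness = "hemisphere_average_thickness",
                                           area = "hemisphere_total_area")) {
  check_measure_table(adjusted)
  df <- adjusted
  if (!is.null(qc)) {
    df <- dplyr::left_join(df, dplyr::select(qc, -dplyr::any_of("z")),
                           by = c("subject_id", "region", "hemisphere", "measure"))
    df <- dplyr::filter(df, !isTRUE_vec(.data$flagged))
  }
  wide <- tidyr::pivot_wider(df, id_cols = c("subject_id", "region", "measure"),
                             names_from = "hemisphere", values_from = "value")
  if (!"left" %in% names(wide)) wide$left <- NA_real_
  if (!"right" %in% names(wide)) wide$right <- NA_real_
  wide <- dplyr::mutate(wide, basi = ifelse(
    is.na(.data$left) | is.na(.data$right), NA_real_,
    compute_basi(.data$left, .data$right)))

  reg <- dplyr::semi_join(wide, manifest, by = c("region", "measure"))
  mat <- tidyr::pivot_wider(
    dplyr::select(reg, dplyr::all_of(c("subject_id", "region", "basi"))),
    names_from = "region", values_from = "basi")
  # keep manifest column order; regions absent from the data are dropped
  cols <- intersect(manifest$region, names(mat))
  mat <- dplyr::select(mat, dplyr::all_of(c("subject_id", cols)))

  thick_regions <- manifest$region[manifest$measure == "thickness"]
  mat$mean_regional_thickness_basi <-
    rowMeans(as.matrix(mat[, intersect(thick_regions, cols), drop = FALSE]),
             na.rm = TRUE)
  for (kind in c("thickness", "area")) {
    colname <- paste0("total_", kind, "_basi")
    srow <- dplyr::filter(wide, .data$region == summary_regions[[kind]])
    if (nrow(srow) > 0) {
      mat <- dplyr::left_join(
        mat, setNames(dplyr::select(srow, dplyr::all_of(c("subject_id", "basi"))),
                      c("subject_id", colname)),
        by = "subject_id")
    } else if (kind == "thickness") {
      # fall back: BASI of the mean regional thickness per hemisphere
      hemi <- dplyr::summarise(
        dplyr::group_by(dplyr::filter(wide, .data$region %in% thick_regions),
                        .data$subject_id),
        basi = compute_basi(mean(.data$left, na.rm = TRUE),
                            mean(.data$right, na.rm = TRUE)))
      mat <- dplyr::left_join(mat, setNames(hemi, c("subject_id", colname)),
                              by = "subject_id")
    } else {
      mat[[colname]] <- NA_real_
    }
  }
  structure(mat, regions = cols, class = c("basi_table", class(mat)))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Pearson correlation of illness duration with summary BASI
#'
#' Correlates duration of illness with the BASI of hemispheric average
#' cortical thickness and of total surface area, listwise-excluding subjects
#' with missing duration.
#'
#' @param basi A [basi_table()].
#' @param cohort Cohort tibble with `subject_id` and `duration`.
#' @return Tibble: `summary_measure`, `r`, `p`, `n`.
#' @export
duration_correlations <- function(basi, cohort) {
  df <- dplyr::left_join(
    dplyr::select(cohort, dplyr::all_of(c("subject_id", "duration"))),
    basi, by = "subject_id")
  purrr::map_dfr(c("total_thickness_basi", "total_area_basi"), function(col) {
    ok <- complete.cases(df$duration, df[[col]])
    if (sum(ok) < 3) abort(glue::glue("fewer than 3 complete cases for {col}"))
    x <- df$duration[ok]
    y <- df[[col]][ok]
    if (sd(x) == 0) abort("duration is constant: correlation undefined")
    ct <- cor.test(x, y, method = "pearson")
    tibble(summary_measure = col, r = unname(ct$estimate),
           p = ct$p.value, n = sum(ok))
  })
}
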