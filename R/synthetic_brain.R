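#' Simulation configuration for synthetic regional brain measures
#'
#' Emulates a FreeSurfer-style long-format regional measure table for the 51
#' paired BASI regions plus two hemispheric summary regions (average
#' cortical thickness and total surface area), with subject covariates (ICV,
#' age, sex, scanner) injected as known linear effects that cancel between
#' hemispheres, independent per-hemisphere measurement noise, an optional
#' planted negative correlation between illness duration and the summary
#' thickness asymmetry, an optional planted sparse link from chosen BASI
#' regions to the SAI, and optional injected outliers.
#'
#' @param duration_rho Planted correlation between duration and the
#'   hemispheric-average-thickness asymmetry (default -0.2, i.e. thinning of
#'   the relatively thicker hemisphere with longer illness).
#' @param planted_regions Regions whose asymmetry is linked to the SAI
#'   (default none: facial and brain asymmetry uncoupled).
#' @param planted_snr Signal-to-noise ratio of the planted SAI link
#'   (variance ratio; the planted column's correlation with the SAI is
#'   `sqrt(snr/(1+snr))`).
#' @param asym_sd SD of the baseline per-region asymmetry (unitless BASI
#'   scale, default 0.02).
#' @param noise_frac Per-hemisphere measurement noise as a fraction of the
#'   regional baseline (default 0.01).
#' @param n_scanners Number of scanner levels.
#' @param outliers Optional tibble (`subject_id`, `region`, `hemisphere`,
#'   `z`) of values to displace to the given cohort z-score after generation.
#' @param manifest Region manifest, see [basi_region_manifest()].
#' @param seed Master seed.
#' @return A `brain_sim_config` list.
#' @export
brain_sim_config <- function(duration_rho = -0.2,
                             planted_regions = character(0),
                             planted_snr = 5,
                             asym_sd = 0.02,
                             noise_frac = 0.01,
                             n_scanners = 3,
                             outliers = NULL,
                             manifest = basi_region_manifest(),
                             seed = 1) {
  stopifnot(abs(duration_rho) <= 1, planted_snr >= 0, asym_sd > 0)
  if (!all(planted_regions %in% manifest$region)) {
    abort("planted_regions must be rows of the region manifest")
  }
  structure(list(duration_rho = duration_rho, planted_regions = planted_regions,
                 planted_snr = planted_snr, asym_sd = asym_sd,
                 noise_frac = noise_frac, n_scanners = n_scanners,
                 outliers = outliers, manifest = manifest, seed = seed),
            class = "brain_sim_config")
}

#' Simulate regional brain measures consistent with a given SAI vector
#'
#' Generates, per subject and paired region, strictly positive left/right
#' measures whose asymmetry carries the configured planted structure (see
#' [brain_sim_config()]). Covariate effects are identical in both
#' hemispheres so they perturb raw values but not the true asymmetry;
#' [adjust_measures()] should remove them.
#'
#' @param cfg A [brain_sim_config()].
#' @param sai Numeric SAI vector, one per subject.
#' @param cohort Cohort tibble supplying `subject_id`, `age`, `gender`,
#'   `duration` for the same subjects (row-aligned with `sai`).
#' @return List: `measures` (long tibble), `covariates` (tibble),
#'   `true_asym` (subject x region matrix of planted asymmetries).
#' @export
simulate_brain <- function(cfg, sai, cohort) {
  if (length(sai) != nrow(cohort)) abort("sai length must equal nrow(cohort)")
  set.seed(cfg$seed)
  n <- nrow(cohort)
  man <- cfg$manifest
  regions <- c(man$region, "hemisphere_average_thickness", "hemisphere_total_area")
  measure_of <- c(setNames(man$measure, man$region),
                  hemisphere_average_thickness = "thickness",
                  hemisphere_total_area = "area")
  baseline <- c(
    setNames(ifelse(man$measure == "thickness",
                    rnorm(nrow(man), 2.5, 0.15),
                    exp(rnorm(nrow(man), log(2000), 0.5))), man$region),
    hemisphere_average_thickness = 2.5,
    hemisphere_total_area = 90000
  )

  s_sai <- if (sd(sai, na.rm = TRUE) > 0) {
    s <- (sai - mean(sai, na.rm = TRUE)) / sd(sai, na.rm = TRUE)
    ifelse(is.na(s), 0, s)
  } else rep(0, n)
  s_dur <- rep(0, n)
  ok <- !is.na(cohort$duration)
  if (sum(ok) > 2 && sd(cohort$duration[ok]) > 0) {
    s_dur[ok] <- (cohort$duration[ok] - mean(cohort$duration[ok])) /
      sd(cohort$duration[ok])
  }

  w_link <- sqrt(cfg$planted_snr / (1 + cfg$planted_snr))
  A <- matrix(rnorm(n * length(regions)), n,
              dimnames = list(cohort$subject_id, regions))
  for (r in cfg$planted_regions) {
    A[, r] <- w_link * s_sai + sqrt(1 - w_link^2) * rnorm(n)
  }
  rho <- cfg$duration_rho
  A[, "hemisphere_average_thickness"] <-
    rho * s_dur + sqrt(1 - rho^2) * rnorm(n)
  A <- cfg$asym_sd * A

  covariates <- tibble(
    subject_id = cohort$subject_id,
    icv = rnorm(n, 1.5e6, 1.2e5),
    age = cohort$age,
    sex = cohort$gender,
    scanner = sample(paste0("scanner", seq_len(cfg$n_scanners)), n, replace = TRUE)
  )
  scanner_off <- setNames(seq_len(cfg$n_scanners) - (cfg$n_scanners + 1) / 2,
                          paste0("scanner", seq_len(cfg$n_scanners))) * 0.02
  # covariate effect, as a multiplicative factor common to both hemispheres
  cov_factor <- 1 - 0.002 * (covariates$age - mean(covariates$age)) +
    0.02 * (covariates$sex == "M") +
    scanner_off[covariates$scanner] +
    0.05 * (covariates$icv - mean(covariates$icv)) / sd(covariates$icv)

  rows <- purrr::map_dfr(regions, function(r) {
    b <- baseline[[r]]
    subj_scale <- 1 + rnorm(n, 0, 0.04)
    core <- b * subj_scale * cov_factor
    eps_l <- rnorm(n, 0, cfg$noise_frac * b)
    eps_r <- rnorm(n, 0, cfg$noise_frac * b)
    tibble(
      subject_id = rep(cohort$subject_id, 2),
      region = r,
      hemisphere = rep(c("left", "right"), each = n),
      measure = measure_of[[r]],
      value = c(core * (1 + A[, r] / 2) + eps_l,
                core * (1 - A[, r] / 2) + eps_r)
    )
  })
  if (!is.null(cfg$outliers)) {
    for (i in seq_len(nrow(cfg$outliers))) {
      o <- cfg$outliers[i, ]
      cell <- rows$region == o$region & rows$hemisphere == o$hemisphere
      hit <- cell & rows$subject_id == o$subject_id
      if (!any(hit)) abort("outlier request does not match any generated cell")
      # solve for the displaced value so that its *post-injection* cohort
      # z-score equals the requested z (the injected point shifts the cell
      # mean and inflates the SD, which caps the achievable z near sqrt(n))
      others <- rows$value[cell & !hit]
      nn <- length(others) + 1
      z_of <- function(x) {
        v <- c(others, x)
        (x - mean(v)) / sd(v)
      }
      z_max <- (nn - 1) / sqrt(nn)
      if (abs(o$z) >= z_max) {
        abort(glue::glue("requested outlier z = {o$z} is unreachable for a ",
                         "cohort of {nn} (max |z| = {round(z_max, 2)})"))
      }
      m0 <- mean(others); s0 <- sd(others)
      lim <- if (o$z >= 0) c(m0, m0 + 1e3 * s0 * nn) else c(m0 - 1e3 * s0 * nn, m0)
      rows$value[hit] <- stats::uniroot(function(x) z_of(x) - o$z,
                                        lim, tol = 1e-12)$root
    }
  }
  if (any(rows$value <= 0)) {
    warn("some generated measures are non-positive; consider smaller noise")
  }
  list(measures = rows, covariates = covariates, true_asym = A)
}
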