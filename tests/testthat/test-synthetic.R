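test_that("the template is an exactly symmetric, valid disk mesh", {
  tmpl <- make_template(2000)
  expect_equal(nrow(tmpl$vertices), 2000)
  # exact mirror symmetry, vertices and landmarks
  mi <- mirror_index(tmpl)
  refl <- ref_reflect_field(tmpl$vertices, mi)
  expect_identical(unname(refl), unname(tmpl$vertices))
  lms <- unclass(tmpl$landmarks)
  expect_identical(unname(lms["cheilion_L", ] * c(-1, 1, 1)),
                   unname(lms["cheilion_R", ]))
  expect_true(all(lms[c("nasion", "pronasale", "subnasale", "gnathion"), 1] == 0))
  # Euler characteristic of a disk: V - E + F = 1
  tr <- tmpl$triangles
  edges <- unique(rbind(t(apply(tr[, 1:2], 1, sort)),
                        t(apply(tr[, 2:3], 1, sort)),
                        t(apply(tr[, c(1, 3)], 1, sort))))
  expect_equal(nrow(tmpl$vertices) - nrow(edges) + nrow(tr), 1)
  expect_error(make_template(200), "M >= 500")
})

test_that("simulated mode fields have exact mirror parity", {
  tmpl <- cached_template(600)
  sim <- simulate_faces(face_sim_config(M = 600, n_per_group = c(CTRL = 3),
                                        seed = 71), template = tmpl)
  mi <- mirror_index(tmpl)
  for (m in sim$modes$sym) {
    expect_identical(ref_reflect_field(m, mi), m)
  }
  for (m in sim$modes$asym) {
    expect_identical(ref_reflect_field(m, mi), -m)
  }
  # unit RMS normalization
  for (m in c(sim$modes$sym, sim$modes$asym)) {
    expect_equal(mean(rowSums(m^2)), 1, tolerance = 1e-12)
  }
})

test_that("face simulation is reproducible and honours the cohort config", {
  cfg <- face_sim_config(M = 600, n_per_group = c(CTRL = 5, FS = 4, IGE = 2),
                         seed = 72)
  s1 <- simulate_faces(cfg)
  s2 <- simulate_faces(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$faces[[3]]$vertices, s2$faces[[3]]$vertices)
  expect_equal(nrow(s1$cohort), 11)
  expect_equal(as.vector(table(s1$cohort$group)[c("CTRL", "FS", "IGE")]),
               c(5L, 4L, 2L))
  expect_true(all(s1$cohort$age >= 18 & s1$cohort$age <= 77))
  ok <- !is.na(s1$cohort$duration)
  expect_true(all(s1$cohort$duration[ok] <= s1$cohort$age[ok]))
  expect_true(all(is.na(s1$cohort$duration[s1$cohort$group == "CTRL"])))
  expect_true(all(s1$cohort$lesion_side[s1$cohort$group != "FS"] == "none"))
  expect_error(face_sim_config(n_per_group = c(XX = 3)), "group names")
})

test_that("a degenerate noise-free configuration reproduces the template", {
  tmpl <- cached_template(600)
  cfg <- face_sim_config(M = 600, n_per_group = c(CTRL = 8),
                         sym_sd = 0, asym_sd = 0,
                         delta = c(CTRL = 0, FC = 0, FS = 0, IGE = 0),
                         noise_sd = 0,
                         pose_sd = c(rotation = 0, translation = 0), seed = 73)
  sim <- simulate_faces(cfg, template = tmpl)
  for (f in sim$faces) {
    expect_equal(f$vertices, tmpl$vertices, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # every corresponded surface reproduces the template point-for-point
  surf <- correspond_cohort(tmpl, sim$faces)
  for (s in surf[c(1, 9)]) {
    expect_equal(s$points, tmpl$vertices, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("brain simulation is reproducible, positive and plants its signals", {
  set.seed(74)
  n <- 150
  cohort <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                           age = runif(n, 18, 77),
                           gender = sample(c("F", "M"), n, TRUE),
                           duration = runif(n, 1, 40))
  sai <- rnorm(n, 5, 0.3)
  cfg <- brain_sim_config(planted_regions = c("entorhinal", "fimbria", "pallidum"),
                          planted_snr = 5, seed = 75)
  b1 <- simulate_brain(cfg, sai, cohort)
  b2 <- simulate_brain(cfg, sai, cohort)
  expect_identical(b1$measures, b2$measures)
  expect_true(all(b1$measures$value > 0))
  expect_equal(nrow(b1$measures), n * 2 * 53) # 51 regions + 2 summaries
  # planted SAI link: the three linked columns correlate with SAI
  for (r in cfg$planted_regions) {
    expect_gt(cor(b1$true_asym[, r], sai), 0.8)
  }
  # planted duration link on the thickness summary column
  expect_lt(cor(b1$true_asym[, "hemisphere_average_thickness"], cohort$duration),
            -0.05)
  expect_error(brain_sim_config(planted_regions = "nonexistent_region"),
               "manifest")
})

test_that("an injected outlier is flagged by QC at its planted location", {
  set.seed(76)
  n <- 60
  cohort <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                           age = runif(n, 18, 77),
                           gender = sample(c("F", "M"), n, TRUE),
                           duration = runif(n, 1, 30))
  out_spec <- tibble::tibble(subject_id = "s007", region = "pallidum",
                             hemisphere = "left", z = 6)
  cfg <- brain_sim_config(outliers = out_spec, seed = 77)
  b <- simulate_brain(cfg, rnorm(n, 5, 0.3), cohort)
  qc <- qc_outliers(b$measures, z_threshold = 4.7)
  hit <- qc[qc$flagged, ]
  expect_true(any(hit$subject_id == "s007" & hit$region == "pallidum" &
                    hit$hemisphere == "left"))
})

test_that("a null duration slope gives correlations centred on zero", {
  set.seed(78)
  rs <- vapply(1:10, function(i) {
    n <- 100
    cohort <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                             age = runif(n, 18, 77),
                             gender = sample(c("F", "M"), n, TRUE),
                             duration = runif(n, 1, 40))
    b <- simulate_brain(brain_sim_config(duration_rho = 0, seed = i),
                        rnorm(n, 5, 0.3), cohort)
    adj <- adjust_measures(b$measures, b$covariates)
    tab <- basi_table(adj)
    duration_correlations(tab, cohort)$r[1]
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("adjustment then BASI is a no-op on covariate-free synthetic data", {
  set.seed(79)
  n <- 40
  cohort <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                           age = runif(n, 18, 77),
                           gender = sample(c("F", "M"), n, TRUE),
                           duration = runif(n, 1, 30))
  b <- simulate_brain(brain_sim_config(seed = 80), rnorm(n, 5, 0.3), cohort)
  flat <- dplyr::mutate(b$covariates, icv = 1.5e6, age = 40, sex = "F",
                        scanner = "s1")
  adj <- suppressWarnings(adjust_measures(b$measures, flat))
  t1 <- basi_table(adj)
  t2 <- basi_table(b$measures)
  expect_equal(as.matrix(t1[, attr(t1, "regions")]),
               as.matrix(t2[, attr(t2, "regions")]), tolerance = 1e-10)
})

test_that("study drivers produce tidy summaries, plots and artifacts", {
  tmpl <- cached_template(600)
  study <- run_study(
    face_cfg = face_sim_config(M = 600,
                               n_per_group = c(CTRL = 26, FS = 16, FC = 8, IGE = 4),
                               seed = 81),
    lasso_reps = 5, min_controls = 8,
    out_dir = withr::local_tempdir())
  expect_s3_class(study, "facesym_study")
  # tidiers
  td <- tidy(study$model)
  expect_equal(sum(td$retained), study$model$retained)
  expect_equal(glance(study$model)$coverage_achieved,
               sum(study$model$variances[1:study$model$retained]) /
                 sum(study$model$variances))
  expect_named(tidy(study$regression),
               c("term", "estimate", "std_error", "statistic", "p_value",
                 "conf_low", "conf_high"))
  expect_equal(glance(study$lasso)$n_rep, 5)
  expect_equal(tidy(study$lasso), study$lasso$selection_frequency)
  # plots build without evaluation errors
  expect_s3_class(plot_sai_groups(study$sai), "ggplot")
  expect_s3_class(autoplot(study$lasso), "ggplot")
  expect_s3_class(autoplot(study$model), "ggplot")
})
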