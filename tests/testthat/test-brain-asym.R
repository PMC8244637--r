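make_measures <- function(values, region = "precentral", measure = "thickness") {
  n <- length(values) / 2
  tibble::tibble(
    subject_id = rep(sprintf("s%03d", seq_len(n)), 2),
    region = region,
    hemisphere = rep(c("left", "right"), each = n),
    measure = measure,
    value = values)
}

flat_covariates <- function(ids) {
  tibble::tibble(subject_id = ids, icv = 1.5e6, age = 40, sex = "F",
                 scanner = "scanner1")
}

test_that("adjustment is a no-op when covariates carry no information", {
  set.seed(31)
  m <- make_measures(rnorm(40, 2.5, 0.1))
  adj <- suppressWarnings(adjust_measures(m, flat_covariates(unique(m$subject_id))))
  expect_equal(adj$value, m$value, tolerance = 1e-12)
})

test_that("a planted linear age effect is removed exactly", {
  set.seed(32)
  n <- 30
  ids <- sprintf("s%03d", 1:n)
  cov <- tibble::tibble(subject_id = ids, icv = rnorm(n, 1.5e6, 1e5),
                        age = runif(n, 20, 70),
                        sex = sample(c("F", "M"), n, TRUE),
                        scanner = sample(c("a", "b"), n, TRUE))
  base <- rnorm(n, 2.5, 0.05)
  beta_age <- 0.01
  vals <- c(base + beta_age * cov$age, base + beta_age * cov$age)
  adj <- adjust_measures(make_measures(vals), cov)
  lhs <- adj$value[adj$hemisphere == "left"]
  # zero-noise planted effect: residual slope against age is numerically zero
  slope <- coef(lm(lhs ~ cov$age))[2]
  expect_lt(abs(slope), 1e-10)
  # values stay on the original positive scale (centred at the same mean)
  expect_equal(mean(lhs), mean(vals[1:n]), tolerance = 1e-10)
})

test_that("a planted scanner offset is removed by adjustment", {
  set.seed(33)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  scanner <- rep(c("sc1", "sc2"), each = n / 2)
  cov <- tibble::tibble(subject_id = ids, icv = rnorm(n, 1.5e6, 1e5),
                        age = runif(n, 20, 70), sex = "F", scanner = scanner)
  delta <- 0.4
  vals0 <- rnorm(n, 2.5, 0.05) + delta * (scanner == "sc2")
  adj <- suppressWarnings(
    adjust_measures(make_measures(c(vals0, vals0)), cov))
  lhs <- adj$value[adj$hemisphere == "left"]
  gap <- mean(lhs[scanner == "sc2"]) - mean(lhs[scanner == "sc1"])
  expect_lt(abs(gap), 0.02)
})

test_that("QC flags at the inclusive 4.7 boundary, in either direction", {
  # construct a cohort whose extreme member's sample z-score is exactly 4.7:
  # values (t, -t, 3x(u, -u), 0...) have exact zero mean, and u < t is tuned
  # so the extreme value's computed z lands on the representable value 4.7
  n <- 100
  base <- function(u, t = 1) c(t, -t, rep(c(u, -u), 3), rep(0, n - 8))
  u0 <- sqrt(((n - 1) / 4.7^2 - 2) / 6)
  u <- NA
  for (k in -40:40) {
    cand <- u0 * (1 + k * .Machine$double.eps)
    v <- base(cand)
    if ((v[1] - mean(v)) / sd(v) == 4.7) { u <- cand; break }
  }
  expect_false(is.na(u)) # a representable exact-boundary fixture exists
  v <- base(u)
  qc <- suppressWarnings(qc_outliers(make_measures(c(v, rnorm(n, 0, 1e-3)))))
  left <- qc[qc$hemisphere == "left", ]
  expect_identical(left$z[1], 4.7)
  expect_true(left$flagged[1])   # z = +4.7: flagged (inclusive)
  expect_true(left$flagged[2])   # z = -4.7: either direction
  expect_false(any(left$flagged[-(1:2)])) # the u entries sit well inside
  # just below the boundary (z is scale-free, so widen the spread instead)
  u469 <- sqrt(((n - 1) / 4.69^2 - 2) / 6)
  v469 <- base(u469)
  z469 <- (v469[1] - mean(v469)) / sd(v469)
  expect_lt(z469, 4.7)
  qc2 <- suppressWarnings(qc_outliers(make_measures(c(v469, rnorm(n, 0, 1e-3)))))
  expect_false(qc2$flagged[qc2$hemisphere == "left"][1])
})

test_that("zero-dispersion cells warn and yield no flags", {
  m <- make_measures(rep(2.5, 40))
  expect_warning(qc <- qc_outliers(m), "zero-dispersion")
  expect_false(any(qc$flagged))
})

test_that("QC flags are invariant to affine rescaling of a region", {
  set.seed(34)
  v <- rnorm(50)
  v[7] <- 6
  m1 <- make_measures(c(v, rnorm(50)))
  m2 <- m1
  m2$value[m2$hemisphere == "left"] <- 3 * m2$value[m2$hemisphere == "left"] + 10
  q1 <- suppressWarnings(qc_outliers(m1))
  q2 <- suppressWarnings(qc_outliers(m2))
  expect_identical(q1$flagged, q2$flagged)
})

test_that("BASI follows its defining formula and symmetries", {
  expect_identical(compute_basi(2.5, 2.5), 0)
  expect_identical(compute_basi(3, 1), 1)
  set.seed(35)
  l <- runif(50, 0.5, 5)
  r <- runif(50, 0.5, 5)
  expect_equal(compute_basi(l, r), -compute_basi(r, l), tolerance = 1e-14)
  expect_equal(compute_basi(3.7 * l, 3.7 * r), compute_basi(l, r),
               tolerance = 1e-12)
  expect_true(all(abs(compute_basi(l, r)) < 2))
  expect_error(compute_basi(1, -1), "non-positive")
})

test_that("the BASI table reproduces planted asymmetries region by region", {
  man <- basi_region_manifest()
  expect_equal(nrow(man), 51)
  n <- 12
  ids <- sprintf("s%03d", 1:n)
  rows <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
    tibble::tibble(subject_id = rep(ids, 2), region = man$region[i],
                   hemisphere = rep(c("left", "right"), each = n),
                   measure = man$measure[i],
                   value = rep(c(1.02, 1.00), each = n) *
                     ifelse(man$measure[i] == "thickness", 2.5, 1500))
  })
  tab <- basi_table(rows, manifest = man)
  expect_equal(length(attr(tab, "regions")), 51)
  vals <- as.matrix(tab[, attr(tab, "regions")])
  expect_equal(unname(vals), matrix(0.02 / 1.01, n, 51), tolerance = 1e-12)
  # hemispheric mean fallback gives the same uniform value
  expect_equal(tab$total_thickness_basi, rep(0.02 / 1.01, n), tolerance = 1e-12)
  # perfectly symmetric brain: all zero
  sym <- dplyr::mutate(rows, value = ifelse(.data$measure == "thickness", 2.5, 1500))
  tab0 <- basi_table(sym, manifest = man)
  expect_true(all(as.matrix(tab0[, attr(tab0, "regions")]) == 0))
})

test_that("QC-excluded and missing hemispheres become missing BASI cells", {
  man <- basi_region_manifest()[1:3, ]
  n <- 10
  ids <- sprintf("s%03d", 1:n)
  rows <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(subject_id = rep(ids, 2), region = man$region[i],
                   hemisphere = rep(c("left", "right"), each = n),
                   measure = man$measure[i], value = rnorm(2 * n, 2.5, 0.05))
  })
  # drop one hemisphere row entirely
  rows <- rows[-1, ]
  qc <- tibble::tibble(subject_id = ids[2], region = man$region[2],
                       hemisphere = "right", measure = man$measure[2],
                       flagged = TRUE)
  tab <- basi_table(rows, qc = qc, manifest = man)
  expect_true(is.na(tab[[man$region[1]]][tab$subject_id == ids[1]]))
  expect_true(is.na(tab[[man$region[2]]][tab$subject_id == ids[2]]))
  expect_false(anyNA(tab[[man$region[3]]]))
})

test_that("duration correlations recover planted and null associations", {
  set.seed(36)
  n <- 200
  cohort <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                           duration = runif(n, 1, 40))
  sdur <- scale(cohort$duration)[, 1]
  rho <- -0.2
  tab <- tibble::tibble(
    subject_id = cohort$subject_id,
    total_thickness_basi = 0.02 * (rho * sdur + sqrt(1 - rho^2) * rnorm(n)),
    total_area_basi = 0.02 * rnorm(n))
  class(tab) <- c("basi_table", class(tab))
  out <- duration_correlations(tab, cohort)
  r_th <- out$r[out$summary_measure == "total_thickness_basi"]
  r_ar <- out$r[out$summary_measure == "total_area_basi"]
  expect_lt(abs(r_th - rho), 2 / sqrt(n)) # within the sampling CI
  expect_lt(abs(r_ar), 2 / sqrt(n))
  cohort$duration <- 10
  expect_error(duration_correlations(tab, cohort), "constant")
})
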