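test_that("group comparisons report t-tests, ANOVA and Bonferroni", {
  set.seed(41)
  df <- tibble::tibble(
    sai = c(rnorm(30, 5.0, 0.3), rnorm(30, 5.0, 0.3), rnorm(30, 5.3, 0.3)),
    group = rep(c("CTRL", "FC", "FS"), each = 30))
  out <- compare_sai_groups(df)
  expect_equal(sum(out$test == "t-test"), 3)
  expect_equal(sum(out$test == "anova"), 1)
  # Bonferroni multiplies by the number of pairwise comparisons, capped at 1
  tt <- out[out$test == "t-test", ]
  expect_equal(tt$p_adj, pmin(1, 3 * tt$p), tolerance = 1e-12)
  expect_true(all(tt$p_adj >= tt$p))
  # identical groups: |t| tiny, p near 1
  same <- tibble::tibble(sai = rep(rnorm(20, 5, 0.2), 2),
                         group = rep(c("A", "B"), each = 20))
  out2 <- compare_sai_groups(same, correction = "none")
  expect_lt(abs(out2$statistic[1]), 1e-10)
  expect_equal(out2$p[1], 1, tolerance = 1e-9)
  expect_error(compare_sai_groups(tibble::tibble(sai = c(1, 2, 3),
                                                 group = c("A", "A", "B"))),
               ">= 2 subjects")
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(42)
  df <- tibble::tibble(sai = rnorm(40, 5, 0.3) + rep(c(0, 0.2), each = 20),
                       group = rep(c("A", "B"), each = 20))
  tt <- compare_sai_groups(df, var_equal = TRUE, correction = "none")
  F_ <- summary(aov(sai ~ group, data = df))[[1]][["F value"]][1]
  expect_equal(tt$statistic[1]^2, F_, tolerance = 1e-10)
})

test_that("a powered two-group difference is detected consistently", {
  set.seed(43)
  rejections <- vapply(1:200, function(i) {
    df <- tibble::tibble(sai = c(rnorm(100, 0, 1), rnorm(100, 1, 1)),
                         group = rep(c("A", "B"), each = 100))
    compare_sai_groups(df, correction = "none")$p[1] < 0.001
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
})

test_that("the SAI regression recovers a zero-noise planted model exactly", {
  set.seed(44)
  n <- 120
  df <- tibble::tibble(
    age = runif(n, 18, 77),
    gender = sample(c("F", "M"), n, TRUE),
    group = sample(c("CTRL", "FC", "FS", "IGE"), n, TRUE))
  df$sai <- 4.9 + 0.004 * df$age + 0.09 * (df$group == "FS") +
    0.094 * (df$gender == "M")
  fit <- suppressWarnings(sai_regression(df)) # lm warns on a perfect fit
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 4.9, tolerance = 1e-8)
  expect_equal(unname(est["age"]), 0.004, tolerance = 1e-10)
  expect_equal(unname(est["groupFS"]), 0.09, tolerance = 1e-8)
  expect_equal(unname(est["genderM"]), 0.094, tolerance = 1e-8)
  expect_equal(unname(est[c("groupFC", "groupIGE")]), c(0, 0), tolerance = 1e-8)
  # CI geometry: contains the estimate, half-width = critical t x SE
  co <- fit$coefficients
  expect_true(all(co$conf_low <= co$estimate & co$estimate <= co$conf_high))
  crit <- qt(0.975, fit$fit$df.residual)
  expect_equal(co$conf_high - co$estimate, crit * co$std_error, tolerance = 1e-10)
})

test_that("constant predictors are reported as collinear", {
  df <- tibble::tibble(age = runif(30, 20, 60), gender = "F",
                       group = rep(c("CTRL", "FS"), 15),
                       sai = rnorm(30, 5, 0.2))
  expect_error(sai_regression(df), "constant in the sample")
})

test_that("group dummies reproduce group mean differences in balanced designs", {
  set.seed(45)
  n <- 40
  df <- tibble::tibble(
    group = rep(c("CTRL", "FS"), each = n),
    age = rep(runif(n, 20, 60), 2), # identical age distribution per group
    sai = rnorm(2 * n, 5, 0.3))
  fit <- sai_regression(df, predictors = c("age", "group"))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  diff_means <- mean(df$sai[df$group == "FS"]) - mean(df$sai[df$group == "CTRL"])
  expect_equal(unname(est["groupFS"]), diff_means, tolerance = 1e-10)
})

test_that("univariate screening gates predictors into the multivariate model", {
  set.seed(46)
  n <- 200
  df <- tibble::tibble(
    age = runif(n, 18, 77),
    gender = sample(c("F", "M"), n, TRUE),
    group = sample(c("CTRL", "FS"), n, TRUE))
  df$sai <- 5 + 0.01 * df$age + rnorm(n, 0, 0.1) # only age matters
  fit <- sai_regression(df, screen = TRUE)
  expect_true("age" %in% fit$predictors)
  expect_false("group" %in% fit$predictors)
})

test_that("discrimination rates separate clusters and respect fold limits", {
  set.seed(47)
  X <- rbind(matrix(rnorm(50 * 4, 0), 50),
             matrix(rnorm(50 * 4, 4), 50))
  y <- rep(c("ctrl", "case"), each = 50)
  out <- discrimination_rates(X, y, folds = 5)
  expect_setequal(out$classifier, c("closest_mean", "svm", "lda"))
  expect_true(all(out$rate >= 0.95))
  expect_error(discrimination_rates(X[1:50, ], y[1:50]), ">= 2 classes")
  expect_error(discrimination_rates(X, y, folds = 60), "smaller than the fold")
})

test_that("shuffled labels give near-chance discrimination", {
  set.seed(48)
  X <- matrix(rnorm(120 * 4), 120)
  rates <- vapply(1:10, function(i) {
    y <- sample(rep(c("a", "b"), each = 60))
    discrimination_rates(X, y, folds = 5, classifiers = "closest_mean",
                         seed = i)$rate
  }, 0)
  expect_lt(abs(mean(rates) - 0.5), 0.1)
})

test_that("anthropometric group tests mirror the case/control layout", {
  set.seed(49)
  n <- 60
  mk <- function(group, gender, shift) {
    tibble::tibble(subject_id = paste0(group, gender, 1:n), group = group,
                   gender = gender, measure = "nose_length",
                   value = rnorm(n, 47 - shift, 1.5))
  }
  df <- dplyr::bind_rows(mk("CTRL", "F", 0), mk("FS", "F", 1),
                         mk("CTRL", "M", 0), mk("FS", "M", 0))
  out <- anthropometric_group_test(df)
  expect_equal(nrow(out), 2)
  fs_f <- out[out$gender == "F", ]
  # bookkeeping: reported means equal sample means exactly
  expect_identical(fs_f$mean_ctrl, mean(df$value[df$group == "CTRL" & df$gender == "F"]))
  expect_equal(fs_f$n_case, n)
  # a planted 1 mm reduction at sigma = 1.5, n = 60/group is well powered
  expect_lt(fs_f$p, 0.05)
  expect_gt(out$p[out$gender == "M"], 0.001) # no planted effect for males
})

test_that("a planted shorter nose is detected in most replicates", {
  set.seed(50)
  hits <- vapply(1:60, function(i) {
    n <- 60
    df <- tibble::tibble(
      subject_id = as.character(1:(2 * n)),
      group = rep(c("CTRL", "FS"), each = n),
      gender = "F", measure = "nose_length",
      value = c(rnorm(n, 47, 1.5), rnorm(n, 46, 1.5)))
    anthropometric_group_test(df)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("null anthropometric p-values are uniform", {
  set.seed(51)
  ps <- vapply(1:200, function(i) {
    n <- 30
    df <- tibble::tibble(
      subject_id = as.character(1:(2 * n)),
      group = rep(c("CTRL", "FS"), each = n),
      gender = "F", measure = "nose_length",
      value = rnorm(2 * n, 47, 1.5))
    anthropometric_group_test(df)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
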