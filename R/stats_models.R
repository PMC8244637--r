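#' Group comparisons of the SAI
#'
#' Pairwise two-sample t-tests (Welch by default) over all group pairs plus a
#' one-way ANOVA across all groups, with optional Bonferroni correction of
#' the pairwise p-values (multiplied by the number of pairwise comparisons,
#' capped at 1). All statistics run on the log scale of the asymmetry weight
#' (the SAI itself).
#'
#' @param data Tibble with the SAI and grouping columns.
#' @param sai_col,group_col Column names (defaults `"sai"`, `"group"`).
#' @param correction `"bonferroni"` or `"none"`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble, one row per test: `test` ("t-test"/"anova"), `group1`,
#'   `group2`, per-group n/mean/sd, `statistic`, `df`, `p`, `p_adj`.
#' @export
compare_sai_groups <- function(data, sai_col = "sai", group_col = "group",
                               correction = c("bonferroni", "none"),
                               var_equal = FALSE) {
  correction <- match.arg(correction)
  df <- tibble(sai = data[[sai_col]], group = as.character(data[[group_col]]))
  df <- dplyr::filter(df, !is.na(.data$sai))
  sizes <- table(df$group)
  if (any(sizes < 2)) {
    abort(glue::glue("every group needs >= 2 subjects with SAI; too small: ",
                     "{paste(names(sizes)[sizes < 2], collapse = ', ')}"))
  }
  groups <- sort(names(sizes))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- purrr::map_dfr(pairs, function(pr) {
    x <- df$sai[df$group == pr[1]]
    y <- df$sai[df$group == pr[2]]
    tt <- t.test(x, y, var.equal = var_equal)
    tibble(test = "t-test", group1 = pr[1], group2 = pr[2],
           n1 = length(x), n2 = length(y),
           mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value,
           p_adj = if (correction == "bonferroni") min(1, m * tt$p.value) else tt$p.value)
  })
  if (length(groups) > 2) {
    av <- summary(aov(sai ~ group, data = df))[[1]]
    rows <- dplyr::bind_rows(rows, tibble(
      test = "anova", group1 = paste(groups, collapse = "/"), group2 = NA,
      n1 = nrow(df), n2 = NA, mean1 = mean(df$sai), sd1 = sd(df$sai),
      mean2 = NA, sd2 = NA, statistic = av[["F value"]][1],
      df = av[["Df"]][1], p = av[["Pr(>F)"]][1], p_adj = av[["Pr(>F)"]][1]))
  }
  rows
}

#' Multivariate linear regression of SAI on cohort predictors
#'
#' Ordinary least squares of the SAI on age, gender and epilepsy-type dummies
#' (controls as the reference level), reporting coefficient, standard error,
#' t, p and 95% confidence interval per predictor. An optional univariate
#' screening step (p < `screen_alpha` in single-predictor models) can gate
#' entry into the multivariate model.
#'
#' @param data Tibble with `sai`, `age`, `gender`, `group` columns.
#' @param predictors Predictor column names (default age, gender, group).
#' @param reference_group Reference level for the group factor ("CTRL").
#' @param screen Apply univariate screening before the multivariate fit.
#' @param screen_alpha Univariate inclusion threshold (default 0.05).
#' @param conf_level Confidence level (default 0.95).
#' @return A `sai_regression` object wrapping the `lm` fit; its
#'   `coefficients` element is the tidy coefficient tibble.
#' @export
sai_regression <- function(data, predictors = c("age", "gender", "group"),
                           reference_group = "CTRL", screen = FALSE,
                           screen_alpha = 0.05, conf_level = 0.95) {
  df <- dplyr::filter(data, !is.na(.data$sai))
  if ("group" %in% predictors) {
    df$group <- stats::relevel(factor(df$group), ref = reference_group)
  }
  if ("gender" %in% predictors) df$gender <- factor(df$gender)
  # degenerate single-level factors are collinear with the intercept
  for (p in predictors) {
    if (is.factor(df[[p]]) && nlevels(droplevels(df[[p]])) < 2) {
      abort(glue::glue("predictor '{p}' is constant in the sample (collinear ",
                       "with the intercept)"))
    }
  }
  if (screen) {
    keep <- predictors[vapply(predictors, function(p) {
      fit1 <- lm(stats::reformulate(p, response = "sai"), data = df)
      an <- stats::anova(fit1)
      an[["Pr(>F)"]][1] < screen_alpha
    }, TRUE)]
    if (length(keep) == 0) keep <- predictors # never fit an empty model
    predictors <- keep
  }
  fit <- lm(stats::reformulate(predictors, response = "sai"), data = df)
  if (nrow(df) <= length(coef(fit)) ) {
    abort("fewer observations than model parameters")
  }
  if (anyNA(coef(fit))) {
    abort(glue::glue("collinear design; aliased column(s): ",
                     "{paste(names(coef(fit))[is.na(coef(fit))], collapse = ', ')}"))
  }
  sm <- summary(fit)$coefficients
  crit <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  coefs <- tibble(
    term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4],
    conf_low = sm[, 1] - crit * sm[, 2], conf_high = sm[, 1] + crit * sm[, 2]
  )
  structure(list(fit = fit, coefficients = coefs, conf_level = conf_level,
                 n = nrow(df), predictors = predictors),
            class = "sai_regression")
}

#' @export
print.sai_regression <- function(x, ...) {
  cat("<sai_regression> n = ", x$n, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Multi-folded discrimination testing
#'
#' Stratified k-fold cross-validated classification accuracy of group labels
#' from feature vectors (typically retained DSM PC scores), for three
#' classifiers: closest mean (assign to the nearest class centroid in
#' Euclidean feature space; implemented natively), a support vector machine
#' (`e1071::svm`) and linear discriminant analysis (`MASS::lda`).
#'
#' @param features Numeric matrix or data frame, one row per subject.
#' @param labels Class labels (two or more classes).
#' @param folds Number of stratified folds (default 10).
#' @param classifiers Subset of `c("closest_mean", "svm", "lda")`.
#' @param seed Seed for the fold assignment.
#' @return Tibble: `classifier`, `rate` (cross-validated accuracy), `folds`.
#' @export
discrimination_rates <- function(features, labels, folds = 10,
                                 classifiers = c("closest_mean", "svm", "lda"),
                                 seed = 1) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) abort("discrimination testing needs >= 2 classes")
  sizes <- table(y)
  if (any(sizes < folds)) {
    abort(glue::glue("class(es) smaller than the fold count ({folds}): ",
                     "{paste(names(sizes)[sizes < folds], collapse = ', ')}"))
  }
  set.seed(seed)
  fold_id <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  predict_fold <- function(method, train, test) {
    switch(method,
      closest_mean = {
        cent <- t(vapply(levels(y), function(lev) {
          colMeans(X[train, , drop = FALSE][y[train] == lev, , drop = FALSE])
        }, numeric(ncol(X))))
        d2 <- outer(rowSums(X[test, , drop = FALSE]^2), rep(1, nrow(cent))) +
          outer(rep(1, length(test)), rowSums(cent^2)) -
          2 * X[test, , drop = FALSE] %*% t(cent)
        factor(levels(y)[apply(d2, 1, which.min)], levels = levels(y))
      },
      svm = {
        fit <- e1071::svm(X[train, , drop = FALSE], y[train], kernel = "linear")
        predict(fit, X[test, , drop = FALSE])
      },
      lda = {
        fit <- MASS::lda(X[train, , drop = FALSE], grouping = y[train])
        predict(fit, X[test, , drop = FALSE])$class
      })
  }
  purrr::map_dfr(classifiers, function(m) {
    correct <- 0L
    for (k in seq_len(folds)) {
      test <- which(fold_id == k)
      train <- which(fold_id != k)
      pred <- predict_fold(m, train, test)
      correct <- correct + sum(pred == y[test])
    }
    tibble(classifier = m, rate = correct / length(y), folds = folds)
  })
}

#' Gender-stratified anthropometric group tests
#'
#' Per gender and per measure, a two-sample t-test of each case group against
#' controls on landmark-derived lengths (mm), mirroring the layout of a
#' case/control anthropometry table.
#'
#' @param data Long tibble: `subject_id`, `group`, `gender`, `measure`,
#'   `value` (mm).
#' @param control_group Name of the control group (default "CTRL").
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return Tibble: `gender`, `measure`, `group`, `n_ctrl`, `n_case`,
#'   `mean_ctrl`, `mean_case`, `statistic`, `p`.
#' @export
anthropometric_group_test <- function(data, control_group = "CTRL",
                                      var_equal = FALSE) {
  case_groups <- setdiff(unique(data$group), control_group)
  combos <- tidyr::expand_grid(gender = sort(unique(data$gender)),
                               measure = unique(data$measure),
                               group = case_groups)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    g <- combos$gender[i]; msr <- combos$measure[i]; grp <- combos$group[i]
    ctrl <- data$value[data$gender == g & data$measure == msr &
                         data$group == control_group]
    case <- data$value[data$gender == g & data$measure == msr &
                         data$group == grp]
    if (length(ctrl) < 2 || length(case) < 2) {
      abort(glue::glue("group '{grp}' / controls too small for gender {g}, ",
                       "measure {msr}"))
    }
    tt <- t.test(ctrl, case, var.equal = var_equal)
    tibble(gender = g, measure = msr, group = grp,
           n_ctrl = length(ctrl), n_case = length(case),
           mean_ctrl = mean(ctrl), mean_case = mean(case),
           statistic = unname(tt$statistic), p = tt$p.value)
  })
}
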