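#' Normalize a feature matrix for sparse regression
#'
#' Column-wise: subtract the dataset mean, then divide by the Euclidean norm
#' of the centred column, so every non-constant feature has mean 0 and unit
#' Euclidean norm and the L1 penalty treats features comparably. Constant
#' columns are centred, flagged, and left with a unit divisor. The operation
#' is idempotent.
#'
#' @param raw Numeric matrix or data frame (subjects x features).
#' @return A `feature_matrix`: the normalized matrix with attributes `center`
#'   (per-feature mean), `norm` (per-feature Euclidean divisor), `constant`
#'   (logical), `raw` (the input matrix).
#' @export
#' @examples
#' normalize_features(cbind(a = c(1, 2, 3))) # (-1, 0, 1) / sqrt(2)
normalize_features <- function(raw) {
  X <- as.matrix(raw)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature", seq_len(ncol(X)))
  if (anyNA(X)) abort("feature matrix contains missing values; drop rows upstream")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  nrm <- sqrt(colSums(Xc^2))
  constant <- nrm < 1e-12
  if (any(constant)) {
    warn(glue::glue("constant feature column(s) left unscaled: ",
                    "{paste(colnames(X)[constant], collapse = ', ')}"))
  }
  div <- ifelse(constant, 1, nrm)
  out <- sweep(Xc, 2, div, "/")
  structure(out, center = ctr, norm = div, constant = constant, raw = X,
            class = c("feature_matrix", "matrix", "array"))
}

#' Append clinical features to a BASI feature matrix
#'
#' Adds lesion laterality (coded left -1, right +1, none 0) and/or
#' epilepsy-type dummies (reference level dropped) from the cohort table,
#' then re-normalizes all columns with [normalize_features()].
#'
#' @param X A [normalize_features()] matrix (its raw values are reused).
#' @param cohort Cohort tibble row-aligned to `X` (`subject_id` order must
#'   match `rownames(X)` when present, otherwise row order is trusted).
#' @param add Subset of `c("lesion_laterality", "epilepsy_type")`.
#' @param group_levels Admissible group labels.
#' @return A new `feature_matrix` with the appended columns.
#' @export
augment_features <- function(X, cohort,
                             add = c("lesion_laterality", "epilepsy_type"),
                             group_levels = c("CTRL", "FC", "FS", "IGE")) {
  add <- match.arg(add, several.ok = TRUE)
  raw <- attr(X, "raw") %||% as.matrix(X)
  if (nrow(raw) != nrow(cohort)) abort("cohort rows must align with feature rows")
  if (!is.null(rownames(raw)) && "subject_id" %in% names(cohort) &&
      !identical(rownames(raw), cohort$subject_id)) {
    abort("cohort subject order does not match feature matrix rows")
  }
  extra <- NULL
  if ("lesion_laterality" %in% add) {
    side <- cohort$lesion_side %||% abort("cohort lacks 'lesion_side'")
    bad <- setdiff(unique(side), c("left", "right", "none"))
    if (length(bad) > 0) {
      abort(glue::glue("unknown lesion_side value(s): {paste(bad, collapse = ', ')}"))
    }
    extra <- cbind(extra, lesion_laterality = c(left = -1, right = 1, none = 0)[side])
  }
  if ("epilepsy_type" %in% add) {
    bad <- setdiff(unique(cohort$group), group_levels)
    if (length(bad) > 0) {
      abort(glue::glue("unknown group label(s): {paste(bad, collapse = ', ')}"))
    }
    grp <- factor(cohort$group, levels = group_levels)
    grp <- droplevels(grp)
    mm <- model.matrix(~grp)[, -1, drop = FALSE]
    colnames(mm) <- sub("^grp", "type_", colnames(mm))
    extra <- cbind(extra, mm)
  }
  normalize_features(cbind(raw, extra))
}

#' Repeated cross-validated LASSO protocol
#'
#' The full repeated sparse-prediction protocol: per repetition the data are
#' split randomly into `train_frac` training and the rest test; on the
#' training set, k-fold cross-validation over the alpha grid selects the
#' penalty; the model is refit on the whole training set at the chosen alpha
#' and evaluated on the test set by Spearman rank correlation and mean
#' squared error. Repetitions with an intercept-only model (or otherwise
#' constant test predictions) record a Spearman rho of exactly 0. Selected
#' features are those with nonzero coefficients.
#'
#' Two CV selection criteria are offered; ties always break toward the
#' larger, sparser alpha. `"mse"` (the default) minimizes the mean squared
#' error of the pooled CV predictions; on weak data it returns the
#' intercept-only model for the majority of repetitions, the protocol's
#' characteristic reported behaviour. `"correlation"` maximizes the Pearson
#' correlation between measured and CV-predicted outcome (alphas whose folds
#' all fit the bare intercept count as correlation 0, so a fully sparse
#' model can win); because correlation ignores calibration, it rewards
#' overfit models whose CV predictions still track the dataset's sample
#' correlations, and on weak data it almost never returns an intercept-only
#' model — the methods vignette discusses why the two criteria diverge.
#'
#' The L1-penalized linear fits are computed by \pkg{glmnet} with
#' `standardize = FALSE` (features are expected to be pre-normalized at the
#' dataset level with [normalize_features()]; the mild train/test leakage
#' this implies is deliberate protocol behaviour, avoidable by normalizing
#' per split upstream). The intercept is never penalized.
#'
#' @param X Feature matrix (ideally a [normalize_features()] result).
#' @param y Numeric outcome (the SAI), length `nrow(X)`.
#' @param n_rep Number of repetitions (default 1000).
#' @param train_frac Training fraction per split (default 0.8).
#' @param alpha_grid Penalty grid; default the 13 consecutive powers of two
#'   from 2^-16 to 2^-4.
#' @param cv_folds Cross-validation folds on the training set (default 10).
#' @param cv_criterion CV alpha-selection criterion: `"mse"` (default) or
#'   `"correlation"` (see Details).
#' @param seed Master seed; spawns one RNG stream per repetition, so results
#'   are bit-reproducible.
#' @return A `lasso_protocol` object: `repetitions` tibble (rep, alpha, rho,
#'   mse, intercept_only, n_selected, selected list-column),
#'   `selection_frequency` tibble, `mean_rho`, `mean_mse`,
#'   `n_intercept_only`, `config`.
#' @export
run_protocol <- function(X, y, n_rep = 1000, train_frac = 0.8,
                         alpha_grid = 2^seq(-16, -4), cv_folds = 10,
                         cv_criterion = c("mse", "correlation"), seed = 1) {
  cv_criterion <- match.arg(cv_criterion)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(alpha_grid) == 0) abort("alpha grid is empty")
  if (n < 25) abort(glue::glue("protocol needs >= 25 subjects, got {n}"))
  if (p < 1) abort("need at least one feature")
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  feat <- colnames(X) %||% paste0("feature", seq_len(p))
  lam <- sort(unique(alpha_grid), decreasing = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_rep)
  n_train <- round(train_frac * n)

  one_rep <- function(r) {
    set.seed(rep_seeds[r])
    train <- sample.int(n, n_train)
    test <- setdiff(seq_len(n), train)
    Xtr <- X[train, , drop = FALSE]
    ytr <- y[train]
    fold_id <- sample(rep(seq_len(cv_folds), length.out = n_train))
    cv_pred <- matrix(NA_real_, n_train, length(lam))
    any_features <- rep(FALSE, length(lam))
    for (k in seq_len(cv_folds)) {
      hold <- fold_id == k
      fit <- glmnet::glmnet(Xtr[!hold, , drop = FALSE], ytr[!hold],
                            family = "gaussian", lambda = lam,
                            standardize = FALSE)
      cv_pred[hold, ] <- predict(fit, Xtr[hold, , drop = FALSE], s = lam)
      any_features <- any_features | (fit$df > 0)
    }
    crit <- if (cv_criterion == "mse") {
      -colMeans((cv_pred - ytr)^2)
    } else {
      cv_cor <- apply(cv_pred, 2, function(pr) {
        if (sd(pr) < 1e-12) 0 else cor(pr, ytr)
      })
      cv_cor[is.na(cv_cor)] <- 0
      # an alpha whose folds all fit the bare intercept IS the intercept-only
      # model: its criterion is 0 by convention (pooled fold means otherwise
      # carry spurious variation), so a fully sparse model can win
      cv_cor[!any_features] <- 0
      cv_cor
    }
    best <- which.max(crit) # lam is decreasing, so ties pick the sparser fit
    alpha <- lam[best]
    fit <- glmnet::glmnet(Xtr, ytr, family = "gaussian", lambda = lam,
                          standardize = FALSE)
    beta <- drop(as.matrix(coef(fit, s = alpha)))[-1]
    selected <- feat[beta != 0]
    pred <- drop(predict(fit, X[test, , drop = FALSE], s = alpha))
    intercept_only <- length(selected) == 0
    rho <- if (intercept_only || sd(pred) < 1e-12 || sd(y[test]) < 1e-12) 0
           else cor(pred, y[test], method = "spearman")
    tibble(rep = r, alpha = alpha, rho = rho,
           mse = mean((pred - y[test])^2),
           intercept_only = intercept_only,
           n_selected = length(selected), selected = list(selected))
  }
  reps <- purrr::map_dfr(seq_len(n_rep), one_rep)
  counts <- table(factor(unlist(reps$selected), levels = feat))
  freq <- tibble(feature = feat,
                 frequency_pct = 100 * as.numeric(counts) / n_rep)
  freq <- dplyr::arrange(freq, dplyr::desc(.data$frequency_pct))
  structure(
    list(repetitions = reps, selection_frequency = freq,
         mean_rho = mean(reps$rho), mean_mse = mean(reps$mse),
         n_intercept_only = sum(reps$intercept_only),
         config = list(n = n, p = p, n_rep = n_rep, train_frac = train_frac,
                       alpha_grid = lam, cv_folds = cv_folds,
                       cv_criterion = cv_criterion, seed = seed,
                       rep_seeds = rep_seeds, features = feat)),
    class = "lasso_protocol"
  )
}

#' @export
print.lasso_protocol <- function(x, ...) {
  cat("<lasso_protocol> ", x$config$n_rep, " repetitions, n = ", x$config$n,
      ", p = ", x$config$p, "\n",
      "  mean Spearman rho ", sprintf("%.3f", x$mean_rho),
      ", mean MSE ", sprintf("%.3f", x$mean_mse),
      ", intercept-only ", x$n_intercept_only, "/", x$config$n_rep, "\n",
      sep = "")
  cat("  top features:\n")
  print(head(x$selection_frequency, 5))
  invisible(x)
}

#' Per-feature selection frequencies
#'
#' 100 x (repetitions in which the feature had a nonzero coefficient) /
#' (total repetitions), sorted descending. Features are multi-selected, so
#' the column has no sum constraint.
#'
#' @param result A [run_protocol()] result.
#' @return Tibble: `feature`, `frequency_pct`.
#' @export
selection_frequencies <- function(result) {
  result$selection_frequency
}

#' Write a protocol result manifest (JSON) and frequency CSV
#'
#' @param result A [run_protocol()] result.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_protocol_result <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    manifest <- list(
      config = result$config[c("n", "p", "n_rep", "train_frac", "cv_folds", "seed")],
      alpha_grid = result$config$alpha_grid,
      mean_rho = result$mean_rho, mean_mse = result$mean_mse,
      n_intercept_only = result$n_intercept_only,
      repetitions = dplyr::select(result$repetitions, -dplyr::all_of("selected")),
      selection_frequency = result$selection_frequency
    )
    jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    write.csv(result$selection_frequency, csv_path, row.names = FALSE)
  }
  invisible(result)
}
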