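#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dense surface model: one row per mode
#'
#' @param x A [fit_dsm()] model.
#' @param ... Unused.
#' @return Tibble: `mode`, `variance`, `variance_fraction`,
#'   `cumulative_fraction`, `retained`.
#' @method tidy dsm_model
#' @export
tidy.dsm_model <- function(x, ...) {
  vf <- x$variances / sum(x$variances)
  tibble(mode = seq_along(x$variances), variance = x$variances,
         variance_fraction = vf, cumulative_fraction = cumsum(vf),
         retained = seq_along(vf) <= x$retained)
}

#' One-row summary of a dense surface model
#' @inheritParams tidy.dsm_model
#' @method glance dsm_model
#' @export
glance.dsm_model <- function(x, ...) {
  tibble(n_train = x$n_train, M = x$M, n_modes = length(x$variances),
         retained = x$retained, coverage_target = x$coverage_target,
         coverage_achieved = sum(x$variances[seq_len(x$retained)]) / sum(x$variances))
}

#' Tidy coefficient table of an SAI regression
#' @param x A [sai_regression()] fit.
#' @param ... Unused.
#' @method tidy sai_regression
#' @export
tidy.sai_regression <- function(x, ...) x$coefficients

#' One-row summary of an SAI regression
#' @inheritParams tidy.sai_regression
#' @method glance sai_regression
#' @export
glance.sai_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = x$n, r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, statistic = unname(s$fstatistic[1]),
         df = unname(s$fstatistic[2]), df_residual = unname(s$fstatistic[3]))
}

#' Tidy a repeated-LASSO result: per-feature selection frequencies
#' @param x A [run_protocol()] result.
#' @param ... Unused.
#' @method tidy lasso_protocol
#' @export
tidy.lasso_protocol <- function(x, ...) x$selection_frequency

#' One-row summary of a repeated-LASSO result
#' @inheritParams tidy.lasso_protocol
#' @method glance lasso_protocol
#' @export
glance.lasso_protocol <- function(x, ...) {
  tibble(n = x$config$n, p = x$config$p, n_rep = x$config$n_rep,
         mean_rho = x$mean_rho, mean_mse = x$mean_mse,
         n_intercept_only = x$n_intercept_only)
}
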