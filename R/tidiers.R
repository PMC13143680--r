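#' Tidy an OPLS-DA model
#'
#' One row per feature: predictive weight, loading and VIP.
#'
#' @param x an `opls_model`.
#' @param ... unused.
#' @return tibble with `feature`, `weight`, `loading`, `vip`.
#' @method tidy opls_model
#' @export
tidy.opls_model <- function(x, ...) {
  tibble(feature = names(x$vip), weight = unname(x$weights),
         loading = unname(x$loadings), vip = unname(x$vip))
}

#' Glance at an OPLS-DA model
#'
#' @param x an `opls_model`.
#' @param ... unused.
#' @return one-row tibble: `r2y`, `q2`, `n_ortho`, `cv_folds`, `n`.
#' @method glance opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble(r2y = x$r2y, q2 = x$q2, n_ortho = x$n_ortho,
         cv_folds = x$cv_folds, n = length(x$y))
}

#' Tidy a model evaluation report
#'
#' Long metric table covering discrimination and calibration.
#'
#' @param x a `model_report` from [nested_cv_evaluate()].
#' @param ... unused.
#' @return tibble with `metric`, `estimate`, `conf_low`, `conf_high`.
#' @method tidy model_report
#' @export
tidy.model_report <- function(x, ...) {
  cal <- x$calibration
  tibble(metric = c("apparent_auc", "cv_auc", "optimism", "hl_chi2", "hl_p",
                    "calibration_slope", "calibration_intercept", "brier"),
         estimate = c(x$apparent_auc, x$cv_auc, x$optimism, cal$hl_chi2,
                      cal$hl_p, cal$slope, cal$intercept, cal$brier),
         conf_low = c(x$apparent_ci[1], x$cv_ci[1], rep(NA_real_, 6)),
         conf_high = c(x$apparent_ci[2], x$cv_ci[2], rep(NA_real_, 6)))
}

#' Glance at a model evaluation report
#'
#' @param x a `model_report`.
#' @param ... unused.
#' @return one-row tibble of headline metrics.
#' @method glance model_report
#' @export
glance.model_report <- function(x, ...) {
  tibble(tier = x$tier, n = x$n, folds = x$folds, repeats = x$repeats,
         apparent_auc = x$apparent_auc, cv_auc = x$cv_auc,
         optimism = x$optimism, brier = x$calibration$brier)
}

#' Tidy a permutation validation report
#'
#' @param x a `permutation_report`.
#' @param ... unused.
#' @return the per-permutation tibble (`perm`, `r2y`, `q2`, `cor`).
#' @method tidy permutation_report
#' @export
tidy.permutation_report <- function(x, ...) {
  as_tibble(unclass(x)[c("perm", "r2y", "q2", "cor")])
}

#' Glance at a permutation validation report
#'
#' @param x a `permutation_report`.
#' @param ... unused.
#' @return one-row tibble: originals, permutation maxima, intercepts, pass.
#' @method glance permutation_report
#' @export
glance.permutation_report <- function(x, ...) {
  o <- attr(x, "original")
  tibble(n_perm = nrow(x), r2y = o$r2y, q2 = o$q2,
         max_perm_r2y = max(x$r2y), max_perm_q2 = max(x$q2),
         q2_intercept = attr(x, "q2_intercept"),
         r2y_intercept = attr(x, "r2y_intercept"),
         pass = attr(x, "pass"))
}

#' Tidy a nomogram
#'
#' @param x a `nomogram_points`.
#' @param ... unused.
#' @return the per-feature point table.
#' @method tidy nomogram_points
#' @export
tidy.nomogram_points <- function(x, ...) x$table
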