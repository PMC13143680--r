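#' Model tier definition
#'
#' The three-tier comparison: a clinical base model (age, BMI, HbA1c, SBP), a
#' metabolomics-enhanced model adding the top flux markers, and the full
#' fusion model adding the digital urine phenotypes.
#'
#' @param name tier name.
#' @param features character vector of predictor columns (non-empty).
#' @return object of class `model_tier`.
#' @export
model_tier <- function(name, features) {
  assert_that(length(features) > 0, "feature list must be non-empty")
  structure(list(name = name, features = features), class = "model_tier")
}

#' Default model tiers
#'
#' @param flux_features flux-ratio columns for the metabolomics tier (default
#'   indoxyl sulfate, C8-carnitine and phenylacetylglutamine flux ratios).
#' @param physicalomics_features digital urine columns added by the fusion
#'   tier (default foam half-life and yellowness).
#' @return named list of [model_tier()] objects `clinical`, `metabolomics`,
#'   `fusion`.
#' @export
default_tiers <- function(flux_features = c("indoxyl_sulfate", "c8_carnitine",
                                            "phenylacetylglutamine"),
                          physicalomics_features = c("t_half_meas",
                                                     "b_star_meas")) {
  clinical <- c("age", "bmi", "hba1c", "sbp")
  list(clinical = model_tier("clinical", clinical),
       metabolomics = model_tier("metabolomics", c(clinical, flux_features)),
       fusion = model_tier("fusion", c(clinical, flux_features,
                                       physicalomics_features)))
}

# stratified fold assignment: each class spread evenly over k folds
stratified_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- which(y01 == cl)
    assert_that(length(idx) >= k, "class too small to stratify across folds")
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

# permutation importance of a ranger forest, averaged over cv folds
cv_permutation_importance <- function(X, y01, folds = 5, num.trees = 300) {
  fold <- stratified_folds(y01, folds)
  imp <- matrix(0, folds, ncol(X), dimnames = list(NULL, colnames(X)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- ranger::ranger(x = X[tr, , drop = FALSE],
                          y = factor(y01[tr]),
                          num.trees = num.trees,
                          importance = "permutation",
                          seed = f)
    imp[f, ] <- fit$variable.importance[colnames(X)]
  }
  colMeans(imp)
}

#' Recursive feature elimination with random forests
#'
#' Iteratively drops the lowest-importance 20% of the remaining features,
#' ranking by permutation importance of a random forest averaged over
#' cross-validation folds fit on training subsets only. Constant features are
#' discarded first with a warning. When embedded in [nested_cv_evaluate()]
#' the routine only ever sees the outer-loop training folds, so held-out
#' folds never inform selection.
#'
#' @param X samples x features data frame or matrix.
#' @param y binary labels.
#' @param n_keep target number of features.
#' @param folds inner CV folds for importance averaging.
#' @param drop_frac fraction of remaining features dropped per round.
#' @param num.trees forest size per fit.
#' @param seed integer seed.
#' @return list with `selected` (character), `ranking` (best first: survivors
#'   in final importance order, then eliminated features in reverse
#'   elimination order).
#' @export
rfe_select <- function(X, y, n_keep, folds = 5, drop_frac = 0.2,
                       num.trees = 300, seed = 1) {
  X <- as.data.frame(X)
  y01 <- as_binary01(y)
  assert_that(n_keep <= ncol(X), "n_keep exceeds the number of features")
  set.seed(seed)
  const <- names(X)[purrr::map_dbl(X, function(v) var(as.numeric(v))) == 0]
  if (length(const)) {
    warn(paste0("dropping constant feature(s): ", paste(const, collapse = ", ")))
    X <- X[, setdiff(names(X), const), drop = FALSE]
    assert_that(n_keep <= ncol(X), "n_keep exceeds the non-constant features")
  }
  eliminated <- character(0)
  current <- names(X)
  imp <- NULL
  while (length(current) > n_keep) {
    imp_cur <- cv_permutation_importance(as.matrix(X[, current, drop = FALSE]),
                                         y01, folds, num.trees)
    n_drop <- max(1L, floor(length(current) * drop_frac))
    n_drop <- min(n_drop, length(current) - n_keep)
    drop_feats <- names(sort(imp_cur))[seq_len(n_drop)]
    eliminated <- c(drop_feats[order(imp_cur[drop_feats])], eliminated)
    current <- setdiff(current, drop_feats)
    imp <- imp_cur
  }
  if (is.null(imp)) {
    imp <- cv_permutation_importance(as.matrix(X), y01, folds, num.trees)
  }
  final_imp <- imp[current]
  list(selected = current,
       ranking = c(names(sort(final_imp, decreasing = TRUE)),
                   c(eliminated, const)))
}

#' Repeated stratified nested cross-validation of one model tier
#'
#' Evaluates a random-forest classifier on the tier's features with repeated
#' stratified k-fold cross-validation. Optional feature selection
#' ([rfe_select()]) is re-run inside every outer training fold so held-out
#' folds stay blind to it. Out-of-fold predicted probabilities are pooled
#' (averaged over repeats per subject) and summarised: cross-validated AUC
#' with a DeLong confidence interval, apparent (training) AUC, the optimism
#' (apparent minus cross-validated, warning when negative), and calibration
#' metrics on the out-of-fold predictions.
#'
#' @param data data frame holding features and the label column.
#' @param tier a [model_tier()] (or character feature vector).
#' @param label name of the binary outcome column.
#' @param folds,repeats cross-validation geometry (defaults 10 and 5).
#' @param seed integer seed.
#' @param num.trees forest size.
#' @param select optional list of arguments for in-fold [rfe_select()] (must
#'   contain `n_keep`; `folds`, `num.trees` optional).
#' @return object of class `model_report`.
#' @export
nested_cv_evaluate <- function(data, tier, label = "outcome", folds = 10,
                               repeats = 5, seed = 1, num.trees = 500,
                               select = NULL) {
  feats <- if (inherits(tier, "model_tier")) tier$features else tier
  tname <- if (inherits(tier, "model_tier")) tier$name else "custom"
  assert_that(all(feats %in% names(data)), "missing feature columns")
  y01 <- as_binary01(data[[label]])
  X <- as.data.frame(data[, feats, drop = FALSE])
  set.seed(seed)
  oof <- matrix(NA_real_, nrow(X), repeats)
  sel_log <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y01, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      use_feats <- feats
      if (!is.null(select)) {
        sel <- rfe_select(X[tr, , drop = FALSE], y01[tr],
                          n_keep = select$n_keep,
                          folds = select$folds %||% 5,
                          num.trees = select$num.trees %||% 300,
                          seed = seed * 1000 + r * 100 + f)
        use_feats <- sel$selected
        sel_log[[length(sel_log) + 1L]] <- use_feats
      }
      fit <- ranger::ranger(x = X[tr, use_feats, drop = FALSE],
                            y = factor(y01[tr]), probability = TRUE,
                            num.trees = num.trees, seed = seed + r * 100 + f)
      pr <- predict(fit, X[!tr, use_feats, drop = FALSE])$predictions[, "1"]
      oof[!tr, r] <- pr
    }
  }
  oof_mean <- rowMeans(oof)
  # apparent performance: full-data fit predicted on the training data
  full <- ranger::ranger(x = X, y = factor(y01), probability = TRUE,
                         num.trees = num.trees, seed = seed)
  app_pred <- predict(full, X)$predictions[, "1"]

  roc_cv <- pROC::roc(y01, oof_mean, quiet = TRUE, direction = "<")
  roc_app <- pROC::roc(y01, app_pred, quiet = TRUE, direction = "<")
  ci_cv <- as.numeric(pROC::ci.auc(roc_cv, method = "delong"))
  # random forests routinely separate their own training data perfectly;
  # pROC's degenerate-CI note about that is expected, not actionable
  ci_app <- suppressWarnings(
    as.numeric(pROC::ci.auc(roc_app, method = "delong")))
  cv_auc <- as.numeric(pROC::auc(roc_cv))
  apparent_auc <- as.numeric(pROC::auc(roc_app))
  optimism <- apparent_auc - cv_auc
  if (optimism < 0) warn("negative optimism: apparent AUC below cross-validated AUC")
  calib <- calibration_assess(clamp(oof_mean, 1e-6, 1 - 1e-6), y01)
  structure(list(tier = tname, features = feats, n = nrow(X),
                 folds = folds, repeats = repeats, seed = seed,
                 apparent_auc = apparent_auc,
                 apparent_ci = ci_app[c(1, 3)],
                 cv_auc = cv_auc, cv_ci = ci_cv[c(1, 3)],
                 optimism = optimism, calibration = calib,
                 oof_pred = oof_mean, apparent_pred = app_pred, y = y01,
                 selected_features = sel_log),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model tier '%s': n = %d, %d x %d-fold CV\n", x$tier, x$n,
              x$repeats, x$folds))
  cat(sprintf("  apparent AUC = %.3f (%.3f-%.3f)\n", x$apparent_auc,
              x$apparent_ci[1], x$apparent_ci[2]))
  cat(sprintf("  cross-validated AUC = %.3f (%.3f-%.3f), optimism = %.3f\n",
              x$cv_auc, x$cv_ci[1], x$cv_ci[2], x$optimism))
  cat(sprintf("  calibration: slope %.3f, intercept %.3f, Brier %.3f\n",
              x$calibration$slope, x$calibration$intercept,
              x$calibration$brier))
  invisible(x)
}

#' DeLong comparison of two correlated AUCs
#'
#' AUCs, DeLong confidence intervals and the two-sided DeLong test for the
#' difference of two predictors scored on the same subjects.
#'
#' @param pred_a,pred_b predicted scores for the same subjects.
#' @param y binary labels (both classes present).
#' @return one-row tibble: `auc_a`, `auc_b`, `ci_a_low`, `ci_a_high`,
#'   `ci_b_low`, `ci_b_high`, `auc_diff`, `p_value`.
#' @export
delong_auc <- function(pred_a, pred_b, y) {
  y01 <- as_binary01(y)
  ra <- pROC::roc(y01, pred_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y01, pred_b, quiet = TRUE, direction = "<")
  cia <- as.numeric(pROC::ci.auc(ra, method = "delong"))
  cib <- as.numeric(pROC::ci.auc(rb, method = "delong"))
  p <- if (isTRUE(all.equal(pred_a, pred_b))) 1 else
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value
  tibble(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
         ci_a_low = cia[1], ci_a_high = cia[3],
         ci_b_low = cib[1], ci_b_high = cib[3],
         auc_diff = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
         p_value = p)
}

#' Calibration assessment of predicted probabilities
#'
#' Hosmer-Lemeshow goodness of fit on risk-decile groups (empty or tied
#' groups are merged with a warning), logistic recalibration for the
#' calibration slope (coefficient of logit(pred)) and intercept (offset
#' model), and the Brier score (mean squared error of the probabilities).
#'
#' @param pred predicted probabilities in (0, 1).
#' @param y binary outcomes.
#' @param n_groups number of Hosmer-Lemeshow groups (default 10).
#' @return list: `hl_chi2`, `hl_df`, `hl_p`, `slope`, `intercept`, `brier`,
#'   `groups` (tibble of per-group observed/expected).
#' @export
calibration_assess <- function(pred, y, n_groups = 10) {
  y01 <- as_binary01(y)
  assert_that(all(pred > 0 & pred < 1), "predictions must lie in (0, 1)")
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < n_groups + 1) warn("tied predictions: merging calibration groups")
  g <- if (length(br) < 2) factor(rep(1, length(pred)))
       else cut(pred, breaks = br, include.lowest = TRUE)
  grp <- tibble(g = g, pred = pred, y = y01) |>
    summarise(n = dplyr::n(), observed = sum(.data$y),
              expected = sum(.data$pred), mean_pred = mean(.data$pred),
              .by = "g") |>
    arrange(.data$mean_pred)
  pbar <- grp$expected / grp$n
  hl_chi2 <- sum((grp$observed - grp$expected)^2 /
                   (grp$n * pbar * (1 - pbar)))
  hl_df <- nrow(grp) - 2
  hl_p <- if (hl_df > 0) pchisq(hl_chi2, hl_df, lower.tail = FALSE) else NA_real_
  lp <- qlogis(pred)
  slope <- if (var(lp) == 0) {
    warn("constant predictions: calibration slope undefined")
    NA_real_
  } else unname(coef(glm(y01 ~ lp, family = binomial()))[2])
  intercept <- unname(coef(glm(y01 ~ offset(lp), family = binomial()))[1])
  list(hl_chi2 = hl_chi2, hl_df = hl_df, hl_p = hl_p, slope = slope,
       intercept = intercept, brier = mean((pred - y01)^2), groups = grp)
}

#' Continuous net reclassification and integrated discrimination improvement
#'
#' Category-free NRI:
#' \eqn{[P(\uparrow|D=1) - P(\downarrow|D=1)] + [P(\downarrow|D=0) - P(\uparrow|D=0)]}
#' where up/down is any increase/decrease of the predicted risk under the new
#' model. IDI: the change in mean predicted risk among events minus the
#' change among non-events. Percentile-bootstrap confidence intervals.
#'
#' @param pred_old,pred_new predicted risks in \[0, 1\] for the same subjects.
#' @param y binary outcomes (at least one event and one non-event).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return one-row tibble: `nri`, `nri_low`, `nri_high`, `idi`, `idi_low`,
#'   `idi_high`.
#' @export
nri_idi <- function(pred_old, pred_new, y, n_boot = 1000, seed = 1,
                    conf = 0.95) {
  y01 <- as_binary01(y)
  assert_that(any(y01 == 1) && any(y01 == 0),
              "need at least one event and one non-event")
  point <- function(po, pn, yy) {
    d <- pn - po
    ev <- yy == 1
    nri <- (mean(d[ev] > 0) - mean(d[ev] < 0)) +
      (mean(d[!ev] < 0) - mean(d[!ev] > 0))
    idi <- (mean(pn[ev]) - mean(po[ev])) - (mean(pn[!ev]) - mean(po[!ev]))
    c(nri = nri, idi = idi)
  }
  est <- point(pred_old, pred_new, y01)
  set.seed(seed)
  boots <- purrr::map(seq_len(n_boot), function(i) {
    repeat {
      idx <- sample(length(y01), replace = TRUE)
      if (any(y01[idx] == 1) && any(y01[idx] == 0)) break
    }
    point(pred_old[idx], pred_new[idx], y01[idx])
  })
  bm <- do.call(rbind, boots)
  a <- (1 - conf) / 2
  tibble(nri = est["nri"],
         nri_low = quantile(bm[, "nri"], a), nri_high = quantile(bm[, "nri"], 1 - a),
         idi = est["idi"],
         idi_low = quantile(bm[, "idi"], a), idi_high = quantile(bm[, "idi"], 1 - a))
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at threshold probability tau:
#' \eqn{NB(\tau) = TP/N - (FP/N)\,\tau/(1-\tau)}, against the treat-all
#' strategy (every subject treated) and treat-none (net benefit 0).
#'
#' @param pred predicted probabilities.
#' @param y binary outcomes.
#' @param thresholds threshold probabilities in (0, 1); values at 1 are
#'   dropped.
#' @return tibble of class `dca_curve`: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
decision_curve <- function(pred, y, thresholds = seq(0.05, 0.95, by = 0.05)) {
  y01 <- as_binary01(y)
  bad <- thresholds <= 0 | thresholds >= 1
  if (any(bad)) {
    warn("dropping thresholds outside (0, 1)")
    thresholds <- thresholds[!bad]
  }
  n <- length(y01); prev <- mean(y01)
  out <- purrr::map(thresholds, function(tau) {
    treat <- pred >= tau
    tp <- sum(treat & y01 == 1) / n
    fp <- sum(treat & y01 == 0) / n
    odds <- tau / (1 - tau)
    tibble(threshold = tau,
           nb_model = tp - fp * odds,
           nb_all = prev - (1 - prev) * odds,
           nb_none = 0)
  }) |> list_rbind()
  class(out) <- c("dca_curve", class(out))
  out
}

#' Build a nomogram from a fitted logistic model
#'
#' Converts an additive logistic fit into the familiar points scale: each
#' feature's contribution is rescaled so the widest-range feature spans 0-100
#' points (reference = the value giving the lowest risk), and the total score
#' maps back to predicted probability through the linear predictor -- the
#' round trip is exact for an additive model.
#'
#' @param fit a `glm` binomial fit on numeric features.
#' @param data optional data frame giving feature ranges (defaults to the
#'   model frame).
#' @return object of class `nomogram_points`: per-feature point table,
#'   `lp0` (linear predictor at all references) and `points_per_lp`.
#' @export
build_nomogram <- function(fit, data = NULL) {
  assert_that(inherits(fit, "glm"), "fit must be a glm")
  mf <- data %||% fit$model
  feats <- attr(fit$terms, "term.labels")
  beta <- coef(fit)[feats]
  assert_that(!anyNA(beta), "all features must have estimated coefficients")
  rng <- purrr::map(feats, function(f) range(mf[[f]]))
  span <- purrr::map_dbl(seq_along(feats), function(i)
    abs(beta[i]) * diff(rng[[i]]))
  assert_that(all(span > 0), "zero-range feature: nomogram undefined")
  scale_pts <- 100 / max(span)
  tab <- purrr::map(seq_along(feats), function(i) {
    b <- beta[i]
    ref <- if (b > 0) rng[[i]][1] else rng[[i]][2]
    tibble(feature = feats[i], beta = unname(b), min = rng[[i]][1],
           max = rng[[i]][2], reference = ref,
           points_per_unit = unname(b) * scale_pts,
           max_points = span[i] * scale_pts)
  }) |> list_rbind()
  lp0 <- unname(coef(fit)[1]) + sum(tab$beta * tab$reference)
  structure(list(table = tab, lp0 = lp0, points_per_lp = scale_pts),
            class = "nomogram_points")
}

#' Score subjects on a nomogram
#'
#' @param nomogram a `nomogram_points` object.
#' @param newdata data frame with the nomogram's feature columns.
#' @return tibble with per-feature points, `total_points` and `probability`.
#' @export
predict_nomogram <- function(nomogram, newdata) {
  tab <- nomogram$table
  pts <- purrr::map(seq_len(nrow(tab)), function(i) {
    (newdata[[tab$feature[i]]] - tab$reference[i]) * tab$points_per_unit[i]
  })
  names(pts) <- paste0("points_", tab$feature)
  total <- Reduce(`+`, pts)
  as_tibble(pts) |>
    mutate(total_points = total,
           probability = plogis(nomogram$lp0 +
                                  total / nomogram$points_per_lp))
}

#' Events per variable
#'
#' @param n_events number of outcome events.
#' @param n_predictors number of candidate predictors (> 0).
#' @return events per variable, `n_events / n_predictors`.
#' @export
epv <- function(n_events, n_predictors) {
  assert_that(n_predictors > 0, "n_predictors must be > 0")
  n_events / n_predictors
}

#' Riley minimum sample size for a prediction model
#'
#' Minimum n so that the expected global shrinkage factor of a binary
#' prediction model reaches S:
#' \deqn{n = \frac{p}{(S-1)\,\ln(1 - R^2_{CS}/S)}}
#' rounded up, with p candidate predictors and anticipated Cox-Snell R2.
#'
#' @param p number of candidate predictor parameters.
#' @param r2cs anticipated Cox-Snell R-squared (0 < r2cs < s).
#' @param s target shrinkage factor in (0, 1), conventionally 0.9.
#' @return integer minimum sample size.
#' @export
riley_min_n <- function(p, r2cs, s = 0.9) {
  assert_that(s > 0 && s < 1, "s must lie in (0, 1)")
  assert_that(r2cs > 0 && r2cs < s, "need 0 < r2cs < s")
  ceiling(p / ((s - 1) * log(1 - r2cs / s)))
}

#' Hanley-McNeil standard error of an AUC
#'
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_1-1)(Q_1 - A^2) + (n_2-1)(Q_2 - A^2)}
#'                        {n_1 n_2}}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param auc the AUC in (0, 1).
#' @param n1,n2 numbers of cases and controls (>= 1).
#' @return standard error.
#' @export
hanley_se_auc <- function(auc, n1, n2) {
  assert_that(auc > 0 && auc < 1, "auc must lie in (0, 1)")
  assert_that(n1 >= 1 && n2 >= 1, "n1 and n2 must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
}

#' Percentage with one-decimal reporting
#'
#' Convenience for event-rate reporting: `100 * events / n`, optionally
#' rounded.
#'
#' @param events,n counts.
#' @param digits decimal places (default 1; `NULL` for unrounded).
#' @return percentage.
#' @export
proportion_pct <- function(events, n, digits = 1) {
  assert_that(all(n > 0), "n must be > 0")
  p <- 100 * events / n
  if (is.null(digits)) p else round(p, digits)
}
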