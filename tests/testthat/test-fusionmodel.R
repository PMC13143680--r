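test_that("RFE ranks and retains informative features", {
  # a perfectly separating feature is ranked first
  set.seed(1)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- data.frame(sep = y + rnorm(n, 0, 0.05),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  sel <- rfe_select(X, y, n_keep = 1, folds = 3, num.trees = 150, seed = 1)
  expect_identical(sel$selected, "sep")
  expect_identical(sel$ranking[1], "sep")

  # n_keep = n features: everything retained, ranking still produced
  sel_all <- rfe_select(X, y, n_keep = 4, folds = 3, num.trees = 150, seed = 1)
  expect_setequal(sel_all$selected, names(X))
  expect_identical(sort(sel_all$ranking), sort(names(X)))

  # constant features are discarded first with a warning
  X2 <- cbind(X, flat = 1)
  expect_warning(sel2 <- rfe_select(X2, y, n_keep = 2, folds = 3,
                                    num.trees = 100, seed = 1), "constant")
  expect_false("flat" %in% sel2$selected)
  expect_true("flat" %in% sel2$ranking)
})

test_that("RFE recovers most informative features among noise", {
  hits <- purrr::map_int(1:10, function(s) {
    set.seed(s)
    n <- 300; p <- 40
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(0:1, each = n / 2)
    X[y == 1, 1:8] <- X[y == 1, 1:8] + 1       # 1 SD effects
    sel <- rfe_select(as.data.frame(X), y, n_keep = 8, folds = 3,
                      num.trees = 150, seed = s)
    sum(sel$selected %in% paste0("f", 1:8))
  })
  expect_gte(mean(hits), 6)
})

test_that("nested CV reports sane extremes", {
  # perfectly separable data: apparent and cross-validated AUC of 1
  set.seed(2)
  n <- 120
  dat <- tibble::tibble(x = c(rnorm(n / 2, 0, 0.2), rnorm(n / 2, 5, 0.2)),
                        z = rnorm(n), outcome = rep(0:1, each = n / 2))
  # perfect separation triggers benign pROC/glm edge-case warnings
  rep1 <- suppressWarnings(
    nested_cv_evaluate(dat, c("x", "z"), folds = 5, repeats = 2,
                       seed = 1, num.trees = 200))
  expect_equal(rep1$apparent_auc, 1)
  expect_equal(rep1$cv_auc, 1, tolerance = 1e-3)
  expect_gte(rep1$optimism, -1e-6)
  expect_s3_class(glance(rep1), "tbl_df")
  expect_identical(nrow(tidy(rep1)), 8L)

  expect_error(nested_cv_evaluate(dat[c(1:3, (n - 2):n), ], c("x", "z"),
                                  folds = 5),
               "stratify")
})

test_that("DeLong comparison matches pair-counting arithmetic", {
  y <- c(0, 0, 1, 1)
  d1 <- suppressWarnings(delong_auc(c(0.1, 0.2, 0.8, 0.9),
                                    c(0.1, 0.2, 0.8, 0.9), y))
  expect_equal(d1$auc_a, 1)
  expect_equal(d1$auc_diff, 0)
  expect_equal(d1$p_value, 1)

  d2 <- suppressWarnings(delong_auc(c(0.2, 0.8, 0.4, 0.9),
                                    c(0.1, 0.2, 0.8, 0.9), y))
  expect_equal(d2$auc_a, 0.75)   # 3 of 4 concordant pairs

  # oracle: concordance count on random scores
  set.seed(3)
  yy <- rbinom(60, 1, 0.4); sc <- runif(60)
  pairs <- expand.grid(i = which(yy == 1), j = which(yy == 0))
  auc_hand <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                          ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(delong_auc(sc, sc, yy)$auc_a, auc_hand)

  expect_error(delong_auc(sc, sc, rep(1, 60)), "binary|class")
})

test_that("calibration metrics follow their definitions", {
  # uninformative constant prediction on balanced outcomes: Brier 0.25
  y <- rep(0:1, 50)
  # constant predictions warn twice: merged groups and undefined slope
  expect_warning(expect_warning(
    cal <- calibration_assess(rep(0.5, 100), y), "tied"), "constant")
  expect_equal(cal$brier, 0.25)
  expect_true(is.na(cal$slope))

  # predictions equal to group frequencies: HL chi-square of 0
  pred <- rep(c(0.2, 0.4, 0.6), each = 10)
  yy <- c(rep(c(1, 0, 0, 0, 0), 2), rep(c(1, 1, 0, 0, 0), 2),
          rep(c(1, 1, 1, 0, 0), 2))
  cal2 <- suppressWarnings(calibration_assess(pred, yy, n_groups = 3))
  expect_equal(cal2$hl_chi2, 0, tolerance = 1e-12)

  # self-consistency: outcomes drawn from the stated probabilities
  set.seed(4)
  p <- runif(5000, 0.05, 0.95)
  yb <- rbinom(5000, 1, p)
  cal3 <- calibration_assess(p, yb)
  expect_gt(cal3$slope, 0.9); expect_lt(cal3$slope, 1.1)
  expect_gt(cal3$intercept, -0.1); expect_lt(cal3$intercept, 0.1)
  expect_gt(cal3$hl_p, 0.01)
  expect_error(calibration_assess(c(0, 0.5), c(0, 1)), "predictions")
})

test_that("NRI and IDI match their definitions and a brute-force tally", {
  y <- c(1, 1, 0, 0)
  same <- nri_idi(c(0.6, 0.7, 0.2, 0.3), c(0.6, 0.7, 0.2, 0.3), y,
                  n_boot = 50, seed = 1)
  expect_equal(same$nri, 0, ignore_attr = TRUE)
  expect_equal(same$idi, 0, ignore_attr = TRUE)

  # events rise 0.6 -> 0.8, non-events fall 0.3 -> 0.2: IDI = 0.3
  r <- nri_idi(c(0.6, 0.6, 0.3, 0.3), c(0.8, 0.8, 0.2, 0.2), y,
               n_boot = 50, seed = 1)
  expect_equal(r$idi, 0.3, ignore_attr = TRUE)
  # both events up; non-events one down one up: NRI = 1 + 0 = 1
  r2 <- nri_idi(c(0.5, 0.5, 0.5, 0.5), c(0.7, 0.9, 0.4, 0.6), y,
                n_boot = 50, seed = 1)
  expect_equal(r2$nri, 1, ignore_attr = TRUE)

  # brute-force per-subject tally on a random input
  set.seed(5)
  n <- 50
  yy <- rbinom(n, 1, 0.4)
  po <- runif(n); pn <- runif(n)
  up <- pn > po; down <- pn < po
  nri_bf <- (sum(up & yy == 1) - sum(down & yy == 1)) / sum(yy == 1) +
    (sum(down & yy == 0) - sum(up & yy == 0)) / sum(yy == 0)
  idi_bf <- (sum(pn[yy == 1]) - sum(po[yy == 1])) / sum(yy == 1) -
    (sum(pn[yy == 0]) - sum(po[yy == 0])) / sum(yy == 0)
  got <- nri_idi(po, pn, yy, n_boot = 50, seed = 2)
  expect_equal(got$nri, nri_bf, ignore_attr = TRUE)
  expect_equal(got$idi, idi_bf, ignore_attr = TRUE)
  expect_error(nri_idi(po, pn, rep(0, n)), "event|binary")
})

test_that("decision curves follow the net-benefit formula", {
  set.seed(6)
  y <- rep(c(1, 0), times = c(30, 70))   # prevalence 0.3
  perfect <- ifelse(y == 1, 0.99, 0.01)
  dca <- decision_curve(perfect, y, thresholds = c(0.2, 0.5))
  expect_equal(dca$nb_none, c(0, 0))
  # treat-all at tau = 0.2: 0.3 - 0.7 * 0.25 = 0.125
  expect_equal(dca$nb_all[1], 0.125)
  # perfect classifier at tau = 0.5: all TP, no FP
  expect_equal(dca$nb_model[2], 0.3)

  # NB never exceeds prevalence
  sc <- runif(100)
  dca2 <- decision_curve(sc, y)
  expect_true(all(dca2$nb_model <= 0.3 + 1e-12))
  expect_warning(decision_curve(sc, y, thresholds = c(0.5, 1)), "dropping")
  expect_s3_class(ggplot2::autoplot(dca2), "ggplot")
})

test_that("nomogram points round-trip to logistic probabilities", {
  set.seed(7)
  n <- 150
  d <- data.frame(a = rnorm(n), b = runif(n, 10, 40), c = rnorm(n, 5, 2))
  lp <- -1 + 1.2 * d$a - 0.15 * d$b + 0.4 * d$c
  d$y <- rbinom(n, 1, plogis(lp))
  fit <- glm(y ~ a + b + c, data = d, family = binomial())
  nom <- build_nomogram(fit)
  expect_equal(max(nom$table$max_points), 100)
  pred <- predict_nomogram(nom, d)
  direct <- predict(fit, d, type = "response")
  expect_lt(max(abs(pred$probability - direct)), 0.005)
  expect_true(all(pred$total_points >= -1e-9))

  # single-feature model: exact equality
  fit1 <- glm(y ~ a, data = d, family = binomial())
  nom1 <- build_nomogram(fit1)
  expect_equal(predict_nomogram(nom1, d)$probability,
               unname(predict(fit1, d, type = "response")), tolerance = 1e-12)
  # all features at their reference values: zero points
  ref_row <- setNames(as.data.frame(as.list(nom$table$reference)),
                      nom$table$feature)
  expect_equal(predict_nomogram(nom, ref_row)$total_points, 0)
})

test_that("sample-size formulas evaluate correctly", {
  expect_identical(epv(100, 8), 12.5)
  expect_identical(epv(0, 5), 0)
  expect_identical(epv(30, 3), 10)
  expect_error(epv(10, 0), "predictors")

  expect_identical(riley_min_n(15, 0.25, 0.9), 461)
  expect_identical(riley_min_n(8, 0.25, 0.9), 246)
  # linearity in p: doubling p doubles the pre-rounding n
  expect_identical(riley_min_n(30, 0.25, 0.9),
                   ceiling(2 * 15 / ((0.9 - 1) * log(1 - 0.25 / 0.9))))
  expect_error(riley_min_n(8, 0.95, 0.9), "r2cs")

  expect_equal(hanley_se_auc(0.8, 41, 41), 0.0492, tolerance = 1e-3)
  expect_equal(hanley_se_auc(0.5, 41, 41), 0.0641, tolerance = 1e-3)
  expect_lt(hanley_se_auc(0.8, 100, 41), hanley_se_auc(0.8, 41, 41))

  expect_identical(proportion_pct(6, 17), 35.3)
  expect_identical(proportion_pct(42, 80), 52.5)
})
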