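# scale helper retaining centre/scale for prediction
uv_scale <- function(X, center = NULL, scale_ = NULL) {
  center <- center %||% colMeans(X)
  scale_ <- scale_ %||% apply(X, 2, sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  list(X = sweep(sweep(X, 2, center), 2, scale_, "/"),
       center = center, scale = scale_)
}

# core NIPALS O-PLS decomposition with one predictive component;
# returns everything needed to predict new samples
opls_core <- function(Xs, yc, n_ortho) {
  w <- crossprod(Xs, yc) / c(crossprod(yc))
  w <- w / sqrt(sum(w^2))
  W_o <- list(); P_o <- list()
  E <- Xs
  j <- 0L
  while (j < n_ortho) {
    t_p <- E %*% w
    p <- crossprod(E, t_p) / c(crossprod(t_p))
    w_o <- p - c(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10) break
    w_o <- w_o / nw
    t_o <- E %*% w_o
    p_o <- crossprod(E, t_o) / c(crossprod(t_o))
    E <- E - t_o %*% t(p_o)
    j <- j + 1L
    W_o[[j]] <- w_o; P_o[[j]] <- p_o
  }
  t_p <- E %*% w
  p_p <- crossprod(E, t_p) / c(crossprod(t_p))
  q <- c(crossprod(yc, t_p)) / c(crossprod(t_p))
  list(w = w, W_o = W_o, P_o = P_o, t_pred = t_p, p_pred = p_p, q = q,
       n_ortho = j)
}

# orthogonal-filter new (already scaled) samples and return predicted yc
opls_predict_core <- function(core, Xs) {
  E <- Xs
  for (j in seq_along(core$W_o)) {
    t_o <- E %*% core$W_o[[j]]
    E <- E - t_o %*% t(core$P_o[[j]])
  }
  drop(E %*% core$w) * core$q
}

# deterministic fold assignment
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# cross-validated Q2 for a given number of orthogonal components
opls_q2 <- function(X, y01, n_ortho, k = 7, seed = 1) {
  yc_all <- y01 - mean(y01)
  folds <- make_folds(nrow(X), k, seed)
  press <- 0
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- uv_scale(X[tr, , drop = FALSE])
    ytr <- y01[tr]
    core <- opls_core(sc$X, ytr - mean(ytr), n_ortho)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, sc$center), 2, sc$scale, "/")
    pred <- opls_predict_core(core, Xte) + mean(ytr)
    press <- press + sum((y01[!tr] - pred)^2)
  }
  1 - press / sum(yc_all^2)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for two
#' classes: a NIPALS O-PLS decomposition with a single predictive component
#' and `n_ortho` orthogonal (class-irrelevant) components. Columns are
#' centred and unit-variance scaled internally. R2Y is the fraction of class
#' variance explained by the fit; Q2 is its k-fold cross-validated
#' counterpart. With `n_ortho = NULL` the model starts at one orthogonal
#' component and keeps adding while Q2 improves by more than 0.01 (up to
#' `max_ortho`).
#'
#' @param X numeric samples x features matrix (>= 2 samples per class).
#' @param y binary labels (factor, logical or 0/1).
#' @param n_ortho number of orthogonal components, or `NULL` for automatic.
#' @param cv_folds folds for Q2 (default 7).
#' @param max_ortho cap for automatic selection.
#' @param seed seed controlling the CV fold assignment.
#' @return object of class `opls_model` with elements `r2y`, `q2`, `vip`,
#'   `scores` (predictive and orthogonal), `weights`, `loadings`, `n_ortho`.
#' @export
oplsda_fit <- function(X, y, n_ortho = 1, cv_folds = 7, max_ortho = 5,
                       seed = 1) {
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  assert_that(min(table(y01)) >= 2, "need >= 2 samples per class")
  if (is.null(n_ortho)) {
    q_prev <- opls_q2(X, y01, 1, k = cv_folds, seed = seed)
    n_ortho <- 1
    while (n_ortho < max_ortho) {
      q_next <- opls_q2(X, y01, n_ortho + 1, k = cv_folds, seed = seed)
      if (q_next - q_prev <= 0.01) break
      q_prev <- q_next; n_ortho <- n_ortho + 1
    }
  }
  sc <- uv_scale(X)
  yc <- y01 - mean(y01)
  core <- opls_core(sc$X, yc, n_ortho)
  yhat <- drop(core$t_pred) * core$q
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  q2 <- opls_q2(X, y01, core$n_ortho, k = cv_folds, seed = seed)
  p <- ncol(X)
  vip <- sqrt(p) * abs(drop(core$w))
  names(vip) <- colnames(X) %||% paste0("V", seq_len(p))
  t_orth <- if (core$n_ortho > 0)
    do.call(cbind, purrr::map(core$W_o, function(wo) sc$X %*% wo)) else NULL
  structure(list(r2y = r2y, q2 = q2, vip = vip,
                 weights = drop(core$w), loadings = drop(core$p_pred),
                 q = core$q, scores = drop(core$t_pred),
                 scores_orth = t_orth, n_ortho = core$n_ortho,
                 center = sc$center, scale = sc$scale, core = core,
                 y = y01, y_mean = mean(y01), cv_folds = cv_folds,
                 seed = seed),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive +", x$n_ortho, "orthogonal component(s)\n")
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f (%d-fold CV)\n", x$r2y, x$q2,
              x$cv_folds))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP of every feature on the predictive component. For a single predictive
#' component the VIP reduces to \eqn{\sqrt{p}\,|w_j|} with unit-norm weights,
#' so the mean squared VIP is exactly 1.
#'
#' @param model an `opls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  assert_that(inherits(model, "opls_model"), "model must be an opls_model")
  model$vip
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model under `n_perm` random label permutations and applies the
#' standard two-condition pass rule: every permuted R2Y and Q2 must fall below
#' the original values, and the intercept of the regression of permuted Q2 on
#' the absolute label correlation (the Q2 line of the validation plot, which
#' includes the unpermuted point at correlation 1) must be negative.
#'
#' @param X,y data as in [oplsda_fit()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param n_ortho,cv_folds passed to the refits (defaults follow the original
#'   model).
#' @return object of class `permutation_report`: tibble of permuted `r2y`,
#'   `q2`, `cor` plus attributes `original` (model), `q2_intercept`,
#'   `r2y_intercept`, `pass`.
#' @export
permutation_test <- function(X, y, n_perm = 1000, seed = 1, n_ortho = 1,
                             cv_folds = 7) {
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  orig <- oplsda_fit(X, y01, n_ortho = n_ortho, cv_folds = cv_folds)
  set.seed(seed)
  perms <- purrr::map(seq_len(n_perm), function(i) {
    yp <- sample(y01)
    m <- oplsda_fit(X, yp, n_ortho = n_ortho, cv_folds = cv_folds)
    tibble(perm = i, r2y = m$r2y, q2 = m$q2, cor = abs(stats::cor(yp, y01)))
  }) |> list_rbind()
  line <- dplyr::bind_rows(perms[, c("r2y", "q2", "cor")],
                           tibble(r2y = orig$r2y, q2 = orig$q2, cor = 1))
  q2_int <- unname(coef(lm(q2 ~ cor, data = line))[1])
  r2_int <- unname(coef(lm(r2y ~ cor, data = line))[1])
  pass <- all(perms$r2y < orig$r2y) && all(perms$q2 < orig$q2) && q2_int < 0
  structure(perms, class = c("permutation_report", class(perms)),
            original = orig, q2_intercept = q2_int, r2y_intercept = r2_int,
            pass = pass)
}

#' @export
print.permutation_report <- function(x, ...) {
  o <- attr(x, "original")
  cat(sprintf("permutation validation: %d permutations\n", nrow(x)))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n", o$r2y, o$q2))
  cat(sprintf("  max permuted R2Y = %.3f, Q2 = %.3f\n",
              max(x$r2y), max(x$q2)))
  cat(sprintf("  Q2 intercept = %.3f; pass = %s\n",
              attr(x, "q2_intercept"), attr(x, "pass")))
  invisible(x)
}

#' Differential feature selection
#'
#' Selects features with VIP > `vip_threshold` on the OPLS-DA predictive
#' component and Benjamini-Hochberg FDR below `fdr_threshold` from
#' nonparametric per-feature tests (Mann-Whitney U for two groups,
#' Kruskal-Wallis otherwise).
#'
#' @param X samples x features matrix.
#' @param y group labels (two or more groups; VIP requires exactly two).
#' @param vip optional precomputed VIP vector; computed from an OPLS-DA fit
#'   when omitted (two-group case only).
#' @param vip_threshold,fdr_threshold the selection cuts (1.0 and 0.05).
#' @return tibble: `feature`, `vip`, `p_value`, `fdr`, `log2fc` (difference
#'   of group means when data can be negative, log2 ratio otherwise),
#'   `direction`, `selected`.
#' @export
differential_select <- function(X, y, vip = NULL, vip_threshold = 1.0,
                                fdr_threshold = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  grp <- factor(y)
  two <- nlevels(grp) == 2L
  if (is.null(vip)) {
    assert_that(two, "supply VIP explicitly for more than two groups")
    vip <- oplsda_fit(X, grp)$vip
  }
  stats_tbl <- purrr::map(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    p <- if (two)
      suppressWarnings(wilcox.test(x ~ grp)$p.value)
    else kruskal.test(x, grp)$p.value
    if (two) {
      m <- tapply(x, grp, mean)
      l2fc <- if (all(x > 0)) log2(m[2] / m[1]) else m[2] - m[1]
    } else l2fc <- NA_real_
    tibble(feature = colnames(X)[j], p_value = p, log2fc = unname(l2fc))
  }) |> list_rbind()
  stats_tbl |>
    mutate(vip = unname(vip[.data$feature]),
           fdr = p.adjust(.data$p_value, method = "BH"),
           direction = sign(.data$log2fc),
           selected = .data$vip > vip_threshold & .data$fdr < fdr_threshold) |>
    select("feature", "vip", "p_value", "fdr", "log2fc", "direction",
           "selected")
}
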