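#' Major adverse renal event (MARE) definition
#'
#' The composite endpoint: sustained relative eGFR decline of at least
#' `egfr_decline_pct` percent from baseline (confirmed at two consecutive
#' visits), onset of macroalbuminuria (UACR strictly above
#' `macroalbuminuria_uacr` mg/g), or progression to ESRD.
#'
#' @param egfr_decline_pct relative decline threshold in percent (default 30).
#' @param macroalbuminuria_uacr UACR threshold in mg/g (default 300).
#' @return object of class `mare_definition`.
#' @export
mare_definition <- function(egfr_decline_pct = 30,
                            macroalbuminuria_uacr = 300) {
  assert_that(egfr_decline_pct > 0 && macroalbuminuria_uacr > 0,
              "thresholds must be > 0")
  structure(list(egfr_decline_pct = egfr_decline_pct,
                 macroalbuminuria_uacr = macroalbuminuria_uacr),
            class = "mare_definition")
}

#' Classify MARE from longitudinal follow-up
#'
#' Scans each subject's visit history for the composite endpoint. "Sustained"
#' eGFR decline means the relative decline threshold is met at two
#' consecutive visits; the event time is the confirming (second) visit.
#' Macroalbuminuria requires UACR strictly above the threshold (boundary
#' exclusive), eGFR decline is boundary inclusive (>= threshold). Subjects
#' without a qualifying event are censored at their last visit.
#'
#' @param baseline tibble with `subject_id` and baseline `egfr` (> 0).
#' @param visits tibble with `subject_id`, `time_years`, `egfr`, `uacr` and
#'   optionally logical `esrd`; visits are sorted by time within subject.
#' @param definition a [mare_definition()].
#' @return tibble: `subject_id`, `event` (0/1), `event_subtype`
#'   (`"egfr_decline"`, `"macroalbuminuria"`, `"esrd"` or `"censored"`),
#'   `time_years`.
#' @export
classify_mare <- function(baseline, visits, definition = mare_definition()) {
  assert_that(all(c("subject_id", "egfr") %in% names(baseline)),
              "baseline needs subject_id and egfr")
  assert_that(!anyNA(baseline$egfr) && all(baseline$egfr > 0),
              "missing or non-positive baseline eGFR")
  if (!"esrd" %in% names(visits)) visits$esrd <- FALSE
  purrr::map(seq_len(nrow(baseline)), function(i) {
    sid <- baseline$subject_id[i]
    e0 <- baseline$egfr[i]
    v <- visits |> filter(.data$subject_id == sid) |> arrange(.data$time_years)
    if (nrow(v) == 0) {
      return(tibble(subject_id = sid, event = 0L,
                    event_subtype = "censored", time_years = 0))
    }
    thr <- e0 * (1 - definition$egfr_decline_pct / 100)
    dec <- v$egfr <= thr
    t_egfr <- Inf
    if (nrow(v) >= 2) {
      conf <- which(dec[-1] & dec[-nrow(v)])   # consecutive pair
      if (length(conf)) t_egfr <- v$time_years[conf[1] + 1]
    }
    t_macro <- suppressWarnings(
      min(v$time_years[v$uacr > definition$macroalbuminuria_uacr]))
    t_esrd <- suppressWarnings(min(v$time_years[v$esrd]))
    times <- c(egfr_decline = t_egfr, macroalbuminuria = t_macro,
               esrd = t_esrd)
    if (all(!is.finite(times))) {
      tibble(subject_id = sid, event = 0L, event_subtype = "censored",
             time_years = max(v$time_years))
    } else {
      k <- which.min(times)
      tibble(subject_id = sid, event = 1L, event_subtype = names(times)[k],
             time_years = unname(times[k]))
    }
  }) |> list_rbind()
}

#' Risk stratification at the 0.5 score threshold
#'
#' @param scores model risk scores in \[0, 1\].
#' @param cutoff stratification threshold (default 0.5, boundary inclusive
#'   into `"high"`).
#' @return factor with levels `"low"`, `"high"`.
#' @export
risk_stratify <- function(scores, cutoff = 0.5) {
  assert_that(all(scores >= 0 & scores <= 1), "scores must lie in [0, 1]")
  factor(ifelse(scores >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Monte-Carlo projection of event rates
#'
#' Projects the event incidence of each risk stratum by repeated Bernoulli
#' simulation of the per-subject event probabilities: per iteration every
#' subject's event is drawn once, and the stratum event rates are summarised
#' across iterations by their mean and percentile confidence interval.
#'
#' @param event_probs per-subject event probabilities in \[0, 1\].
#' @param strata optional stratum labels (single stratum when omitted);
#'   empty strata are dropped with a warning.
#' @param iterations Monte-Carlo iterations (default 1000).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return tibble of class `mc_projection`: `stratum`, `n`,
#'   `expected_rate` (analytic mean probability), `projected_rate`,
#'   `ci_low`, `ci_high`, `iterations`.
#' @export
monte_carlo_projection <- function(event_probs, strata = NULL,
                                   iterations = 1000, seed = 1,
                                   conf = 0.95) {
  assert_that(all(event_probs >= 0 & event_probs <= 1),
              "probabilities must lie in [0, 1]")
  strata <- strata %||% rep("all", length(event_probs))
  strata <- as.character(strata)
  keep <- !is.na(strata)
  if (any(!keep)) {
    warn("dropping subjects with missing stratum")
    event_probs <- event_probs[keep]; strata <- strata[keep]
  }
  set.seed(seed)
  n <- length(event_probs)
  draws <- matrix(rbinom(n * iterations, 1, rep(event_probs, iterations)),
                  nrow = n)
  a <- (1 - conf) / 2
  out <- purrr::map(unique(strata), function(s) {
    idx <- strata == s
    rates <- colMeans(draws[idx, , drop = FALSE])
    tibble(stratum = s, n = sum(idx),
           expected_rate = mean(event_probs[idx]),
           projected_rate = mean(rates),
           ci_low = unname(quantile(rates, a)),
           ci_high = unname(quantile(rates, 1 - a)),
           iterations = iterations)
  }) |> list_rbind()
  class(out) <- c("mc_projection", class(out))
  out
}

# shared formula builder for the survival wrappers
surv_formula <- function(group, covariates) {
  stats::reformulate(c(group, covariates),
                     response = "survival::Surv(time_years, status)")
}

#' Cox proportional-hazards hazard ratio
#'
#' Partial-likelihood hazard ratio for a group indicator, adjusted for
#' covariates, with Wald confidence intervals. Breslow tie handling is used
#' so that the estimate coincides exactly with the Fine-Gray model when no
#' competing events exist.
#'
#' @param data data frame with `time_years` plus the named columns below.
#' @param event name of the 0/1 primary-event column.
#' @param group name of the exposure column (numeric or two-level factor).
#' @param covariates character vector of adjustment columns.
#' @param conf confidence level.
#' @return tibble: `term`, `hr`, `ci_low`, `ci_high`, `p_value`, `n_events`.
#' @export
cox_hr <- function(data, event = "event", group = "group",
                   covariates = character(), conf = 0.95) {
  d <- as.data.frame(data)
  st <- d[[event]]
  if (is.logical(st)) st <- as.integer(st)
  assert_that(all(st %in% c(0, 1)), "event must be coded 0/1")
  d$status <- as.numeric(st)
  assert_that(sum(d$status) > 0, "no events observed")
  fit <- survival::coxph(surv_formula(group, covariates), data = d,
                         ties = "breslow")
  s <- summary(fit, conf.int = conf)
  tibble(term = rownames(s$coefficients),
         hr = unname(s$coefficients[, "exp(coef)"]),
         ci_low = unname(s$conf.int[, 3]),
         ci_high = unname(s$conf.int[, 4]),
         p_value = unname(s$coefficients[, "Pr(>|z|)"]),
         n_events = sum(d$status))
}

#' Fine-Gray subdistribution hazard ratio
#'
#' Subdistribution hazard model treating competing (non-renal) death as a
#' competing risk: subjects experiencing the competing event remain in the
#' risk set with inverse-probability-of-censoring weights, so the estimated
#' association with the primary event is not biased by informative removal.
#' With no competing events the estimate reduces exactly to the Cox model.
#'
#' @param data data frame with `time_years` and an event-type column.
#' @param event_type name of the column coding `"primary"`,
#'   `"competing_death"`, `"censored"` (or integers 1/2/0).
#' @param group,covariates as in [cox_hr()].
#' @param conf confidence level.
#' @return tibble: `term`, `shr`, `ci_low`, `ci_high`, `p_value`,
#'   `n_primary`, `n_competing`.
#' @export
fine_gray_shr <- function(data, event_type = "event_type", group = "group",
                          covariates = character(), conf = 0.95) {
  d <- as.data.frame(data)
  et <- d[[event_type]]
  if (!is.numeric(et)) {
    et <- dplyr::case_match(as.character(et), "primary" ~ 1L,
                            "competing_death" ~ 2L, "censored" ~ 0L)
  }
  assert_that(!anyNA(et), "event_type must be primary/competing_death/censored")
  assert_that(sum(et == 1) > 0, "no primary events observed")
  covs <- as.matrix(as.data.frame(
    purrr::map(d[, c(group, covariates), drop = FALSE], as.numeric)))
  # tight gradient tolerance first (exact Cox agreement in the degenerate
  # no-competing-events case), relaxing only if the optimiser stalls
  fit <- NULL
  for (gtol in c(1e-10, 1e-8, 1e-6)) {
    fit <- cmprsk::crr(ftime = d$time_years, fstatus = et, cov1 = covs,
                       failcode = 1, cencode = 0, gtol = gtol, maxiter = 100)
    if (fit$converged) break
  }
  assert_that(fit$converged, "Fine-Gray model did not converge")
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf) / 2)
  tibble(term = colnames(covs),
         shr = exp(fit$coef),
         ci_low = exp(fit$coef - z * se),
         ci_high = exp(fit$coef + z * se),
         p_value = 2 * pnorm(-abs(fit$coef / se)),
         n_primary = sum(et == 1), n_competing = sum(et == 2))
}

#' Incidence rate per person-time
#'
#' @param events number of events.
#' @param person_years accumulated person-years (> 0).
#' @param scale reporting scale (default per 1000 person-years).
#' @return rate, `scale * events / person_years`.
#' @export
incidence_rate <- function(events, person_years, scale = 1000) {
  assert_that(all(person_years > 0), "person-years must be > 0")
  scale * events / person_years
}
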