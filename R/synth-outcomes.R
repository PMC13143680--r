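#' Outcome generator configuration
#'
#' Event histories are exponential within a fixed horizon, with group-specific
#' annual hazards for the primary renal composite and a constant competing
#' (non-renal) mortality hazard. Within the T2DM-NoDKD group the latent
#' high-risk stratum is assigned a proportional hazard multiplier
#' (`hr_high_vs_low`); the low-stratum hazard is solved so that the group's
#' marginal 3-year risk matches the configured value given the expected
#' stratum mix.
#'
#' Defaults reproduce the projected 3-year composite risks by group
#' (HC 0%, T2DM-NoDKD 7.8%, DKD 34.0%) and the published high/low stratum
#' hazard ratio of 12.5.
#'
#' @param horizon_years projection horizon (default 3).
#' @param group_risk_3y named per-group probability of the primary event
#'   within the horizon (`hc`, `t2dm`, `dkd`).
#' @param hr_high_vs_low hazard ratio of the high- vs low-risk stratum inside
#'   the T2DM-NoDKD group.
#' @param high_risk_frac expected high-risk fraction inside T2DM-NoDKD used to
#'   solve the stratum hazards (default 17/102).
#' @param competing_mortality_hazard annual non-renal mortality hazard.
#' @param seed integer seed.
#' @return object of class `outcome_config`.
#' @export
outcome_config <- function(horizon_years = 3,
                           group_risk_3y = c(hc = 0, t2dm = 0.078, dkd = 0.34),
                           hr_high_vs_low = 12.5,
                           high_risk_frac = 17 / 102,
                           competing_mortality_hazard = 0.02,
                           seed = 1L) {
  assert_that(horizon_years > 0, "horizon must be > 0")
  assert_that(all(group_risk_3y >= 0 & group_risk_3y < 1),
              "group risks must lie in [0, 1)")
  assert_that(competing_mortality_hazard >= 0 && hr_high_vs_low > 0,
              "hazards must be >= 0")
  structure(list(horizon_years = horizon_years,
                 group_risk_3y = group_risk_3y,
                 hr_high_vs_low = hr_high_vs_low,
                 high_risk_frac = high_risk_frac,
                 competing_mortality_hazard = competing_mortality_hazard,
                 seed = as.integer(seed)),
            class = "outcome_config")
}

# annual hazard giving probability `risk` of an event within `horizon` years
hazard_from_risk <- function(risk, horizon) {
  ifelse(risk <= 0, 0, -log(1 - risk) / horizon)
}

#' Generate synthetic time-to-event outcomes
#'
#' Draws, for each cohort subject, an exponential primary-event time at the
#' subject's hazard and an exponential competing-mortality time; the first of
#' (primary, competing death, administrative censoring at the horizon) is
#' recorded.
#'
#' @param cohort a `cohort_table` with `group` and `risk_stratum` columns.
#' @param config an [outcome_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return tibble (class `outcome_table`) with `subject_id`, `group`,
#'   `risk_stratum`, `time_years`, `event` (0/1 primary), `event_type`
#'   (`"primary"`, `"competing_death"` or `"censored"`).
#' @export
generate_outcomes <- function(cohort, config = outcome_config(), seed = NULL) {
  assert_that("risk_stratum" %in% names(cohort),
              "cohort must carry a risk_stratum column")
  assert_that(inherits(config, "outcome_config"),
              "config must be an outcome_config")
  set.seed(seed %||% config$seed)
  H <- config$horizon_years
  lam_g <- hazard_from_risk(config$group_risk_3y, H)

  # split the T2DM group hazard into stratum hazards matching the marginal risk
  p_hi <- config$high_risk_frac
  hr <- config$hr_high_vs_low
  risk_t2dm <- config$group_risk_3y[["t2dm"]]
  lam_lo <- if (risk_t2dm <= 0) 0 else
    uniroot(function(l) {
      p_hi * (1 - exp(-hr * l * H)) + (1 - p_hi) * (1 - exp(-l * H)) - risk_t2dm
    }, c(1e-10, hazard_from_risk(risk_t2dm, H) * 2))$root

  lam <- dplyr::case_when(
    cohort$group == "hc"  ~ lam_g[["hc"]],
    cohort$group == "dkd" ~ lam_g[["dkd"]],
    cohort$risk_stratum == "high" ~ lam_lo * hr,
    TRUE ~ lam_lo)

  n <- nrow(cohort)
  t_primary <- ifelse(lam > 0, rexp(n, pmax(lam, 1e-300)), Inf)
  lam_d <- config$competing_mortality_hazard
  t_death <- if (lam_d > 0) rexp(n, lam_d) else rep(Inf, n)

  time <- pmin(t_primary, t_death, H)
  type <- dplyr::case_when(
    t_primary <= t_death & t_primary <= H ~ "primary",
    t_death < t_primary & t_death <= H ~ "competing_death",
    TRUE ~ "censored")
  out <- tibble(subject_id = cohort$subject_id, group = cohort$group,
                risk_stratum = cohort$risk_stratum,
                time_years = time,
                event = as.integer(type == "primary"),
                event_type = type)
  class(out) <- c("outcome_table", class(out))
  out
}
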