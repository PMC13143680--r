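#' Metabolite panel effect configuration
#'
#' Configures [generate_metabolite_panel()]. Each row of `effects` describes
#' one targeted metabolite: geometric-mean baseline concentrations in serum
#' and urine (umol/L), the DKD-vs-T2DM log2 fold changes in each fluid, the
#' platform limit of detection (umol/L) per fluid, and the fraction of values
#' set missing completely at random.
#'
#' The defaults emulate the "high serum / low urine" flux mismatch of
#' protein-bound uremic toxins (indoxyl sulfate, p-cresyl sulfate,
#' phenylacetylglutamine), the serum accumulation of acylcarnitines, and the
#' urinary depletion of TCA-cycle intermediates, on top of realistic baseline
#' concentrations. The indoxyl sulfate and p-cresyl sulfate LODs are the
#' validated platform values (15.2 and 22.4 nmol/L).
#'
#' @param effects tibble with columns `metabolite`, `base_serum`, `base_urine`,
#'   `serum_log2fc`, `urine_log2fc`, `lod`, `missing_rate`.
#' @param conc_sdlog log-scale biological SD of concentrations (default 0.4).
#' @param urine_creatinine_mmol median and quartiles (mmol/L) for urinary
#'   creatinine, log-normal across subjects.
#' @param seed integer seed.
#' @return object of class `flux_effect_config`.
#' @export
flux_effect_config <- function(effects = default_flux_effects(),
                               conc_sdlog = 0.4,
                               urine_creatinine_mmol = c(10, 7, 15),
                               seed = 1L) {
  req <- c("metabolite", "base_serum", "base_urine", "serum_log2fc",
           "urine_log2fc", "lod", "missing_rate")
  assert_that(all(req %in% names(effects)), "effects table is missing columns")
  assert_that(all(effects$lod > 0), "lod must be > 0")
  assert_that(all(effects$missing_rate >= 0 & effects$missing_rate <= 0.5),
              "missing_rate must lie in [0, 0.5]")
  assert_that(!"creatinine" %in% effects$metabolite,
              "creatinine is generated from the cohort, not the effects table")
  structure(list(effects = effects, conc_sdlog = conc_sdlog,
                 urine_creatinine_mmol = urine_creatinine_mmol,
                 seed = as.integer(seed)),
            class = "flux_effect_config")
}

#' Default targeted-panel effects
#' @return tibble accepted by [flux_effect_config()].
#' @export
default_flux_effects <- function() {
  tibble(
    metabolite   = c("indoxyl_sulfate", "p_cresyl_sulfate", "phenylacetylglutamine",
                     "c8_carnitine", "c16_carnitine", "c18_carnitine",
                     "succinate", "citrate", "kynurenine", "tryptophan"),
    base_serum   = c(2.0, 3.5, 4.0, 0.15, 0.12, 0.08, 5.0, 120, 2.0, 55),
    base_urine   = c(60, 90, 250, 0.9, 0.25, 0.15, 45, 350, 3.5, 60),
    serum_log2fc = c(1.5, 1.2, 1.0, 0.8, 0.9, 0.9, 0.3, -0.2, 0.7, -0.3),
    urine_log2fc = c(-1.0, -0.8, -0.7, -0.5, -0.4, -0.4, -0.8, -0.6, 0.5, -0.4),
    lod          = c(0.0152, 0.0224, 0.05, 0.005, 0.005, 0.005, 0.5, 1.0, 0.02, 0.5),
    missing_rate = c(0.02, 0.02, 0.05, 0.08, 0.10, 0.12, 0.05, 0.02, 0.05, 0.02)
  )
}

#' Generate a paired serum/urine metabolite panel
#'
#' Draws absolute concentrations (umol/L) for every subject x metabolite in
#' both fluids, including creatinine (serum creatinine is carried over from
#' the cohort; urinary creatinine is log-normal). DKD subjects receive the
#' configured log2 fold changes in each fluid. Values that fall below the
#' platform LOD are recorded as censored (`concentration` is `NA`,
#' `censored = TRUE`); the configured fraction of values is additionally set
#' missing completely at random (`censored = FALSE`). Creatinine is never
#' missing or censored.
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param config a [flux_effect_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return long tibble (class `paired_panel`) with columns `subject_id`,
#'   `group`, `metabolite`, `fluid`, `concentration`, `censored`, `lod`.
#' @export
generate_metabolite_panel <- function(cohort, config = flux_effect_config(),
                                      seed = NULL) {
  assert_that(nrow(cohort) > 0, "cohort must be non-empty")
  assert_that(inherits(config, "flux_effect_config"),
              "config must be a flux_effect_config")
  set.seed(seed %||% config$seed)
  eff <- config$effects
  n <- nrow(cohort)
  is_dkd <- cohort$group == "dkd"

  panel <- purrr::map(seq_len(nrow(eff)), function(i) {
    e <- eff[i, ]
    draw <- function(base, l2fc) {
      base * 2^(l2fc * is_dkd) * exp(rnorm(n, 0, config$conc_sdlog))
    }
    purrr::map(c("serum", "urine"), function(fl) {
      conc <- if (fl == "serum") draw(e$base_serum, e$serum_log2fc)
              else draw(e$base_urine, e$urine_log2fc)
      cens <- conc < e$lod
      conc[cens] <- NA_real_
      miss <- !cens & runif(n) < e$missing_rate
      conc[miss] <- NA_real_
      tibble(subject_id = cohort$subject_id, group = cohort$group,
             metabolite = e$metabolite, fluid = fl,
             concentration = conc, censored = cens, lod = e$lod)
    }) |> list_rbind()
  }) |> list_rbind()

  ucr <- config$urine_creatinine_mmol
  lp <- lnorm_from_quartiles(ucr[1] * 1000, ucr[2] * 1000, ucr[3] * 1000)
  creat <- dplyr::bind_rows(
    tibble(subject_id = cohort$subject_id, group = cohort$group,
           metabolite = "creatinine", fluid = "serum",
           concentration = cohort$serum_creatinine, censored = FALSE,
           lod = 1),
    tibble(subject_id = cohort$subject_id, group = cohort$group,
           metabolite = "creatinine", fluid = "urine",
           concentration = rlnorm(n, lp$meanlog, lp$sdlog), censored = FALSE,
           lod = 1))

  out <- dplyr::bind_rows(panel, creat) |>
    arrange(.data$subject_id, .data$metabolite, .data$fluid)
  class(out) <- c("paired_panel", class(out))
  out
}
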