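#' Drop metabolites with excessive missingness
#'
#' A metabolite is excluded when its missing fraction strictly exceeds the
#' threshold in *either* biofluid. Below-LOD censored entries are not
#' missingness (they carry information) and do not count; creatinine is never
#' dropped. Dropped metabolite names are attached as the
#' `"dropped_metabolites"` attribute and messaged.
#'
#' @param panel a long `paired_panel` tibble (columns `subject_id`,
#'   `metabolite`, `fluid`, `concentration`, `censored`, `lod`).
#' @param threshold maximum tolerated missing fraction (default 0.20).
#' @return the filtered panel.
#' @export
filter_missingness <- function(panel, threshold = 0.20) {
  miss <- panel |>
    mutate(missing = is.na(.data$concentration) & !.data$censored) |>
    summarise(frac = mean(.data$missing),
              .by = c("metabolite", "fluid"))
  drop <- miss |>
    filter(.data$frac > threshold, .data$metabolite != "creatinine") |>
    pull(.data$metabolite) |>
    unique()
  out <- panel |> filter(!.data$metabolite %in% drop)
  if (length(drop)) {
    message("dropping ", length(drop), " metabolite(s) with >",
            round(100 * threshold), "% missing values: ",
            paste(drop, collapse = ", "))
  }
  attr(out, "dropped_metabolites") <- drop
  out
}

#' K-nearest-neighbour imputation of missing panel values
#'
#' Missing (not censored) concentrations are replaced, per biofluid, by the
#' mean of the k nearest subjects' observed values. Distances are Euclidean
#' over z-scored log10 concentrations of the features observed in both
#' subjects (censored entries enter the distance at LOD/2); ties are broken
#' by subject order, making the result deterministic. When fewer than k
#' complete neighbours exist, all available ones are used; when none exist an
#' error is raised.
#'
#' @param panel a `paired_panel` (after [filter_missingness()]).
#' @param k number of neighbours (default 5).
#' @return panel with missing values imputed and a logical `knn_imputed`
#'   column.
#' @export
knn_impute <- function(panel, k = 5) {
  panel$knn_imputed <- FALSE
  for (fl in unique(panel$fluid)) {
    sub <- panel[panel$fluid == fl, ]
    # working value for distances: observed, or LOD/2 when censored
    wv <- ifelse(sub$censored & is.na(sub$concentration),
                 sub$lod / 2, sub$concentration)
    wide <- tibble(subject_id = sub$subject_id, metabolite = sub$metabolite,
                   value = log10(wv)) |>
      pivot_wider(names_from = "metabolite", values_from = "value")
    ids <- wide$subject_id
    M <- as.matrix(wide[, -1, drop = FALSE])
    Mz <- scale(M)
    Mz[, attr(Mz, "scale") == 0 | is.na(attr(Mz, "scale"))] <- 0
    obsM <- !is.na(M)
    need <- which(is.na(M), arr.ind = TRUE)
    if (nrow(need)) {
      for (r in unique(need[, 1])) {
        js <- need[need[, 1] == r, 2]
        cand <- which(seq_along(ids) != r)
        shared <- obsM[r, , drop = TRUE]
        d2 <- purrr::map_dbl(cand, function(cc) {
          use <- shared & obsM[cc, ]
          if (!any(use)) return(Inf)
          sum((Mz[r, use] - Mz[cc, use])^2) / sum(use)
        })
        ord <- cand[order(d2, cand)]
        for (j in js) {
          donors <- ord[!is.na(M[ord, j])]
          assert_that(length(donors) > 0,
                      paste0("no complete neighbour available for ",
                             colnames(M)[j]))
          use <- head(donors, k)
          imput <- mean(10^M[use, j])
          sel <- panel$fluid == fl & panel$subject_id == ids[r] &
            panel$metabolite == colnames(M)[j]
          panel$concentration[sel] <- imput
          panel$knn_imputed[sel] <- TRUE
        }
      }
    }
  }
  panel
}

#' Impute below-LOD values as LOD/2
#'
#' Every censored entry is set to half its platform limit of detection, the
#' standard substitution that keeps the downstream log transform finite.
#'
#' @param panel a `paired_panel`.
#' @return panel with censored concentrations filled and a logical
#'   `lod_imputed` column.
#' @export
impute_lod <- function(panel) {
  cen <- panel$censored & is.na(panel$concentration)
  assert_that(!any(cen & is.na(panel$lod)),
              "censored entry without an LOD value")
  panel$lod_imputed <- cen
  panel$concentration[cen] <- panel$lod[cen] / 2
  panel
}

#' Serum-to-urine flux ratio matrix
#'
#' For every subject and metabolite the double-creatinine-normalised flux
#' ratio
#' \deqn{\log_{10}\frac{[C]^{serum}_{met} / [C]^{serum}_{creat}}
#'                     {[C]^{urine}_{met} / [C]^{urine}_{creat}}}
#' is computed. High values flag systemic retention with low urinary
#' excretion (a tubular secretory-failure readout). The ratio is exactly
#' invariant to uniform dilution of either fluid and to any concentration
#' unit applied consistently. The panel must be fully imputed (no missing, no
#' censored-without-value entries).
#'
#' @param panel an imputed `paired_panel` containing creatinine in both fluids
#'   for every subject.
#' @return wide tibble (class `flux_matrix`): `subject_id`, `group` (if
#'   present) and one log10 flux-ratio column per metabolite. Imputation
#'   provenance flags are kept in the `"provenance"` attribute (long tibble).
#' @export
flux_ratio <- function(panel) {
  assert_that(!anyNA(panel$concentration),
              "panel still contains missing values; impute first")
  assert_that(all(panel$concentration > 0),
              "zero or negative concentration encountered")
  has_group <- "group" %in% names(panel)
  creat <- panel |>
    filter(.data$metabolite == "creatinine") |>
    select("subject_id", "fluid", creat = "concentration") |>
    pivot_wider(names_from = "fluid", values_from = "creat",
                names_prefix = "creat_")
  assert_that(all(!is.na(creat$creat_serum)) && all(!is.na(creat$creat_urine)),
              "creatinine must be present in both fluids for every subject")
  wide <- panel |>
    filter(.data$metabolite != "creatinine") |>
    select("subject_id", "metabolite", "fluid", "concentration") |>
    pivot_wider(names_from = "fluid", values_from = "concentration") |>
    left_join(creat, by = "subject_id") |>
    mutate(flux = log10((.data$serum / .data$creat_serum) /
                        (.data$urine / .data$creat_urine)))
  out <- wide |>
    select("subject_id", "metabolite", "flux") |>
    pivot_wider(names_from = "metabolite", values_from = "flux")
  if (has_group) {
    out <- panel |> distinct(.data$subject_id, .data$group) |>
      right_join(out, by = "subject_id")
  }
  prov_cols <- intersect(c("lod_imputed", "knn_imputed"), names(panel))
  if (length(prov_cols)) {
    attr(out, "provenance") <- panel |>
      select(dplyr::all_of(c("subject_id", "metabolite", "fluid", prov_cols)))
  }
  class(out) <- c("flux_matrix", class(out))
  out
}

#' Probabilistic quotient normalisation
#'
#' Classical PQN: each sample's dilution factor is the median of its
#' feature-wise quotients against a reference spectrum (by default the median
#' spectrum of the supplied samples, in practice the pooled-QC median); the
#' sample is divided by its factor.
#'
#' @param mat numeric samples x features matrix (or data frame of numerics).
#' @param reference reference spectrum (strictly positive on used features);
#'   default column medians of `mat`.
#' @return list with `normalized` (matrix) and `dilution_factors`.
#' @export
pqn_normalize <- function(mat, reference = NULL) {
  M <- as.matrix(mat)
  reference <- reference %||% apply(M, 2, median, na.rm = TRUE)
  use <- reference > 0
  assert_that(any(use), "reference must be strictly positive somewhere")
  factors <- apply(M[, use, drop = FALSE], 1, function(x)
    median(x / reference[use], na.rm = TRUE))
  assert_that(all(is.finite(factors) & factors > 0),
              "all-zero or degenerate sample: PQN factor undefined")
  list(normalized = M / factors, dilution_factors = factors)
}

#' Creatinine-adjusted total-useful-signal normalisation
#'
#' Divides each sample by the geometric mean of its total signal across
#' retained features and its urinary creatinine:
#' \eqn{x_i / \sqrt{\mathrm{TUS}_i \cdot \mathrm{creat}_i}}. Both factors
#' scale linearly with urine dilution, so the normalised profile is exactly
#' invariant to uniform dilution of a sample; using their geometric mean
#' hedges the pure total-signal correction against the asymmetric signal
#' shifts severe disease can induce.
#'
#' @param mat numeric samples x features matrix.
#' @param urine_creatinine per-sample urinary creatinine (> 0).
#' @return list with `normalized` and `factors`.
#' @export
tus_normalize <- function(mat, urine_creatinine) {
  M <- as.matrix(mat)
  assert_that(length(urine_creatinine) == nrow(M),
              "one creatinine value per sample required")
  assert_that(all(urine_creatinine > 0), "creatinine must be > 0")
  tus <- rowSums(M, na.rm = TRUE)
  assert_that(all(tus > 0), "zero total signal in at least one sample")
  factors <- sqrt(tus * urine_creatinine)
  list(normalized = M / factors, factors = factors)
}

#' Concordance of feature selection under two normalisations
#'
#' Runs the package's differential-selection rule (VIP > 1 and BH-FDR below
#' the cut, see [differential_select()]) on both normalised matrices and
#' reports the overlap of the selected feature sets.
#'
#' @param matA,matB samples x features matrices over the same feature universe.
#' @param y binary group labels.
#' @param ... passed to [differential_select()].
#' @return list with `jaccard` (|intersection| / |union|), `overlap_a`,
#'   `overlap_b` (per-list overlap fractions) and the two selected sets.
#'   All are `NA` with a warning when neither run selects anything.
#' @export
normalization_concordance <- function(matA, matB, y, ...) {
  assert_that(identical(colnames(matA), colnames(matB)),
              "matrices must share a feature universe")
  selA <- differential_select(matA, y, ...) |> filter(.data$selected) |>
    pull(.data$feature)
  selB <- differential_select(matB, y, ...) |> filter(.data$selected) |>
    pull(.data$feature)
  if (length(selA) == 0 && length(selB) == 0) {
    warn("no features selected under either normalisation: concordance undefined")
    return(list(jaccard = NA_real_, overlap_a = NA_real_, overlap_b = NA_real_,
                selected_a = selA, selected_b = selB))
  }
  inter <- length(intersect(selA, selB))
  list(jaccard = inter / length(union(selA, selB)),
       overlap_a = if (length(selA)) inter / length(selA) else NA_real_,
       overlap_b = if (length(selB)) inter / length(selB) else NA_real_,
       selected_a = selA, selected_b = selB)
}
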