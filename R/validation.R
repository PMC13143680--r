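#' Coefficient of variation of replicate measurements
#'
#' Analytical precision summary: CV% = 100 x sample SD / mean, per feature.
#'
#' @param replicates numeric vector of repeated measurements of one feature,
#'   or a data frame of replicates (one column per feature).
#' @return tibble with columns `feature`, `n`, `mean`, `sd`, `cv_pct`
#'   (`cv_pct` is `NA` with a warning when the mean is 0).
#' @export
precision_stats <- function(replicates) {
  if (is.numeric(replicates)) replicates <- tibble(value = replicates)
  purrr::imap(replicates, function(x, nm) {
    assert_that(length(x) >= 2, "need at least 2 replicates")
    m <- mean(x); s <- sd(x)
    cv <- if (m == 0) {
      warn(paste0("mean of '", nm, "' is 0: CV undefined"))
      NA_real_
    } else 100 * s / m
    tibble(feature = nm, n = length(x), mean = m, sd = s, cv_pct = cv)
  }) |> list_rbind()
}

#' Bland-Altman agreement of paired measurements
#'
#' Mean bias, 95% limits of agreement (bias +/- 1.96 x SD of the paired
#' differences) and the share of differences inside the limits.
#'
#' @param x,y paired measurement vectors (e.g. two technical replicates).
#' @return one-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `pct_within`, `n`.
#' @export
bland_altman <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need at least 3 complete pairs")
  d <- x - y
  bias <- mean(d); s <- sd(d)
  lo <- bias - 1.96 * s; hi <- bias + 1.96 * s
  tibble(bias = bias, loa_low = lo, loa_high = hi, sd_diff = s,
         pct_within = 100 * mean(d >= lo & d <= hi), n = length(d))
}
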