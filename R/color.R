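#' Fit a colour-card correction transform
#'
#' Least-squares affine colour correction: a 3x3 matrix plus offset mapping
#' observed patch RGB to the card's reference RGB, fitted per channel over the
#' patches. At least 4 patches are required (12 unknowns per channel / 4 per
#' channel of the design).
#'
#' @param patches data frame with observed columns `r`, `g`, `b` and reference
#'   columns `ref_r`, `ref_g`, `ref_b` (as returned by [card_colors()]), or
#'   `observed`/`reference` numeric matrices via the two-argument form.
#' @param reference optional n x 3 reference matrix when `patches` is an
#'   observed n x 3 matrix.
#' @return object of class `color_transform`: list with `matrix` (3x3),
#'   `offset` (length 3) and `rmse`.
#' @export
fit_color_correction <- function(patches, reference = NULL) {
  if (is.null(reference)) {
    assert_that(all(c("r", "g", "b", "ref_r", "ref_g", "ref_b") %in%
                      names(patches)),
                "patches must carry r,g,b and ref_r,ref_g,ref_b columns")
    obs <- as.matrix(patches[, c("r", "g", "b")])
    ref <- as.matrix(patches[, c("ref_r", "ref_g", "ref_b")])
  } else {
    obs <- as.matrix(patches); ref <- as.matrix(reference)
  }
  assert_that(nrow(obs) >= 4, "colour correction needs at least 4 patches")
  X <- cbind(1, obs)
  qrX <- qr(X)
  assert_that(qrX$rank == 4L, "patch design is rank deficient")
  B <- qr.coef(qrX, ref)                       # 4 x 3: offset row + matrix
  fit <- X %*% B
  structure(list(matrix = t(B[-1, , drop = FALSE]),
                 offset = as.numeric(B[1, ]),
                 rmse = sqrt(mean((fit - ref)^2))),
            class = "color_transform")
}

#' Apply a colour transform to an image or colour matrix
#'
#' @param x H x W x 3 array in \[0,1\], or an n x 3 colour matrix.
#' @param transform a `color_transform` from [fit_color_correction()].
#' @return same shape as `x`, clipped to \[0,1\].
#' @export
apply_color_transform <- function(x, transform) {
  assert_that(inherits(transform, "color_transform"),
              "transform must be a color_transform")
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    m <- matrix(x, ncol = 3L) %*% t(transform$matrix)
    m <- sweep(m, 2, transform$offset, "+")
    array(clamp(m, 0, 1), d)
  } else {
    m <- as.matrix(x) %*% t(transform$matrix)
    clamp(sweep(m, 2, transform$offset, "+"), 0, 1)
  }
}

#' Extract chromatic features from a urine image series
#'
#' Applies the colour correction, averages the liquid region of the first
#' frame, converts the mean sRGB colour to CIELAB (D65 white point, standard
#' sRGB companding) and derives chroma \eqn{C^* = \sqrt{a^{*2} + b^{*2}}} and
#' the dilution-corrected yellowness
#' \eqn{b^*_{adj} = b^* \times 650 / \mathrm{osmolality}}, which rescales
#' yellowness to a 650 mOsm/kg reference urine concentration.
#'
#' @param series a `urine_series` (or any list with `frames` and `liquid_roi`).
#' @param transform a `color_transform`; use
#'   `fit_color_correction(card_colors(series))`.
#' @param osmolality urine osmolality in mOsm/kg (> 0).
#' @param frame frame index to measure (default 1).
#' @return one-row tibble: `L_star`, `a_star`, `b_star`, `chroma_C`, `b_adj`,
#'   `osmolality_mosm`.
#' @export
extract_chromatic <- function(series, transform, osmolality, frame = 1) {
  assert_that(osmolality > 0, "osmolality must be > 0")
  roi <- series$liquid_roi
  assert_that(length(roi$rows) > 0 && length(roi$cols) > 0,
              "liquid ROI is empty")
  img <- series$frames[[frame]]$img
  img <- apply_color_transform(img, transform)
  mean_rgb <- c(mean(img[roi$rows, roi$cols, 1]),
                mean(img[roi$rows, roi$cols, 2]),
                mean(img[roi$rows, roi$cols, 3]))
  lab <- convertColor(matrix(mean_rgb, 1), from = "sRGB", to = "Lab")
  tibble(L_star = lab[1], a_star = lab[2], b_star = lab[3],
         chroma_C = sqrt(lab[2]^2 + lab[3]^2),
         b_adj = lab[3] * 650 / osmolality,
         osmolality_mosm = osmolality)
}

#' Dilution-corrected yellowness
#'
#' \eqn{b^*_{adj} = b^* \times 650 / \mathrm{osmolality}}; identical to
#' \eqn{b^*} at the 650 mOsm/kg reference osmolality.
#'
#' @param b_star CIELAB b* value(s).
#' @param osmolality urine osmolality in mOsm/kg (> 0).
#' @return numeric vector.
#' @export
b_adjusted <- function(b_star, osmolality) {
  assert_that(all(osmolality > 0), "osmolality must be > 0")
  b_star * 650 / osmolality
}
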