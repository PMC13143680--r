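# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "dkdflux_error")
  invisible(TRUE)
}

# convert a median + quartiles (on the raw scale) to log-normal meanlog/sdlog;
# the IQR is assumed symmetric on the log scale
lnorm_from_quartiles <- function(med, q1, q3) {
  assert_that(all(c(med, q1, q3) > 0) && q1 < q3,
              "median/quartiles must be positive with q1 < q3")
  list(meanlog = log(med), sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

# latent (Gaussian copula) correlation for a Spearman target on any
# continuous marginals: rho_latent = 2 sin(pi * rho_s / 6)
latent_from_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

# binary y as 0/1 numeric, with checks
as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  u <- sort(unique(y))
  assert_that(length(u) == 2L && all(u %in% c(0, 1)),
              "labels must be binary (two classes, coded 0/1)")
  as.numeric(y)
}

# luminance of an H x W x 3 array in [0,1]
luminance <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
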