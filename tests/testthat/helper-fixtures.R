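# shared fixture builders (everything generated in code; no stored data)

# minimal paired panel in the long layout used throughout the flux module
make_panel <- function(subjects, metabolite, fluid, conc,
                       censored = FALSE, lod = 0.01) {
  tibble::tibble(subject_id = subjects, metabolite = metabolite,
                 fluid = fluid, concentration = conc,
                 censored = censored, lod = lod)
}

# panel with creatinine rows for every subject in both fluids
add_creatinine <- function(panel, serum = 80, urine = 8000) {
  ids <- unique(panel$subject_id)
  dplyr::bind_rows(
    panel,
    make_panel(rep(ids, 2), "creatinine",
               rep(c("serum", "urine"), each = length(ids)),
               c(rep(serum, length(ids)), rep(urine, length(ids))),
               censored = FALSE, lod = 1))
}

# identity colour transform (fit on the reference card mapped to itself)
identity_transform <- function() {
  ref <- dkdflux:::card_reference_colors()
  fit_color_correction(ref, ref)
}

# synthetic series with a single uniform-colour "liquid" frame, enough for
# extract_chromatic
solid_series <- function(rgb, n = 20) {
  img <- array(rep(rgb, each = n * n), c(n, n, 3))
  list(frames = list(list(time_s = 0, img = img)),
       liquid_roi = list(rows = 1:n, cols = 1:n),
       foam_roi = list(rows = 1:n, cols = 1:n),
       pixel_scale_mm = 0.1)
}

# two-cluster Gaussian data with a configurable shift on selected features
make_clusters <- function(n_per_class, p, informative = seq_len(p),
                          delta = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c(0, 1), each = n_per_class)
  X[y == 1, informative] <- X[y == 1, informative] + delta
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

# simulate proper Fine-Gray data: subdistribution of the primary event
# F1(t; x) = 1 - (1 - p0 (1 - exp(-t)))^exp(beta x); competing events
# exponential among the remainder (Fine & Gray's construction)
simulate_fine_gray <- function(n, beta, p0 = 0.4, cens_rate = 0.15,
                               seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  eta <- exp(beta * x)
  p_cause1 <- 1 - (1 - p0)^eta
  cause1 <- runif(n) < p_cause1
  u <- runif(n)
  # invert the conditional subdistribution for cause-1 times
  t1 <- -log(1 - (1 - (1 - u * p_cause1)^(1 / eta)) / p0)
  t2 <- rexp(n, 1)
  time <- ifelse(cause1, t1, t2)
  cens <- rexp(n, cens_rate)
  tibble::tibble(
    x = x,
    time_years = pmin(time, cens),
    event_type = dplyr::case_when(
      cens < time ~ "censored",
      cause1 ~ "primary",
      TRUE ~ "competing_death"))
}
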