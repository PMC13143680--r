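test_that("missingness filter applies the strict >20% rule per fluid", {
  ids <- sprintf("S%03d", 1:100)
  conc_a <- c(rep(NA_real_, 21), runif(79, 1, 2))   # 21% missing in serum
  conc_b <- c(rep(NA_real_, 20), runif(80, 1, 2))   # exactly 20%
  pan <- dplyr::bind_rows(
    make_panel(ids, "met_a", "serum", conc_a),
    make_panel(ids, "met_a", "urine", runif(100, 1, 2)),
    make_panel(ids, "met_b", "serum", conc_b),
    make_panel(ids, "met_b", "urine", runif(100, 1, 2))) |>
    add_creatinine()
  out <- suppressMessages(filter_missingness(pan))
  expect_identical(attr(out, "dropped_metabolites"), "met_a")
  expect_false("met_a" %in% out$metabolite)
  expect_true("met_b" %in% out$metabolite)   # boundary retained

  clean <- make_panel(ids, "met_c", "serum", runif(100)) |> add_creatinine()
  expect_identical(filter_missingness(clean)$concentration,
                   clean$concentration)
})

test_that("KNN imputation uses nearest-neighbour means deterministically", {
  # S1 is identical to S2 on the complete feature; k = 1 copies S2's value
  pan <- dplyr::bind_rows(
    make_panel(c("S1", "S2", "S3"), "met_a", "serum", c(10, 10, 1000)),
    make_panel(c("S1", "S2", "S3"), "met_b", "serum", c(NA, 7, 9)))
  out <- knn_impute(pan, k = 1)
  expect_equal(out$concentration[out$metabolite == "met_b" &
                                   out$subject_id == "S1"], 7)
  expect_true(out$knn_imputed[out$metabolite == "met_b" &
                                out$subject_id == "S1"])

  # two equidistant neighbours (symmetric on the log scale) average to 5
  pan2 <- dplyr::bind_rows(
    make_panel(c("S1", "S2", "S3"), "met_a", "serum", c(10, 5, 20)),
    make_panel(c("S1", "S2", "S3"), "met_b", "serum", c(NA, 4, 6)))
  out2 <- knn_impute(pan2, k = 2)
  expect_equal(out2$concentration[out2$metabolite == "met_b" &
                                    out2$subject_id == "S1"], 5)

  # no missing entries: identity
  pan3 <- make_panel(c("S1", "S2"), "met_a", "serum", c(1, 2))
  expect_equal(knn_impute(pan3)$concentration, c(1, 2))
})

test_that("LOD/2 imputation is exact and flagged", {
  pan <- make_panel(c("S1", "S2"), "indoxyl_sulfate", "serum",
                    c(NA, 0.5), censored = c(TRUE, FALSE), lod = 0.0152)
  out <- impute_lod(pan)
  expect_equal(out$concentration, c(0.0076, 0.5))
  expect_identical(out$lod_imputed, c(TRUE, FALSE))

  # whole column censored: constant LOD/2, all flagged
  pan2 <- make_panel(c("S1", "S2", "S3"), "met", "urine", rep(NA_real_, 3),
                     censored = TRUE, lod = 0.4)
  out2 <- impute_lod(pan2)
  expect_true(all(out2$concentration == 0.2))
  expect_true(all(out2$lod_imputed))

  pan3 <- make_panel("S1", "met", "urine", NA_real_, censored = TRUE,
                     lod = NA_real_)
  expect_error(impute_lod(pan3), "LOD")
})

test_that("flux ratio evaluates its defining equation and invariances", {
  # metabolite tracking creatinine exactly in both fluids: ratio 0
  pan0 <- make_panel(rep("S1", 2), "met", c("serum", "urine"), c(80, 8000)) |>
    add_creatinine(serum = 80, urine = 8000)
  expect_equal(flux_ratio(pan0)$met, 0)

  # worked example: log10((100/80)/(50/8000)) = log10(200)
  pan <- make_panel(rep("S1", 2), "indoxyl_sulfate", c("serum", "urine"),
                    c(100, 50)) |>
    add_creatinine(serum = 80, urine = 8000)
  fx <- flux_ratio(pan)
  expect_equal(fx$indoxyl_sulfate, log10(200))
  expect_equal(fx$indoxyl_sulfate, 2.301, tolerance = 1e-3)

  # uniform dilution of either fluid leaves the ratio exactly unchanged
  dilute <- function(p, fl, k) {
    p$concentration[p$fluid == fl] <- p$concentration[p$fluid == fl] * k
    p
  }
  expect_identical(flux_ratio(dilute(pan, "urine", 13.7))$indoxyl_sulfate,
                   fx$indoxyl_sulfate)
  expect_identical(flux_ratio(dilute(pan, "serum", 0.02))$indoxyl_sulfate,
                   fx$indoxyl_sulfate)
  # consistent unit change across all four concentrations
  pan_nmol <- pan; pan_nmol$concentration <- pan$concentration * 1000
  expect_equal(flux_ratio(pan_nmol)$indoxyl_sulfate, fx$indoxyl_sulfate)

  expect_error(flux_ratio(make_panel("S1", "met", "serum", NA_real_)),
               "missing")
})

test_that("the imputation pipeline is idempotent on its own output", {
  coh <- generate_cohort(cohort_config(n_per_group = c(hc = 8, t2dm = 8,
                                                       dkd = 8)))
  pan <- generate_metabolite_panel(coh)
  once <- impute_lod(knn_impute(suppressMessages(filter_missingness(pan))))
  twice <- impute_lod(knn_impute(suppressMessages(filter_missingness(once))))
  expect_equal(twice$concentration, once$concentration)
  expect_equal(flux_ratio(twice)[, -1], flux_ratio(once)[, -1],
               ignore_attr = TRUE)
})

test_that("PQN factors are medians of quotients", {
  ref <- c(1, 2, 4)
  M <- rbind(s1 = 2 * ref, s2 = ref, s3 = c(2 * ref[1], 2 * ref[2], 8 * ref[3]))
  out <- pqn_normalize(M, reference = ref)
  expect_equal(unname(out$dilution_factors), c(2, 1, 2))
  expect_equal(unname(out$normalized["s1", ]), ref)
  expect_equal(unname(out$normalized["s3", ]), c(ref[1], ref[2], 4 * ref[3]))

  # property: a sample equal to c x reference has factor exactly c
  set.seed(1)
  ref2 <- runif(30, 0.5, 5)
  for (cc in c(0.25, 1, 3.7)) {
    expect_equal(unname(pqn_normalize(rbind(cc * ref2, ref2),
                                      reference = ref2)$dilution_factors[1]),
                 cc)
  }
  expect_error(pqn_normalize(rbind(c(0, 0), c(1, 1)), reference = c(1, 1)),
               "degenerate|zero")
})

test_that("TUS normalisation is dilution invariant", {
  M <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 1, 1))
  creat <- c(10, 20, 8)
  out <- tus_normalize(M, creat)
  # hand-computed: row / sqrt(rowSum * creatinine)
  expect_equal(out$normalized["a", ], M["a", ] / sqrt(6 * 10))
  # proportional sample with proportionally scaled creatinine: identical output
  expect_equal(unname(out$normalized["a", ]), unname(out$normalized["b", ]))
  # uniform dilution of one sample (features and creatinine): exact invariance
  k <- 4.2
  M2 <- M; M2["c", ] <- M["c", ] * k
  creat2 <- creat; creat2[3] <- creat[3] * k
  out2 <- tus_normalize(M2, creat2)
  expect_equal(out2$normalized["c", ], out$normalized["c", ])
  expect_error(tus_normalize(M, c(1, -1, 1)), "creatinine")
})

test_that("normalisation concordance reflects selection overlap", {
  cl <- make_clusters(30, 12, informative = 1:6, delta = 4, seed = 2)
  same <- normalization_concordance(cl$X, cl$X, cl$y)
  expect_equal(same$jaccard, 1)

  # disjoint constructed selections: matrix A separates f1, B separates f2
  set.seed(3)
  n <- 60; y <- rep(0:1, each = 30)
  base <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  A <- base; A[y == 1, 1] <- A[y == 1, 1] + 6
  B <- base; B[y == 1, 2] <- B[y == 1, 2] + 6
  dis <- normalization_concordance(A, B, y)
  expect_equal(dis$jaccard, 0)

  # strong injected effects: PQN and TUS select nearly the same features
  set.seed(4)
  n2 <- 50
  conc <- exp(matrix(rnorm(2 * n2 * 20, 2, 0.3), 2 * n2, 20))
  colnames(conc) <- paste0("m", 1:20)
  y2 <- rep(0:1, each = n2)
  conc[y2 == 1, 1:8] <- conc[y2 == 1, 1:8] * 3
  dil <- exp(rnorm(2 * n2, 0, 0.5))          # per-sample dilution
  obs <- conc * dil
  creat <- 100 * dil * exp(rnorm(2 * n2, 0, 0.1))
  pq <- pqn_normalize(obs)$normalized
  tu <- tus_normalize(obs, creat)$normalized
  conc_chk <- normalization_concordance(pq, tu, y2)
  expect_gt(conc_chk$jaccard, 0.9)
})
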