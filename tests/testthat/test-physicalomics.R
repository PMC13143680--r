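test_that("colour correction recovers applied casts and validates inputs", {
  ref <- dkdflux:::card_reference_colors()
  # observed == reference: identity transform, zero residual
  tf <- fit_color_correction(ref, ref)
  expect_equal(tf$matrix, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tf$offset, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(tf$rmse, 0, tolerance = 1e-10)

  # channel scaling by (0.9, 1.1, 1.0): recovered inverse diagonal, and
  # applying the transform restores the reference exactly
  cast <- diag(c(0.9, 1.1, 1.0))
  obs <- ref %*% t(cast)
  tf2 <- fit_color_correction(obs, ref)
  expect_equal(diag(tf2$matrix), 1 / c(0.9, 1.1, 1.0), tolerance = 1e-6)
  expect_equal(apply_color_transform(obs, tf2), ref, tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(fit_color_correction(ref[1:3, ], ref[1:3, ]), "4 patches")
})

test_that("chromatic extraction reproduces reference CIELAB values", {
  tf <- identity_transform()
  w <- extract_chromatic(solid_series(c(1, 1, 1)), tf, osmolality = 650)
  expect_equal(w$L_star, 100, tolerance = 1e-4)
  expect_equal(w$a_star, 0, tolerance = 1e-4)
  expect_equal(w$b_star, 0, tolerance = 1e-4)
  expect_equal(w$chroma_C, 0, tolerance = 1e-4)
  # pure sRGB yellow: b* ~ 94.5 against reference conversion tables
  y <- extract_chromatic(solid_series(c(1, 1, 0)), tf, osmolality = 650)
  expect_equal(y$b_star, 94.5, tolerance = 0.005)
  expect_error(extract_chromatic(solid_series(c(1, 1, 0)), tf, osmolality = 0),
               "osmolality")
})

test_that("dilution-corrected yellowness follows the osmolality rescaling", {
  expect_equal(b_adjusted(24.6, 420.3), 24.6 * 650 / 420.3)
  expect_equal(b_adjusted(24.6, 420.3), 38.04, tolerance = 1e-3)
  expect_identical(b_adjusted(24.6, 650), 24.6)
  osm <- seq(300, 900, by = 50)
  expect_true(all(diff(b_adjusted(10, osm)) < 0))
})

test_that("chromaticity is invariant to invertible casts after correction", {
  set.seed(5)
  for (i in 1:4) {
    cast <- diag(runif(3, 0.85, 1.15)) + matrix(runif(9, 0, 0.04), 3)
    sp <- image_spec(lab_color = c(60, 8, 30), cast = cast,
                     frame_times_s = c(0, 30), seed = i)
    ser <- render_urine_series(sp)
    tf <- fit_color_correction(card_colors(ser))
    expect_lt(tf$rmse, 1 / 255)
    feats <- extract_chromatic(ser, tf, osmolality = 500)
    expect_lt(abs(feats$b_star - 30), 1)
  }
})

test_that("foam segmentation matches the rendered ground truth", {
  sp <- image_spec(frame_times_s = c(0, 30, 60, 120), seed = 2)
  ser <- render_urine_series(sp)
  tf <- fit_color_correction(card_colors(ser))
  for (i in c(1, 2)) {
    img <- apply_color_transform(ser$frames[[i]]$img, tf)
    m <- segment_foam(img, ser$foam_roi)
    gt <- sum(ser$foam_masks[[i]])
    expect_lt(abs(sum(m) - gt) / gt, 0.05)
  }
  # no foam band: empty mask
  blank <- array(0.35, c(40, 40, 3))
  roi <- list(rows = 1:40, cols = 1:40)
  expect_equal(sum(segment_foam(blank, roi)), 0)
  # full-ROI foam: mask covers at least 95% of the ROI
  full <- array(0.9, c(40, 40, 3))
  expect_gte(sum(segment_foam(full, roi)) / (40 * 40), 0.95)
  expect_error(segment_foam(blank, list(rows = 1:80, cols = 1:40)), "bounds")
})

test_that("foam heights follow the generative decay law", {
  # 30-pixel band at 0.1 mm/px reads 3.0 mm
  m <- matrix(FALSE, 100, 50); m[41:70, 10:40] <- TRUE
  expect_equal(dkdflux:::mask_height_mm(m, 0.1), 3.0)
  expect_equal(dkdflux:::mask_height_mm(matrix(FALSE, 10, 10), 0.1), 0)

  sp <- image_spec(foam_half_life_s = 30, initial_foam_height_mm = 10,
                   frame_times_s = c(0, 30, 60, 120), noise_sd = 0, seed = 3)
  ser <- render_urine_series(sp)
  traj <- foam_height_trajectory(ser)
  expect_equal(traj$height_mm, c(10, 5, 2.5, 0.625),
               tolerance = ser$pixel_scale_mm * 1.01)
})

test_that("half-life estimation is exact on noiseless decays", {
  fit <- estimate_half_life(c(10, 5, 2.5, 0.625), c(0, 30, 60, 120))
  expect_equal(fit$t_half_s, 30, tolerance = 1e-9)
  expect_false(fit$censored)

  th <- 45.8
  t <- c(0, 30, 60, 120)
  fit2 <- estimate_half_life(10 * 2^(-t / th), t)
  expect_lt(abs(fit2$t_half_s - th) / th, 0.01)

  fit3 <- estimate_half_life(c(10, 10, 10, 10), c(0, 30, 60, 120))
  expect_true(fit3$censored)
  expect_gt(fit3$t_half_s, 120)

  expect_error(estimate_half_life(c(0, 1, 2), c(0, 30, 60)), "t = 0")
})

test_that("half-life is recovered from rendered series across group values", {
  # short half-lives need early frames for identifiability
  times <- c(0, 5, 15, 30, 60, 120)
  for (th in c(4.2, 45.8)) {
    sp <- image_spec(foam_half_life_s = th, frame_times_s = times, seed = 17)
    ser <- render_urine_series(sp)
    # for fast decays the foam is gone by t = 30 s and the MBI is undefined
    feats <- suppressWarnings(extract_physicalomics(ser, osmolality = 500))
    expect_lt(abs(feats$t_half_s - th) / th, 0.10)
  }
})

test_that("micro-bubble index equals the analytic area ratio", {
  scale <- 0.1
  # constructed mask: 100 mm2 of foam, ~20 mm2 of micro-bubbles
  H <- 100; W <- 100
  foam <- matrix(TRUE, H, W)                       # 10000 px = 100 mm2
  bub <- matrix(FALSE, H, W)
  centers <- expand.grid(r = seq(4, 97, by = 7), c = seq(4, 97, by = 7))
  r_px <- 2                                         # d = 0.4 mm: micro
  n_disks <- 159                                    # ~159 * 12.6 px ~ 2000 px
  for (k in seq_len(n_disks)) {
    bub <- dkdflux:::draw_disk(bub, centers$r[k], centers$c[k], r_px)
  }
  frame <- array(0.62, c(H, W, 3))
  for (ch in 1:3) { pl <- frame[, , ch]; pl[bub] <- 0.95; frame[, , ch] <- pl }
  res <- micro_bubble_index(frame, foam, scale)
  analytic <- 100 * sum(bub) * scale^2 / (sum(foam) * scale^2)
  expect_lt(abs(res$mbi_pct - analytic), 1)
  expect_equal(analytic, 20, tolerance = 2)
  expect_true(all(res$bubble_table$micro))

  # all bubbles at or above the 0.5 mm cutoff: MBI = 0
  bub2 <- matrix(FALSE, H, W)
  for (rr in c(20, 50, 80)) bub2 <- dkdflux:::draw_disk(bub2, rr, 50, 5)
  frame2 <- array(0.62, c(H, W, 3))
  for (ch in 1:3) { pl <- frame2[, , ch]; pl[bub2] <- 0.95; frame2[, , ch] <- pl }
  expect_equal(micro_bubble_index(frame2, foam, scale)$mbi_pct, 0)

  # foam consisting solely of micro-bubbles, no interstitial pixels: 100%
  res3 <- micro_bubble_index(frame, bub, scale)
  expect_equal(res3$mbi_pct, 100, tolerance = 1e-9)

  # empty mask: undefined, signalled distinctly from 0
  expect_warning(res4 <- micro_bubble_index(frame, matrix(FALSE, H, W), scale),
                 "undefined")
  expect_true(is.na(res4$mbi_pct))
})

test_that("precision statistics follow the CV definition", {
  expect_equal(precision_stats(c(5, 5, 5))$cv_pct, 0)
  expect_equal(precision_stats(c(9, 10, 11))$cv_pct, 10.0)
  expect_warning(out <- precision_stats(c(0, 0, 0)), "undefined")
  expect_true(is.na(out$cv_pct))
  expect_error(precision_stats(c(1)), "2 replicates")
})

test_that("Bland-Altman agreement matches hand arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  x <- c(2, 1, 2, 1); y <- c(1, 2, 1, 2)   # diffs (1, -1, 1, -1)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sd(c(1, -1, 1, -1)), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2.263, tolerance = 1e-3)

  # paired replicates generated with a +0.15 bias are recovered within CI
  set.seed(8)
  a <- rnorm(50, 10, 1); b <- a - 0.15 + rnorm(50, 0, 0.1)
  bar <- bland_altman(a, b)
  ci <- 1.96 * bar$sd_diff / sqrt(bar$n)
  expect_lt(abs(bar$bias - 0.15), ci)
  expect_gte(bar$pct_within, 90)
})
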