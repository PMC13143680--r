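#' Specification for a rendered urine image series
#'
#' Describes one synthetic sample imaged in a cuvette: the true liquid colour
#' in CIELAB, the foam decay parameters, the bubble-size mixture, the frame
#' times, the pixel scale, and a 3x3 colour cast that simulates non-reference
#' lighting. The rendered frames contain (top to bottom) a 12-patch colour
#' reference card, a foam band whose height follows
#' \eqn{h(t) = h_0 2^{-t/T_{1/2}}} with bubbles drawn as disks, and the liquid
#' column.
#'
#' Bubble diameters are drawn from a two-component log-normal mixture
#' (micro-bubbles < 0.5 mm vs macro-bubbles); `micro_weight` shifts mass to
#' the micro component, which is what raises the micro-bubble index in
#' disease. An explicit `bubble_diameters_mm` vector overrides the mixture.
#'
#' @param lab_color true liquid colour, c(L*, a*, b*).
#' @param foam_half_life_s foam half-life in seconds (> 0).
#' @param initial_foam_height_mm foam height at t = 0 (mm).
#' @param frame_times_s strictly increasing capture times starting at 0.
#' @param pixel_scale_mm physical size of one pixel (mm).
#' @param cast 3x3 colour matrix applied to every rendered pixel.
#' @param n_bubbles expected bubble count in the t = 0 band.
#' @param micro_weight mixture weight of the micro-bubble component.
#' @param bubble_diameters_mm optional explicit diameters to sample from.
#' @param width_px,height_px frame size in pixels.
#' @param noise_sd additive Gaussian pixel noise.
#' @param seed integer seed.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(lab_color = c(65, 5, 35),
                       foam_half_life_s = 45.8,
                       initial_foam_height_mm = 10,
                       frame_times_s = c(0, 30, 60, 120),
                       pixel_scale_mm = 0.1,
                       cast = diag(3),
                       n_bubbles = 140,
                       micro_weight = 0.5,
                       bubble_diameters_mm = NULL,
                       width_px = 200, height_px = 240,
                       noise_sd = 0.006,
                       seed = 1L) {
  assert_that(foam_half_life_s > 0, "foam_half_life_s must be > 0")
  assert_that(pixel_scale_mm > 0, "pixel_scale_mm must be > 0")
  assert_that(initial_foam_height_mm > 0, "initial foam height must be > 0")
  assert_that(frame_times_s[1] == 0 && all(diff(frame_times_s) > 0),
              "frame times must strictly increase starting at 0")
  assert_that(is.matrix(cast) && all(dim(cast) == c(3, 3)),
              "cast must be a 3x3 matrix")
  structure(list(lab_color = lab_color, foam_half_life_s = foam_half_life_s,
                 initial_foam_height_mm = initial_foam_height_mm,
                 frame_times_s = frame_times_s, pixel_scale_mm = pixel_scale_mm,
                 cast = cast, n_bubbles = n_bubbles,
                 micro_weight = micro_weight,
                 bubble_diameters_mm = bubble_diameters_mm,
                 width_px = width_px, height_px = height_px,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_spec")
}

# 12 sRGB reference patches (rows: patches, cols: R,G,B in [0,1])
card_reference_colors <- function() {
  m <- rbind(
    c(0.45, 0.32, 0.26), c(0.77, 0.57, 0.50), c(0.36, 0.48, 0.61),
    c(0.34, 0.42, 0.26), c(0.51, 0.50, 0.69), c(0.39, 0.74, 0.66),
    c(0.85, 0.48, 0.18), c(0.28, 0.36, 0.65), c(0.76, 0.33, 0.38),
    c(0.36, 0.24, 0.42), c(0.62, 0.73, 0.25), c(0.90, 0.63, 0.18))
  colnames(m) <- c("r", "g", "b")
  m
}

# sample bubble diameters (mm) from the two-component log-normal mixture
sample_bubble_diameters <- function(n, spec) {
  if (!is.null(spec$bubble_diameters_mm)) {
    return(sample(spec$bubble_diameters_mm, n, replace = TRUE))
  }
  micro <- runif(n) < spec$micro_weight
  d <- ifelse(micro,
              rlnorm(n, log(0.32), 0.18),   # micro: ~0.22-0.45 mm
              rlnorm(n, log(1.00), 0.25))   # macro: ~0.6-1.7 mm
  clamp(d, 0.2, 2.5)
}

# rasterise a filled disk onto a logical mask; continuous centre coordinates
draw_disk <- function(mask, cy, cx, r_px) {
  H <- nrow(mask); W <- ncol(mask)
  rows <- max(1, floor(cy - r_px)):min(H, ceiling(cy + r_px))
  cols <- max(1, floor(cx - r_px)):min(W, ceiling(cx + r_px))
  dm <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r_px^2
  mask[rows, cols] <- mask[rows, cols] | dm
  mask
}

apply_cast <- function(img, cast) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L) %*% t(cast)
  array(clamp(m, 0, 1), d)
}

#' Render a synthetic urine image series with ground truth
#'
#' Produces one 8-bit-equivalent RGB frame (numeric array in \[0,1\]) per
#' frame time, plus ground-truth foam-band masks, bubble masks and per-bubble
#' tables. The colour card renders at the cast-distorted reference colours,
#' the liquid column at the cast-distorted CIELAB colour, and the foam band
#' follows the exponential decay law. Bubbles are non-overlapping disks whose
#' diameters come from the configured mixture.
#'
#' @param spec an [image_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return object of class `urine_series`: list with `frames` (each a list
#'   `time_s`, `img`), `foam_masks`, `bubble_masks`, `bubble_tables`, `card`
#'   (patch regions and reference colours), `liquid_roi`, `foam_roi`,
#'   `pixel_scale_mm`, `spec`.
#' @export
render_urine_series <- function(spec = image_spec(), seed = NULL) {
  assert_that(inherits(spec, "image_spec"), "spec must be an image_spec")
  set.seed(seed %||% spec$seed)
  H <- spec$height_px; W <- spec$width_px
  scale <- spec$pixel_scale_mm

  # geometry: card strip on top, cuvette (foam above liquid) below
  card_rows <- 6:48
  cuv_cols <- 40:(W - 40)
  liquid_top <- H - 50
  foam_roi <- list(rows = 56:(liquid_top - 1), cols = cuv_cols)
  liquid_roi <- list(rows = liquid_top:(H - 10), cols = cuv_cols)

  h0_px <- spec$initial_foam_height_mm / scale
  assert_that(h0_px <= length(foam_roi$rows),
              "initial foam height exceeds the frame's foam region")

  # card patch regions: 2 rows x 6 patches
  ref <- card_reference_colors()
  regions <- list()
  pw <- 24; ph <- 18; gap <- 4
  for (i in 0:1) for (j in 0:5) {
    k <- i * 6 + j + 1
    regions[[k]] <- list(rows = (8 + i * (ph + gap)) + 0:(ph - 1),
                         cols = (28 + j * (pw + gap)) + 0:(pw - 1))
  }

  base <- array(0.35, c(H, W, 3))
  for (k in seq_len(nrow(ref))) {
    rg <- regions[[k]]
    for (ch in 1:3) base[rg$rows, rg$cols, ch] <- ref[k, ch]
  }
  # cuvette walls
  base[56:(H - 10), c(min(cuv_cols) - 2, max(cuv_cols) + 2), ] <- 0.12
  liquid_rgb <- convertColor(matrix(spec$lab_color, 1), from = "Lab",
                             to = "sRGB", clip = TRUE)
  for (ch in 1:3) base[liquid_roi$rows, liquid_roi$cols, ch] <- liquid_rgb[ch]

  frames <- list(); foam_masks <- list(); bubble_masks <- list()
  bubble_tables <- list()
  for (fi in seq_along(spec$frame_times_s)) {
    t <- spec$frame_times_s[fi]
    img <- base
    h_px <- round(h0_px * 2^(-t / spec$foam_half_life_s))
    foam_mask <- matrix(FALSE, H, W)
    bubble_mask <- matrix(FALSE, H, W)
    btab <- tibble(bubble = integer(), row = numeric(), col = numeric(),
                   d_mm = numeric(), area_mm2 = numeric(), micro = logical())
    if (h_px >= 1) {
      band_rows <- (liquid_top - h_px):(liquid_top - 1)
      foam_mask[band_rows, cuv_cols] <- TRUE
      for (ch in 1:3) img[band_rows, cuv_cols, ch] <- 0.62
      # bubbles, count proportional to current band height
      nb <- round(spec$n_bubbles * h_px / h0_px)
      if (nb > 0) {
        d_mm <- sample_bubble_diameters(nb, spec)
        cys <- numeric(0); cxs <- numeric(0); rs <- numeric(0)
        keep <- integer(0)
        for (b in seq_len(nb)) {
          r_px <- d_mm[b] / 2 / scale
          if (2 * r_px + 2 >= h_px) next   # bubble taller than current band
          ok <- FALSE
          for (try in 1:40) {
            cy <- runif(1, min(band_rows) + r_px, max(band_rows) - r_px)
            cx <- runif(1, min(cuv_cols) + r_px, max(cuv_cols) - r_px)
            if (length(cys) == 0L ||
                all(sqrt((cys - cy)^2 + (cxs - cx)^2) - (rs + r_px) > 1)) {
              ok <- TRUE; break
            }
          }
          if (!ok) next
          cys <- c(cys, cy); cxs <- c(cxs, cx); rs <- c(rs, r_px)
          keep <- c(keep, b)
          bubble_mask <- draw_disk(bubble_mask, cy, cx, r_px)
        }
        if (length(keep)) {
          dk <- d_mm[keep]
          btab <- tibble(bubble = seq_along(keep), row = cys, col = cxs,
                         d_mm = dk, area_mm2 = pi * (dk / 2)^2,
                         micro = dk < 0.5)
        }
        for (ch in 1:3) {
          pl <- img[, , ch]; pl[bubble_mask] <- 0.95; img[, , ch] <- pl
        }
      }
    }
    if (spec$noise_sd > 0) {
      img <- clamp(img + array(rnorm(length(img), 0, spec$noise_sd), dim(img)),
                   0, 1)
    }
    img <- apply_cast(img, spec$cast)
    frames[[fi]] <- list(time_s = t, img = img)
    foam_masks[[fi]] <- foam_mask
    bubble_masks[[fi]] <- bubble_mask
    bubble_tables[[fi]] <- btab
  }
  structure(list(frames = frames, foam_masks = foam_masks,
                 bubble_masks = bubble_masks, bubble_tables = bubble_tables,
                 card = list(regions = regions, reference = ref),
                 liquid_roi = liquid_roi, foam_roi = foam_roi,
                 pixel_scale_mm = scale, spec = spec),
            class = "urine_series")
}

#' Observed colour-card patch colours of one frame
#'
#' Mean RGB of every card patch region in the (possibly cast-distorted)
#' rendered frame, alongside the reference colours; the input to
#' [fit_color_correction()].
#'
#' @param series a `urine_series`.
#' @param frame frame index (default 1).
#' @return tibble with columns `patch`, `r`, `g`, `b` (observed) and
#'   `ref_r`, `ref_g`, `ref_b`.
#' @export
card_colors <- function(series, frame = 1) {
  img <- series$frames[[frame]]$img
  purrr::imap(series$card$regions, function(rg, k) {
    tibble(patch = k,
           r = mean(img[rg$rows, rg$cols, 1]),
           g = mean(img[rg$rows, rg$cols, 2]),
           b = mean(img[rg$rows, rg$cols, 3]),
           ref_r = unname(series$card$reference[k, 1]),
           ref_g = unname(series$card$reference[k, 2]),
           ref_b = unname(series$card$reference[k, 3]))
  }) |> list_rbind()
}
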