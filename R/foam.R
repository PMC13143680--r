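#' Segment the foam band in one frame
#'
#' Intensity thresholding of the luminance inside the foam region of interest,
#' followed by morphological opening and closing to remove speckle. Foam (a
#' bright bubble raft) is well separated in luminance from the dark enclosure
#' background; frames should be colour-corrected first if a strong cast was
#' applied at capture.
#'
#' @param frame H x W x 3 numeric array in \[0,1\].
#' @param foam_roi list with integer `rows` and `cols` delimiting the region
#'   above the liquid.
#' @param threshold luminance cut separating foam from background.
#' @param brush_size diameter (px) of the disc brush used for cleanup.
#' @return logical H x W matrix; `TRUE` for foam pixels, confined to the ROI.
#' @export
segment_foam <- function(frame, foam_roi, threshold = 0.5, brush_size = 3) {
  d <- dim(frame)
  assert_that(max(foam_roi$rows) <= d[1] && max(foam_roi$cols) <= d[2],
              "foam ROI exceeds frame bounds")
  lum <- luminance(frame)
  mask <- matrix(FALSE, d[1], d[2])
  sub <- lum[foam_roi$rows, foam_roi$cols] > threshold
  if (any(sub)) {
    kern <- EBImage::makeBrush(brush_size, shape = "disc")
    sub <- EBImage::closing(EBImage::opening(sub * 1, kern), kern) > 0.5
  }
  mask[foam_roi$rows, foam_roi$cols] <- sub
  mask
}

# per-mask physical height: column-wise vertical extent, median over columns
mask_height_mm <- function(mask, pixel_scale_mm) {
  cols_any <- which(colSums(mask) > 0)
  if (length(cols_any) == 0L) return(0)
  ext <- purrr::map_dbl(cols_any, function(j) {
    r <- which(mask[, j])
    max(r) - min(r) + 1
  })
  median(ext) * pixel_scale_mm
}

#' Foam height trajectory of an image series
#'
#' Segments the foam band in every frame and measures its physical height:
#' the difference between the top-most and bottom-most foam rows per column,
#' summarised by the column-wise median (robust to speckle) and scaled by the
#' pixel size.
#'
#' @param series a `urine_series`.
#' @param transform optional `color_transform` applied before segmentation.
#' @param masks optional list of pre-computed foam masks (one per frame).
#' @param threshold passed to [segment_foam()].
#' @return tibble with columns `time_s`, `height_mm`.
#' @export
foam_height_trajectory <- function(series, transform = NULL, masks = NULL,
                                   threshold = 0.5) {
  assert_that(length(series$frames) >= 2, "need at least 2 frames")
  purrr::map(seq_along(series$frames), function(i) {
    fr <- series$frames[[i]]
    m <- if (!is.null(masks)) masks[[i]] else {
      img <- fr$img
      if (!is.null(transform)) img <- apply_color_transform(img, transform)
      segment_foam(img, series$foam_roi, threshold = threshold)
    }
    tibble(time_s = fr$time_s,
           height_mm = mask_height_mm(m, series$pixel_scale_mm))
  }) |> list_rbind()
}

#' Estimate the foam half-life
#'
#' Fits the exponential decay law \eqn{h(t) = h_0 2^{-t/T_{1/2}}} by least
#' squares on \eqn{\log_2 h} over frames with positive height, and returns the
#' half-life \eqn{T_{1/2}} in seconds. If the observed height never falls
#' below half the initial height within the window and the fitted half-life
#' exceeds the last frame time, the estimate is flagged right-censored
#' (reported as a lower bound, possibly `Inf` for non-decaying foam).
#'
#' @param heights numeric heights in mm (or the tibble returned by
#'   [foam_height_trajectory()]).
#' @param times frame times in seconds (ignored when `heights` is a tibble).
#' @return one-row tibble: `t_half_s`, `censored`, `h0_mm`, `n_used`.
#' @export
estimate_half_life <- function(heights, times = NULL) {
  if (is.data.frame(heights)) {
    times <- heights$time_s; heights <- heights$height_mm
  }
  assert_that(length(heights) == length(times) && length(heights) >= 2,
              "heights and times must match, with >= 2 frames")
  assert_that(heights[1] > 0, "height at t = 0 must be > 0")
  pos <- heights > 0
  h0 <- heights[1]
  last_t <- max(times)
  if (sum(pos) < 2) {
    # decayed below resolution after the first frame: bound from the first gap
    t1 <- min(times[times > 0])
    return(tibble(t_half_s = t1 / 2, censored = FALSE, h0_mm = h0,
                  n_used = sum(pos)))
  }
  fit <- lm(log2(heights[pos]) ~ times[pos])
  slope <- coef(fit)[2]
  t_half <- if (slope < 0) -1 / slope else Inf
  censored <- min(heights) > h0 / 2 && t_half > last_t
  tibble(t_half_s = unname(t_half), censored = censored, h0_mm = h0,
         n_used = sum(pos))
}

#' Micro-bubble index at t = 30 s
#'
#' Segments individual bubbles inside the foam mask (luminance threshold for
#' the bright bubble caps, distance-map watershed to split touching bubbles,
#' connected-component labelling), computes the equivalent-circle diameter
#' \eqn{d = 2\sqrt{A/\pi}} of each bubble, and returns the micro-bubble index:
#' the percentage of the total foam-mask area occupied by bubbles with
#' d < 0.5 mm. Interstitial foam pixels count in the denominator.
#'
#' @param frame H x W x 3 array (the t = 30 s frame, colour-corrected).
#' @param foam_mask logical foam mask for the same frame.
#' @param pixel_scale_mm mm per pixel.
#' @param bubble_threshold luminance cut separating bubble caps from the foam
#'   matrix.
#' @return list with `mbi_pct` (NA with a warning when the foam mask is
#'   empty) and `bubble_table` (tibble: `bubble`, `area_mm2`, `d_mm`, `micro`).
#' @export
micro_bubble_index <- function(frame, foam_mask, pixel_scale_mm,
                               bubble_threshold = 0.8) {
  empty <- tibble(bubble = integer(), area_mm2 = numeric(),
                  d_mm = numeric(), micro = logical())
  if (!any(foam_mask)) {
    warn("empty foam mask: micro-bubble index undefined")
    return(list(mbi_pct = NA_real_, bubble_table = empty))
  }
  lum <- luminance(frame)
  cand <- foam_mask & (lum > bubble_threshold)
  if (!any(cand)) {
    return(list(mbi_pct = 0, bubble_table = empty))
  }
  # split touching bubbles along the distance-map ridge, then label
  dmap <- EBImage::distmap(cand * 1)
  lab <- EBImage::watershed(dmap, tolerance = 0.5)
  areas_px <- tabulate(lab[lab > 0])
  areas_px <- areas_px[areas_px > 0]
  area_mm2 <- areas_px * pixel_scale_mm^2
  d_mm <- 2 * sqrt(area_mm2 / pi)
  tab <- tibble(bubble = seq_along(area_mm2), area_mm2 = area_mm2,
                d_mm = d_mm, micro = d_mm < 0.5)
  total_mm2 <- sum(foam_mask) * pixel_scale_mm^2
  list(mbi_pct = 100 * sum(tab$area_mm2[tab$micro]) / total_mm2,
       bubble_table = tab)
}

#' One-shot physicalomics extraction
#'
#' Convenience wrapper running the full optical pipeline on a rendered or
#' captured series: colour correction from the in-frame card, chromaticity,
#' foam height trajectory, half-life fit and micro-bubble index (measured on
#' the frame closest to t = 30 s).
#'
#' @param series a `urine_series`.
#' @param osmolality urine osmolality (mOsm/kg) for the dilution correction.
#' @return one-row tibble with chromatic features, `t_half_s`, `censored`,
#'   `mbi_pct` and the card-fit `rmse`.
#' @export
extract_physicalomics <- function(series, osmolality) {
  tf <- fit_color_correction(card_colors(series))
  chrom <- extract_chromatic(series, tf, osmolality)
  traj <- foam_height_trajectory(series, transform = tf)
  hl <- estimate_half_life(traj)
  times <- purrr::map_dbl(series$frames, "time_s")
  i30 <- which.min(abs(times - 30))
  img30 <- apply_color_transform(series$frames[[i30]]$img, tf)
  mask30 <- segment_foam(img30, series$foam_roi)
  mbi <- micro_bubble_index(img30, mask30, series$pixel_scale_mm)
  dplyr::bind_cols(chrom,
                   tibble(t_half_s = hl$t_half_s, censored = hl$censored,
                          mbi_pct = mbi$mbi_pct, card_rmse = tf$rmse))
}
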