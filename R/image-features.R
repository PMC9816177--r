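rgb_to_luma <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  if (length(dim(image)) == 3L && dim(image)[3] >= 3L) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  input_error("image must be a 2-d brightness matrix or an H x W x 3 RGB array")
}

#' Per-pixel gradient orientation and magnitude from a Sobel filter
#'
#' Applies the 3x3 Sobel kernels to the brightness image (RGB input is
#' converted by luma weighting 0.299R + 0.587G + 0.114B). The orientation
#' at each pixel is `atan2(Gy, Gx)` mapped to `[0, 180)` degrees — a
#' brightness ramp varying only along x (columns) maps to 0 degrees — and
#' the magnitude is `sqrt(Gx^2 + Gy^2)`. Borders use reflected
#' (edge-replicating) padding.
#'
#' @param image 2-d brightness matrix or H x W x 3 RGB array, values on
#'   any positive scale.
#' @return Object of class `ca_orientation_field`: list with matrices
#'   `orientation` (degrees in `[0, 180)`) and `magnitude`.
#' @export
sobel_orientation_field <- function(image) {
  img <- rgb_to_luma(image)
  if (length(dim(img)) != 2L || any(dim(img) < 3L)) {
    input_error("image must be at least 3 x 3 after brightness conversion")
  }
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(1, 1:h, h), c(1, 1:w, w)]
  nw <- pad[1:h, 1:w];       no <- pad[1:h, 2:(w + 1)];       ne <- pad[1:h, 3:(w + 2)]
  we <- pad[2:(h + 1), 1:w];                                   ea <- pad[2:(h + 1), 3:(w + 2)]
  sw <- pad[3:(h + 2), 1:w]; so <- pad[3:(h + 2), 2:(w + 1)]; se <- pad[3:(h + 2), 3:(w + 2)]
  gx <- (ne + 2 * ea + se) - (nw + 2 * we + sw)
  gy <- (sw + 2 * so + se) - (nw + 2 * no + ne)
  structure(list(orientation = (rad2deg(atan2(gy, gx))) %% 180,
                 magnitude = sqrt(gx^2 + gy^2)),
            class = "ca_orientation_field")
}

orientation_bins <- function(field, n_bins = 36L) {
  b <- floor(field$orientation / (180 / n_bins)) + 1L
  b[b > n_bins] <- n_bins
  b
}

weighted_hist <- function(bin, mag, n_bins = 36L) {
  h <- numeric(n_bins)
  agg <- rowsum(as.vector(mag), as.vector(bin))
  h[as.integer(rownames(agg))] <- agg
  h
}

# magnitude-weighted orientation histogram, 5-degree bins over [0, 180)
orientation_histogram <- function(field, rows = NULL, cols = NULL, n_bins = 36L) {
  ori <- field$orientation; mag <- field$magnitude
  if (!is.null(rows)) { ori <- ori[rows, cols, drop = FALSE]; mag <- mag[rows, cols, drop = FALSE] }
  bin <- floor(ori / (180 / n_bins)) + 1L
  bin[bin > n_bins] <- n_bins
  weighted_hist(bin, mag, n_bins)
}

# plain-list patch statistics from a precomputed histogram
patch_stats_from_hist <- function(h) {
  tot <- sum(h)
  if (tot <= 0) {
    return(list(osi = 0, mean_deg = NA_real_, n_peaks = 0L, total = 0,
                histogram = h))
  }
  centers <- seq(2.5, 177.5, by = 5)
  res <- circular_resultant(centers, h, period = 180)
  list(osi = res$r_bar, mean_deg = res$mean_deg,
       n_peaks = histogram_peaks(h), total = tot, histogram = h)
}

rayleigh_p_from_hist <- function(h, n_px) {
  tot <- sum(h)
  if (tot <= 0) return(1)
  centers <- seq(2.5, 177.5, by = 5)
  rayleigh_test(centers, h, period = 180, n_eff = n_px)$p_value
}

# circular local maxima of a histogram exceeding mean + 3 sd of bin weights
histogram_peaks <- function(h) {
  n <- length(h)
  if (all(h == 0)) return(0L)
  left <- h[c(n, 1:(n - 1))]; right <- h[c(2:n, 1)]
  thr <- mean(h) + 3 * stats::sd(h)
  sum(h > left & h >= right & h > thr)
}

#' Orientation selectivity of an image patch
#'
#' Builds the 36-bin magnitude-weighted orientation histogram of a patch
#' and treats it as a circular distribution with doubled angles (period
#' 180): `osi = |sum_b h_b exp(2 i theta_b)| / sum_b h_b`, and the mean
#' orientation is half the argument of the same sum.
#'
#' @param field A [sobel_orientation_field()].
#' @param rows,cols Integer index vectors delimiting the patch; `NULL`
#'   uses the whole field.
#' @return One-row tibble with `osi`, `mean_orientation_deg` (`NA` when
#'   the patch has zero gradient magnitude, in which case `osi` is
#'   reported as 0), `n_histogram_peaks`, `total_weight` and the
#'   `histogram` (list column).
#' @export
patch_osi <- function(field, rows = NULL, cols = NULL) {
  st <- patch_stats_from_hist(orientation_histogram(field, rows, cols))
  tibble::tibble(osi = st$osi, mean_orientation_deg = st$mean_deg,
                 n_histogram_peaks = st$n_peaks, total_weight = st$total,
                 histogram = list(st$histogram))
}

#' Thresholds for classifying a patch as coloured
#'
#' A patch counts as coloured when (a) every smoothed RGB channel
#' histogram peaks away from black and white (inside `[delta, 255 -
#' delta]`), (b) the three channel peaks are not all within a `delta`-wide
#' band of each other (ruling out gray patches), and (c) the patch is not
#' significantly oriented.
#'
#' @param delta Channel-value threshold (default 30; must lie in
#'   `(0, 128)`).
#' @return List of class `ca_color_criteria`.
#' @export
color_criteria <- function(delta = 30) {
  if (delta <= 0 || delta >= 128) config_error("`delta` must lie in (0, 128)")
  structure(list(delta = delta), class = "ca_color_criteria")
}

# mode of the width-5 moving-average smoothed 256-bin channel histogram;
# ties break toward the lower value (which.max returns the first maximum)
channel_peak <- function(values) {
  h <- tabulate(pmin(pmax(round(values), 0), 255) + 1L, nbins = 256L)
  which.max(moving_average(h, 5L)) - 1L
}

classify_from_parts <- function(n_peaks, p_orient, peaks, delta, p_threshold) {
  oriented_sig <- is.finite(p_orient) && p_orient < p_threshold
  if (oriented_sig && n_peaks == 1L) return("oriented")
  ok_a <- all(peaks >= delta & peaks <= 255 - delta)
  ok_b <- (max(peaks) - min(peaks)) > delta
  if (!oriented_sig && ok_a && ok_b) return("colored")
  "neither"
}

# weights scaled to the pixel count act as effective observations
patch_orientation_p <- function(field, rows = NULL, cols = NULL) {
  h <- orientation_histogram(field, rows, cols)
  n_px <- if (is.null(rows)) length(field$magnitude) else length(rows) * length(cols)
  rayleigh_p_from_hist(h, n_px)
}

#' Classify an image patch as oriented, coloured, or neither
#'
#' A patch is `"oriented"` when the Rayleigh test on its doubled-angle
#' magnitude-weighted orientation histogram is significant (effective
#' sample size = pixel count) and the histogram has exactly one peak
#' (local maxima exceeding the mean bin weight by more than 3 s.d.);
#' patches with multiple orientation peaks are excluded from the oriented
#' class. It is `"colored"` when the [color_criteria()] hold and it is not
#' significantly oriented. Otherwise it is `"neither"`.
#'
#' @param patch H x W x 3 RGB array (channel values in `[0, 255]`) or 2-d
#'   brightness matrix, at least 3 x 3.
#' @param criteria A [color_criteria()].
#' @param p_threshold Rayleigh significance threshold for orientedness.
#' @return A single string: `"oriented"`, `"colored"` or `"neither"`.
#' @export
classify_patch <- function(patch, criteria = color_criteria(),
                           p_threshold = 0.05) {
  dm <- dim(patch)
  if (is.null(dm) || min(dm[1:2]) < 3L) {
    rlang::abort("patch must be at least 3 x 3 pixels", class = "crossadapt_size_error")
  }
  field <- sobel_orientation_field(patch)
  st <- patch_stats_from_hist(orientation_histogram(field))
  p_orient <- rayleigh_p_from_hist(st$histogram, length(field$magnitude))
  if (length(dm) == 3L && dm[3] >= 3L) {
    peaks <- vapply(1:3, function(k) channel_peak(patch[, , k]), numeric(1))
  } else {
    peaks <- rep(channel_peak(patch), 3)
  }
  classify_from_parts(st$n_peaks, p_orient, peaks, criteria$delta, p_threshold)
}

#' Sliding-window feature map of an image
#'
#' Scores every `window` x `window` patch of the image on a grid moved by
#' `stride` pixels (only full windows are used) for orientation content
#' (OSI, mean orientation) and classifies it as oriented, coloured or
#' neither.
#'
#' @param image H x W x 3 RGB array (values in `[0, 255]`) or brightness
#'   matrix.
#' @param window,stride Window size and step in pixels.
#' @inheritParams classify_patch
#' @param field Optional precomputed [sobel_orientation_field()] of
#'   `image`.
#' @return Tibble with one row per window: `win_row`, `win_col` (grid
#'   indices), `row0`, `col0` (top-left pixel), `center_row`,
#'   `center_col`, `osi`, `mean_orientation_deg`, `n_histogram_peaks`,
#'   `p_orientation`, `label`.
#' @export
feature_map <- function(image, window = 50, stride = 10,
                        criteria = color_criteria(), p_threshold = 0.05,
                        field = NULL) {
  if (stride <= 0) config_error("`stride` must be positive")
  dm <- dim(image)
  h <- dm[1]; w <- dm[2]
  if (h < window || w < window) config_error("image smaller than one window")
  if (is.null(field)) field <- sobel_orientation_field(image)
  binmat <- orientation_bins(field)
  mag <- field$magnitude
  r0s <- seq(1, h - window + 1, by = stride)
  c0s <- seq(1, w - window + 1, by = stride)
  is_rgb <- length(dm) == 3L && dm[3] >= 3L
  grid <- expand.grid(ri = seq_along(r0s), ci = seq_along(c0s))
  n_win <- nrow(grid)
  osi <- numeric(n_win); mean_or <- numeric(n_win); n_pk <- integer(n_win)
  p_or <- numeric(n_win); lab <- character(n_win)
  n_px <- window * window
  for (k in seq_len(n_win)) {
    rows <- r0s[grid$ri[k]]:(r0s[grid$ri[k]] + window - 1)
    cols <- c0s[grid$ci[k]]:(c0s[grid$ci[k]] + window - 1)
    st <- patch_stats_from_hist(
      weighted_hist(binmat[rows, cols], mag[rows, cols]))
    p <- rayleigh_p_from_hist(st$histogram, n_px)
    peaks <- if (is_rgb) {
      c(channel_peak(image[rows, cols, 1]), channel_peak(image[rows, cols, 2]),
        channel_peak(image[rows, cols, 3]))
    } else rep(channel_peak(image[rows, cols]), 3)
    osi[k] <- st$osi; mean_or[k] <- st$mean_deg; n_pk[k] <- st$n_peaks
    p_or[k] <- p
    lab[k] <- classify_from_parts(st$n_peaks, p, peaks, criteria$delta, p_threshold)
  }
  out <- tibble::tibble(win_row = grid$ri, win_col = grid$ci,
                        row0 = r0s[grid$ri], col0 = c0s[grid$ci],
                        center_row = r0s[grid$ri] + (window - 1) / 2,
                        center_col = c0s[grid$ci] + (window - 1) / 2,
                        osi = osi, mean_orientation_deg = mean_or,
                        n_histogram_peaks = n_pk, p_orientation = p_or,
                        label = lab)
  attr(out, "window") <- window
  attr(out, "stride") <- stride
  attr(out, "image_dim") <- dm
  out
}
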