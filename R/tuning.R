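#' Circular selectivity index (CSI/OSI) of a tuning curve
#'
#' The colour (period 360) or orientation (period 180) selectivity index is
#' the normalized length of the vector sum of the tuning curve,
#' `|sum_i r_i exp(i phi_i)| / sum_i r_i`, with `phi_i = theta_i` for
#' colour and `phi_i = 2 theta_i` for orientation (angle doubling so that
#' orientation selectivity is well defined on the 180-degree circle). It is
#' 0 for an untuned (flat) curve and 1 for a neuron responding to a single
#' stimulus.
#'
#' @param responses Mean responses (spikes/s or counts), one per angle,
#'   non-negative.
#' @param angles_deg Stimulus angles in degrees.
#' @param period 360 for colour, 180 for orientation.
#' @return The selectivity index in `[0, 1]`; `NA` (with a warning) if all
#'   responses are zero, which is distinct from an untuned curve with
#'   index 0.
#' @examples
#' ang <- seq(0, 337.5, by = 22.5)
#' selectivity_index(rep(10, 16), ang)            # untuned: 0
#' selectivity_index(c(10, rep(0, 15)), ang)      # perfectly selective: 1
#' @export
selectivity_index <- function(responses, angles_deg, period = 360) {
  if (length(responses) != length(angles_deg)) {
    input_error("`responses` and `angles_deg` must have the same length")
  }
  if (any(responses < 0)) input_error("responses must be non-negative")
  if (sum(responses) <= 0) {
    rlang::warn("all responses are zero; selectivity index undefined")
    return(NA_real_)
  }
  circular_resultant(angles_deg, responses, period)$r_bar
}

#' Preferred angle (preferred colour/orientation) of a tuning curve
#'
#' The circular mean of the response-weighted vector sum,
#' `atan2(Im, Re)` of `sum_i r_i exp(i phi_i)`, halved for
#' 180-degree-periodic features and mapped into `[0, period)`.
#'
#' @inheritParams selectivity_index
#' @return Preferred angle in degrees, or `NA` (with a warning) when the
#'   resultant is zero.
#' @export
preferred_angle <- function(responses, angles_deg, period = 360) {
  if (length(responses) != length(angles_deg)) {
    input_error("`responses` and `angles_deg` must have the same length")
  }
  if (any(responses < 0)) input_error("responses must be non-negative")
  res <- circular_resultant(angles_deg, responses, period)
  if (!is.finite(res$r_bar) || Mod(res$z) < 1e-12 * max(res$total, 1)) {
    rlang::warn("zero resultant; preferred angle undefined")
    return(NA_real_)
  }
  res$mean_deg
}

#' Per-neuron tuning curves from a wide trial table
#'
#' @param data A wide trial table with columns `stimulus_angle_deg`,
#'   optionally `condition`, and `neuron_<k>` spike counts.
#' @param window_ms Analysis window in ms used to convert counts to rates;
#'   taken from `attr(data, "window_ms")` when `NULL`.
#' @return A tibble with one row per (condition,) neuron and stimulus
#'   angle: mean rate (spikes/s), `sem`, and `n_trials`.
#' @export
tuning_curve <- function(data, window_ms = NULL) {
  window_ms <- window_ms %||% attr(data, "window_ms")
  if (is.null(window_ms)) input_error("`window_ms` not supplied and not an attribute of `data`")
  w_s <- window_ms / 1000
  cols <- neuron_cols(data)
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(data)[c(intersect(c("condition", "stimulus_angle_deg"), names(data)), cols)],
    cols = dplyr::all_of(cols), names_to = "neuron", values_to = "count"
  )
  grp <- intersect(c("condition", "neuron", "stimulus_angle_deg"), names(long))
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      rate = mean(.data$count) / w_s,
      sem = stats::sd(.data$count) / sqrt(dplyr::n()) / w_s,
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Single-neuron tuning statistics for every neuron of a trial table
#'
#' Computes, per neuron (and per condition when a `condition` column is
#' present): the selectivity index of the trial-averaged tuning curve, the
#' Rayleigh p-value on the rate-weighted per-trial angles, the preferred
#' angle, and the peak firing rate (maximum of the tuning curve).
#'
#' @inheritParams tuning_curve
#' @param period 360 for colour, 180 for orientation; taken from
#'   `attr(data, "period")` when `NULL`.
#' @return A tibble with columns `condition` (if present), `neuron`, `csi`,
#'   `p_value`, `preferred_deg`, `peak_rate`.
#' @export
population_tuning <- function(data, period = NULL, window_ms = NULL) {
  period <- period %||% attr(data, "period") %||% 360
  window_ms <- window_ms %||% attr(data, "window_ms")
  if (is.null(window_ms)) input_error("`window_ms` not supplied and not an attribute of `data`")
  w_s <- window_ms / 1000
  cols <- neuron_cols(data)
  angles <- data$stimulus_angle_deg
  has_cond <- "condition" %in% names(data)
  groups <- if (has_cond) split(seq_len(nrow(data)), data$condition) else list(all = seq_len(nrow(data)))
  out <- purrr::imap(groups, function(idx, cond) {
    cnt <- counts_matrix(data[idx, ])
    ang <- angles[idx]
    uang <- sort(unique(ang))
    purrr::map(seq_along(cols), function(j) {
      cj <- cnt[, j]
      curve <- vapply(uang, function(a) mean(cj[ang == a]), numeric(1)) / w_s
      csi <- if (sum(curve) > 0) circular_resultant(uang, curve, period)$r_bar else NA_real_
      p <- if (sum(cj) > 0) rayleigh_test(ang, cj, period = period)$p_value else NA_real_
      pref <- if (isTRUE(sum(curve) > 0)) circular_resultant(uang, curve, period)$mean_deg else NA_real_
      tibble::tibble(condition = cond, neuron = cols[j], csi = csi,
                     p_value = p, preferred_deg = pref,
                     peak_rate = max(curve))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (!has_cond) out$condition <- NULL
  out
}

#' Time-resolved tuning and tuning latency in sliding windows
#'
#' Evaluates the selectivity index and Rayleigh p-value in windows of
#' `window_ms` sliding by `step_ms` over per-trial binned spike counts,
#' applies a Holm-Bonferroni correction across the windows of the neuron,
#' and defines tuning latency as the first window start at which corrected
#' significance holds.
#'
#' @param counts Matrix of spike counts, trials by time bins.
#' @param angles_deg Stimulus angle of each trial, degrees.
#' @param bin_ms Width of each time bin, ms.
#' @param window_ms,step_ms Sliding-window size and step, ms.
#' @param period 360 for colour, 180 for orientation.
#' @param alpha Significance level applied to the corrected p-values.
#' @param t0_ms Time of the first bin's left edge relative to stimulus
#'   onset, ms.
#' @return A tibble of class `ca_timecourse` with columns
#'   `window_start_ms`, `csi`, `p_value`, `p_holm`, `significant`, and a
#'   `latency_ms` attribute (see [tuning_latency()]).
#' @export
sliding_tuning <- function(counts, angles_deg, bin_ms, window_ms = 200,
                           step_ms = 5, period = 360, alpha = 0.05,
                           t0_ms = 0) {
  counts <- as.matrix(counts)
  n_bins <- ncol(counts)
  epoch_ms <- n_bins * bin_ms
  if (window_ms > epoch_ms) config_error("`window_ms` exceeds the epoch covered by `counts`")
  if (step_ms <= 0 || bin_ms <= 0) config_error("`step_ms` and `bin_ms` must be positive")
  starts <- seq(0, epoch_ms - window_ms, by = step_ms)
  win_bins <- window_ms / bin_ms
  # cumulative counts across bins make every window sum O(trials)
  cs <- cbind(0, t(apply(counts, 1, cumsum)))
  uang <- sort(unique(angles_deg))
  w_s <- window_ms / 1000
  res <- purrr::map(starts, function(s) {
    b0 <- round(s / bin_ms)
    b1 <- b0 + win_bins
    w_tr <- cs[, b1 + 1L] - cs[, b0 + 1L]
    curve <- vapply(uang, function(a) mean(w_tr[angles_deg == a]), numeric(1)) / w_s
    csi <- if (sum(curve) > 0) circular_resultant(uang, curve, period)$r_bar else NA_real_
    p <- if (sum(w_tr) > 0) rayleigh_test(angles_deg, w_tr, period = period)$p_value else 1
    c(csi = csi, p = p)
  })
  res <- do.call(rbind, res)
  p_holm <- stats::p.adjust(res[, "p"], method = "holm")
  out <- tibble::tibble(
    window_start_ms = starts + t0_ms,
    csi = res[, "csi"],
    p_value = res[, "p"],
    p_holm = p_holm,
    significant = p_holm < alpha
  )
  sig <- which(out$significant)
  attr(out, "latency_ms") <- if (length(sig)) out$window_start_ms[sig[1]] else NA_real_
  class(out) <- c("ca_timecourse", class(out))
  out
}

#' Tuning latency of a sliding-window timecourse
#'
#' @param x A `ca_timecourse` from [sliding_tuning()].
#' @return First window start (ms) with corrected significance, or `NA`.
#' @export
tuning_latency <- function(x) attr(x, "latency_ms")

#' Tuning-class assignment for a neuron
#'
#' Assigns each neuron to a tuning class from its colour and orientation
#' Rayleigh p-values. Neurons whose peak firing rate is below
#' `min_peak_rate` (default 10 spikes/s) are excluded to control for noisy
#' tuning-curve estimates.
#'
#' @param p_color,p_orientation Rayleigh p-values for the colour and
#'   orientation tuning curves (vectorized). `NA` counts as not
#'   significant.
#' @param peak_rate Peak firing rate across both tuning curves, spikes/s.
#' @param min_peak_rate Exclusion threshold, spikes/s.
#' @param alpha Significance level.
#' @return Character vector with levels `"color-only"`,
#'   `"orientation-only"`, `"both"`, `"neither"`, `"excluded"`.
#' @export
classify_tuning <- function(p_color, p_orientation, peak_rate,
                            min_peak_rate = 10, alpha = 0.05) {
  sig_c <- !is.na(p_color) & p_color < alpha
  sig_o <- !is.na(p_orientation) & p_orientation < alpha
  out <- dplyr::case_when(
    peak_rate < min_peak_rate ~ "excluded",
    sig_c & sig_o ~ "both",
    sig_c ~ "color-only",
    sig_o ~ "orientation-only",
    .default = "neither"
  )
  out
}
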