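#' Detect fixations from an eye-position trace by velocity thresholding
#'
#' Eye speed is computed by central differences on x and y, smoothed with
#' a short moving average; maximal runs with speed below
#' `velocity_threshold` become fixations, and runs shorter than
#' `min_duration_ms` are discarded (they are typically jitter-induced
#' splits). Microsaccades are within-fixation speed excursions exceeding
#' the fixation's mean speed by more than 3 s.d. while staying below the
#' saccade threshold.
#'
#' @param trace Tibble with `t_ms` (uniform 1-ms sampling), `x_deg`,
#'   `y_deg`, optionally `pupil`; or a `ca_eye_session`.
#' @param velocity_threshold Saccade threshold, deg/s.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @param smooth_ms Moving-average width for the speed trace, ms (odd).
#' @param layout Optional [quadrant_layout()] for quadrant labels.
#' @return Tibble of class `ca_fixations`: `fixation_id`, `onset_ms`,
#'   `offset_ms`, `duration_ms`, `x`, `y` (centroid, degrees),
#'   `quadrant`, `mean_pupil`, `microsaccade_count`,
#'   `microsaccade_peak_velocity` (mean peak, deg/s, `NA` when none).
#' @export
detect_fixations <- function(trace, velocity_threshold = 100,
                             min_duration_ms = 50, smooth_ms = 7,
                             layout = NULL) {
  if (inherits(trace, "ca_eye_session")) {
    layout <- layout %||% trace$layout
    trace <- trace$trace
  }
  n <- nrow(trace)
  if (n < 3L) input_error("trace must contain at least 3 samples")
  dt <- diff(trace$t_ms)
  if (max(abs(dt - dt[1])) > 1e-9) input_error("trace must be uniformly sampled")
  dt_s <- dt[1] / 1000
  x <- trace$x_deg; y <- trace$y_deg
  vx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt_s
  vy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) / dt_s
  speed <- moving_average(sqrt(vx^2 + vy^2), as.integer(smooth_ms))
  below <- speed < velocity_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths * dt[1] >= min_duration_ms)
  has_pupil <- "pupil" %in% names(trace)
  out <- purrr::map(keep, function(k) {
    idx <- starts[k]:ends[k]
    # microsaccade statistics use the fixation interior so that the
    # sub-threshold tails of flanking saccades are not counted
    trim <- 10L
    core <- if (length(idx) > 2L * trim + 20L) idx[(trim + 1L):(length(idx) - trim)] else idx
    sp <- speed[core]
    thr_ms <- mean(sp) + 3 * stats::sd(sp)
    exc <- sp > thr_ms & sp < velocity_threshold
    rexc <- rle(exc)
    n_ms <- sum(rexc$values)
    peak_v <- if (n_ms > 0) {
      e2 <- cumsum(rexc$lengths); s2 <- e2 - rexc$lengths + 1L
      mean(vapply(which(rexc$values), function(j) max(sp[s2[j]:e2[j]]), numeric(1)))
    } else NA_real_
    tibble::tibble(
      onset_ms = trace$t_ms[starts[k]], offset_ms = trace$t_ms[ends[k]],
      duration_ms = trace$t_ms[ends[k]] - trace$t_ms[starts[k]] + dt[1],
      x = mean(x[idx]), y = mean(y[idx]),
      mean_pupil = if (has_pupil) mean(trace$pupil[idx]) else NA_real_,
      microsaccade_count = n_ms, microsaccade_peak_velocity = peak_v)
  }) |> purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          duration_ms = numeric(), x = numeric(), y = numeric(),
                          mean_pupil = numeric(), microsaccade_count = integer(),
                          microsaccade_peak_velocity = numeric())
  }
  out$quadrant <- if (!is.null(layout)) quadrant_of(layout, out$x, out$y) else "none"
  out <- dplyr::mutate(out, fixation_id = dplyr::row_number(), .before = 1)
  class(out) <- c("ca_fixations", class(out))
  out
}

# is the receptive-field bounding region, translated by gaze, fully inside
# a single quadrant and inside the monitor?
rf_confined <- function(layout, x, y, rf_box) {
  ext <- attr(layout, "extent_deg")
  bx1 <- x + rf_box$offset[1] - rf_box$half[1]
  bx2 <- x + rf_box$offset[1] + rf_box$half[1]
  by1 <- y + rf_box$offset[2] - rf_box$half[2]
  by2 <- y + rf_box$offset[2] + rf_box$half[2]
  in_monitor <- bx1 >= ext[1] & bx2 <= ext[2] & by1 >= ext[3] & by2 <= ext[4]
  in_one <- rep(FALSE, length(x))
  for (i in seq_len(nrow(layout))) {
    in_one <- in_one | (bx1 >= layout$xmin[i] & bx2 <= layout$xmax[i] &
                          by1 >= layout$ymin[i] & by2 <= layout$ymax[i])
  }
  in_monitor & in_one
}

#' Extract unadapted/adapted pseudo-trials from a fixation sequence
#'
#' A pseudo-trial is a pair of directly consecutive fixations: gray
#' quadrant followed by a test quadrant (unadapted) or adapter quadrant
#' followed by a test quadrant (adapted). A trial is kept only if the
#' neurons' aggregate receptive-field region — a bounding box at a fixed
#' offset from gaze — lies entirely within one quadrant and inside the
#' monitor during the test fixation.
#'
#' @param fixations A [detect_fixations()] result with quadrant labels.
#' @param layout A [quadrant_layout()].
#' @param rf_box List with `offset = c(x, y)` (degrees from gaze to the RF
#'   box center) and `half = c(w, h)` (half-extents, degrees).
#' @return Tibble of class `ca_pseudo_trials`: `trial_id`, `condition`
#'   (`unadapt`/`adapt`), `test_stimulus` (`test1`/`test2`),
#'   `adapter_duration_ms`, `test_onset_ms`, `test_offset_ms`,
#'   `test_duration_ms`, `mean_pupil`, `microsaccade_count`,
#'   `microsaccade_peak_velocity`.
#' @export
extract_pseudo_trials <- function(fixations, layout,
                                  rf_box = list(offset = c(1.5, -1.5),
                                                half = c(1, 1))) {
  if (!setequal(intersect(layout$role, c("gray", "adapter", "test1", "test2")),
                c("gray", "adapter", "test1", "test2"))) {
    config_error("layout must carry the four roles gray, adapter, test1, test2")
  }
  n <- nrow(fixations)
  if (n < 2L) {
    return(structure(tibble::tibble(trial_id = integer(), condition = character(),
                                    test_stimulus = character(),
                                    adapter_duration_ms = numeric(),
                                    test_onset_ms = numeric(), test_offset_ms = numeric(),
                                    test_duration_ms = numeric(), mean_pupil = numeric(),
                                    microsaccade_count = integer(),
                                    microsaccade_peak_velocity = numeric()),
                     class = c("ca_pseudo_trials", class(tibble::tibble()))))
  }
  confined <- rf_confined(layout, fixations$x, fixations$y, rf_box)
  prev_q <- fixations$quadrant[-n]
  this_q <- fixations$quadrant[-1]
  is_trial <- prev_q %in% c("gray", "adapter") & this_q %in% c("test1", "test2") &
    confined[-1]
  idx <- which(is_trial)
  out <- tibble::tibble(
    trial_id = seq_along(idx),
    condition = ifelse(prev_q[idx] == "gray", "unadapt", "adapt"),
    test_stimulus = this_q[idx],
    adapter_duration_ms = fixations$duration_ms[idx],
    test_onset_ms = fixations$onset_ms[idx + 1L],
    test_offset_ms = fixations$offset_ms[idx + 1L],
    test_duration_ms = fixations$duration_ms[idx + 1L],
    mean_pupil = fixations$mean_pupil[idx + 1L],
    microsaccade_count = fixations$microsaccade_count[idx + 1L],
    microsaccade_peak_velocity = fixations$microsaccade_peak_velocity[idx + 1L]
  )
  class(out) <- c("ca_pseudo_trials", class(out))
  out
}

#' Compare eye-movement covariates between conditions
#'
#' Rank-sum (two-sided Wilcoxon) comparisons of the fixation covariates
#' that could confound an adaptation contrast: adapter-fixation durations
#' preceding test1 versus test2, and test-fixation duration, mean pupil
#' size, microsaccade counts and microsaccade peak velocities between
#' unadapted and adapted trials.
#'
#' @param trials A [extract_pseudo_trials()] result.
#' @return Tibble with one row per comparison: `covariate`, `group1`,
#'   `group2`, `n1`, `n2`, `median1`, `median2`, `p_value`. Comparisons
#'   with an empty group are skipped with a warning.
#' @export
covariate_comparison <- function(trials) {
  cmp <- function(covariate, v1, v2, g1, g2) {
    v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
    if (length(v1) < 2L || length(v2) < 2L) {
      rlang::warn(paste0("skipping `", covariate, "`: fewer than 2 observations in a group"))
      return(NULL)
    }
    p <- if (stats::var(c(v1, v2)) == 0) 1 else {
      suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE)$p.value)
    }
    tibble::tibble(covariate = covariate, group1 = g1, group2 = g2,
                   n1 = length(v1), n2 = length(v2),
                   median1 = stats::median(v1), median2 = stats::median(v2),
                   p_value = p)
  }
  ua <- trials$condition == "unadapt"
  t1 <- trials$test_stimulus == "test1"
  rows <- list(
    cmp("adapter_duration_ms", trials$adapter_duration_ms[t1],
        trials$adapter_duration_ms[!t1], "test1", "test2"),
    cmp("test_duration_ms", trials$test_duration_ms[ua],
        trials$test_duration_ms[!ua], "unadapt", "adapt"),
    cmp("mean_pupil", trials$mean_pupil[ua], trials$mean_pupil[!ua],
        "unadapt", "adapt"),
    cmp("microsaccade_count", as.numeric(trials$microsaccade_count[ua]),
        as.numeric(trials$microsaccade_count[!ua]), "unadapt", "adapt"),
    cmp("microsaccade_peak_velocity", trials$microsaccade_peak_velocity[ua],
        trials$microsaccade_peak_velocity[!ua], "unadapt", "adapt")
  )
  purrr::list_rbind(purrr::compact(rows))
}
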