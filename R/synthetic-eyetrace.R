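#' Four-quadrant stimulus layout for free-viewing sessions
#'
#' The free-viewing display divides the monitor into four quadrants with
#' fixed roles: an isoluminant gray control (top right), the adapter
#' (top left), and two test stimuli (bottom quadrants).
#'
#' @param extent_deg Named or positional `c(xmin, xmax, ymin, ymax)` of
#'   the monitor in degrees of visual angle.
#' @param roles Named character vector assigning the roles `gray`,
#'   `adapter`, `test1`, `test2` to the quadrants `top_left`,
#'   `top_right`, `bottom_left`, `bottom_right`.
#' @return Tibble of class `ca_layout` with one row per quadrant
#'   (`quadrant`, `role`, `xmin`, `xmax`, `ymin`, `ymax`) and an
#'   `extent_deg` attribute.
#' @export
quadrant_layout <- function(extent_deg = c(-20, 20, -15, 15),
                            roles = c(top_left = "adapter", top_right = "gray",
                                      bottom_left = "test1", bottom_right = "test2")) {
  need <- c("gray", "adapter", "test1", "test2")
  if (!setequal(unname(roles), need)) {
    config_error("layout must assign the four roles gray, adapter, test1, test2")
  }
  xm <- mean(extent_deg[1:2]); ym <- mean(extent_deg[3:4])
  q <- tibble::tibble(
    quadrant = c("top_left", "top_right", "bottom_left", "bottom_right"),
    xmin = c(extent_deg[1], xm, extent_deg[1], xm),
    xmax = c(xm, extent_deg[2], xm, extent_deg[2]),
    ymin = c(ym, ym, extent_deg[3], extent_deg[3]),
    ymax = c(extent_deg[4], extent_deg[4], ym, ym)
  )
  q$role <- unname(roles[q$quadrant])
  attr(q, "extent_deg") <- extent_deg
  class(q) <- c("ca_layout", class(q))
  q
}

#' Quadrant role at gaze positions
#'
#' @param layout A [quadrant_layout()].
#' @param x,y Gaze coordinates, degrees.
#' @return Character vector of roles, `"none"` outside the monitor.
#' @export
quadrant_of <- function(layout, x, y) {
  out <- rep("none", length(x))
  for (i in seq_len(nrow(layout))) {
    inq <- x >= layout$xmin[i] & x < layout$xmax[i] &
      y >= layout$ymin[i] & y < layout$ymax[i]
    out[inq] <- layout$role[i]
  }
  out
}

#' Configuration for the synthetic eye-trace generator
#'
#' Gaze is sampled at 1 kHz (the fixed eye-tracker rate). Fixation
#' durations are log-normal; saccades between quadrants follow
#' minimum-jerk position profiles whose peak velocity obeys a main
#' sequence `v_max * (1 - exp(-amplitude / a_scale))`, so inter-quadrant
#' saccades peak well above the 100 deg/s detection threshold while
#' within-fixation velocities (including microsaccades) stay below it.
#'
#' @param duration_s Session duration, seconds.
#' @param sample_rate_hz Must be 1000.
#' @param layout A [quadrant_layout()].
#' @param fixation_meanlog,fixation_sdlog Log-normal parameters of
#'   fixation duration (ms).
#' @param main_sequence Named `c(v_max, a_scale)`: peak-velocity
#'   saturation (deg/s) and amplitude scale (deg).
#' @param microsaccade_rate_hz Microsaccade rate within fixations.
#' @param microsaccade_amplitude_deg,microsaccade_peak_velocity
#'   Microsaccade amplitude (deg) and peak velocity (deg/s, below the
#'   saccade threshold).
#' @param pupil_mean,pupil_sd Pupil size AR(1) process parameters
#'   (arbitrary units).
#' @param position_noise_sd Additive gaze noise s.d., degrees (0 for
#'   noiseless traces).
#' @param target_jitter_deg S.d. of the fixation-target jitter around
#'   quadrant centers.
#' @param seed Integer seed.
#' @return List of class `ca_eye_config`.
#' @export
eye_trace_config <- function(duration_s = 60, sample_rate_hz = 1000,
                             layout = quadrant_layout(),
                             fixation_meanlog = log(250), fixation_sdlog = 0.35,
                             main_sequence = c(v_max = 473, a_scale = 7.8),
                             microsaccade_rate_hz = 1,
                             microsaccade_amplitude_deg = 0.15,
                             microsaccade_peak_velocity = 40,
                             pupil_mean = 1000, pupil_sd = 30,
                             position_noise_sd = 0,
                             target_jitter_deg = 2, seed = 1) {
  if (sample_rate_hz != 1000) config_error("`sample_rate_hz` is fixed at 1000 Hz")
  if (duration_s * 1000 < 100) config_error("duration too short for a single fixation")
  if (microsaccade_peak_velocity >= 100) {
    config_error("microsaccade peak velocity must stay below the 100 deg/s threshold")
  }
  structure(list(duration_s = duration_s, sample_rate_hz = 1000,
                 layout = layout, fixation_meanlog = fixation_meanlog,
                 fixation_sdlog = fixation_sdlog,
                 main_sequence = main_sequence,
                 microsaccade_rate_hz = microsaccade_rate_hz,
                 microsaccade_amplitude_deg = microsaccade_amplitude_deg,
                 microsaccade_peak_velocity = microsaccade_peak_velocity,
                 pupil_mean = pupil_mean, pupil_sd = pupil_sd,
                 position_noise_sd = position_noise_sd,
                 target_jitter_deg = target_jitter_deg,
                 seed = as.integer(seed)),
            class = "ca_eye_config")
}

# minimum-jerk displacement fraction and its time derivative scale
minjerk_pos <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
minjerk_vel <- function(s) 30 * s^2 * (1 - s)^2   # x amplitude / duration

#' Generate a synthetic free-viewing eye trace with ground truth
#'
#' Alternates fixations on randomly chosen quadrant targets with
#' minimum-jerk saccades. Ground-truth fixation intervals are the runs in
#' which the analytic eye speed stays below 100 deg/s (i.e. the
#' sub-threshold complement of the saccades), labelled with the quadrant
#' fixated; microsaccade times and a pupil series are included.
#'
#' @param config An [eye_trace_config()].
#' @return List of class `ca_eye_session` with `trace` (tibble `t_ms`,
#'   `x_deg`, `y_deg`, `pupil`), `fixations` (ground-truth tibble
#'   `onset_ms`, `offset_ms`, `duration_ms`, `quadrant`,
#'   `n_microsaccades`), `layout`, and `config`.
#' @export
generate_eye_trace <- function(config) {
  if (!inherits(config, "ca_eye_config")) config <- do.call(eye_trace_config, config)
  cfg <- config
  n_samp <- round(cfg$duration_s * 1000)
  lay <- cfg$layout
  centers <- cbind((lay$xmin + lay$xmax) / 2, (lay$ymin + lay$ymax) / 2)
  half <- cbind((lay$xmax - lay$xmin) / 2, (lay$ymax - lay$ymin) / 2)
  v_max <- cfg$main_sequence[["v_max"]]; a_scale <- cfg$main_sequence[["a_scale"]]
  with_seed(cfg$seed, {
    x <- numeric(n_samp); y <- numeric(n_samp)
    speed <- numeric(n_samp)          # analytic speed, deg/s
    dwell_q <- character(0); dwell_on <- integer(0); dwell_off <- integer(0)
    ms_times <- integer(0)
    draw_target <- function(qi) {
      jit <- pmin(pmax(stats::rnorm(2, 0, cfg$target_jitter_deg),
                       -0.6 * half[qi, ]), 0.6 * half[qi, ])
      centers[qi, ] + jit
    }
    qi <- sample.int(4, 1)
    pos <- draw_target(qi)
    t <- 1L
    while (t <= n_samp) {
      dur <- max(80L, round(stats::rlnorm(1, cfg$fixation_meanlog, cfg$fixation_sdlog)))
      t_end <- min(t + dur - 1L, n_samp)
      idx <- t:t_end
      x[idx] <- pos[1]; y[idx] <- pos[2]
      # microsaccades: out-and-back minimum-jerk excursions below threshold
      n_ms <- stats::rpois(1, cfg$microsaccade_rate_hz * length(idx) / 1000)
      leg <- max(4L, round(1.875 * cfg$microsaccade_amplitude_deg /
                             cfg$microsaccade_peak_velocity * 1000))
      if (n_ms > 0 && length(idx) > 2L * leg + 4L) {
        starts <- sort(sample(seq(t + 1L, t_end - 2L * leg - 1L), n_ms))
        for (m0 in starts) {
          ang <- stats::runif(1, 0, 2 * pi)
          dvec <- cfg$microsaccade_amplitude_deg * c(cos(ang), sin(ang))
          s <- (1:leg) / leg
          out_idx <- m0:(m0 + leg - 1L); back_idx <- (m0 + leg):(m0 + 2L * leg - 1L)
          x[out_idx] <- pos[1] + dvec[1] * minjerk_pos(s)
          y[out_idx] <- pos[2] + dvec[2] * minjerk_pos(s)
          x[back_idx] <- pos[1] + dvec[1] * minjerk_pos(rev(s))
          y[back_idx] <- pos[2] + dvec[2] * minjerk_pos(rev(s))
          v <- cfg$microsaccade_amplitude_deg * minjerk_vel(s) / (leg / 1000)
          speed[out_idx] <- pmax(speed[out_idx], v)
          speed[back_idx] <- pmax(speed[back_idx], rev(v))
          ms_times <- c(ms_times, m0)
        }
      }
      dwell_q <- c(dwell_q, lay$role[qi]); dwell_on <- c(dwell_on, t)
      dwell_off <- c(dwell_off, t_end)
      t <- t_end + 1L
      if (t > n_samp) break
      # saccade to a different quadrant
      qi_new <- sample(setdiff(1:4, qi), 1)
      target <- draw_target(qi_new)
      amp <- sqrt(sum((target - pos)^2))
      vp <- v_max * (1 - exp(-amp / a_scale))
      T_ms <- max(8L, round(1.875 * amp / vp * 1000))
      n_sac <- min(T_ms, n_samp - t + 1L)
      s <- (1:T_ms) / T_ms
      frac <- minjerk_pos(s)[1:n_sac]
      idx <- t:(t + n_sac - 1L)
      x[idx] <- pos[1] + (target[1] - pos[1]) * frac
      y[idx] <- pos[2] + (target[2] - pos[2]) * frac
      speed[idx] <- amp * minjerk_vel(s)[1:n_sac] / (T_ms / 1000)
      pos <- target; qi <- qi_new
      t <- t + n_sac
    }
    if (cfg$position_noise_sd > 0) {
      x <- x + stats::rnorm(n_samp, 0, cfg$position_noise_sd)
      y <- y + stats::rnorm(n_samp, 0, cfg$position_noise_sd)
    }
    # pupil: AR(1) with stationary s.d. pupil_sd
    phi <- 0.995
    innov_sd <- cfg$pupil_sd * sqrt(1 - phi^2)
    pupil <- stats::filter(stats::rnorm(n_samp, 0, innov_sd), phi,
                           method = "recursive")
    pupil <- cfg$pupil_mean + as.numeric(pupil)
    # ground truth: runs where the analytic speed stays below threshold
    below <- speed < 100
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    fix_runs <- which(r$values)
    truth <- purrr::map(fix_runs, function(k) {
      on <- starts[k]; off <- ends[k]
      mid <- (on + off) %/% 2L
      di <- which(dwell_on <= mid & dwell_off >= pmin(mid, dwell_off))
      q <- quadrant_of(lay, x[mid], y[mid])
      tibble::tibble(onset_ms = on - 1L, offset_ms = off - 1L,
                     duration_ms = off - on + 1L, quadrant = q,
                     n_microsaccades = sum(ms_times >= on & ms_times <= off))
    }) |> purrr::list_rbind()
    trace <- tibble::tibble(t_ms = 0:(n_samp - 1L), x_deg = x, y_deg = y,
                            pupil = pupil)
    structure(list(trace = trace, fixations = truth, layout = lay,
                   config = cfg),
              class = "ca_eye_session")
  })
}

#' @export
print.ca_eye_session <- function(x, ...) {
  cat(sprintf("Synthetic free-viewing session: %.1f s at 1 kHz, %d ground-truth fixations\n",
              nrow(x$trace) / 1000, nrow(x$fixations)))
  invisible(x)
}
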