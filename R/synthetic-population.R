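#' Configuration for the synthetic tuned-population generator
#'
#' Describes a population of von Mises-tuned neurons recorded under
#' randomly interleaved unadapted and adapted trials. The defaults emulate
#' a single passive-fixation session: 16 colour stimuli in 22.5-degree
#' steps (or 16 orientations in 11.25-degree steps), roughly 450 trials
#' per condition (28 per stimulus), a small firing-rate decrease under
#' adaptation (gain 0.967, i.e. -3.3\%), a sharpening of tuning
#' (concentration boost), reduced shared variability (latent s.d. shrink)
#' and an increased tuning latency.
#'
#' @param n_neurons Number of neurons.
#' @param n_trials_per_stimulus Trials per stimulus per condition.
#' @param feature `"color"` (period 360) or `"orientation"` (period 180).
#' @param stimulus_angles Stimulus angles in degrees; defaults to 16
#'   equally spaced values over the feature's period.
#' @param baseline_rate,tuning_amplitude Baseline and tuned-peak increment
#'   of the mean rate, spikes/s.
#' @param tuning_concentration von Mises concentration (kappa) of tuned
#'   neurons; 0 is untuned.
#' @param fraction_untuned Fraction of neurons with kappa = 0.
#' @param shared_dims Number of shared latent dimensions.
#' @param shared_sd Latent s.d. (spikes/s along a unit loading vector).
#' @param private_sd Private trial-to-trial s.d., spikes/s.
#' @param adapt_gain Multiplier on mean rates under adaptation.
#' @param adapt_shared_shrink Multiplier in `(0, 1]` on the shared latent
#'   s.d. under adaptation (values below 1 decorrelate the population).
#' @param adapt_kappa_boost Added to kappa under adaptation (sharpens
#'   tuning; also induces tuning in previously untuned neurons).
#' @param latency_shift_ms Response-onset shift under adaptation, used by
#'   the time-resolved generator.
#' @param window_ms Analysis window used to integerize rates into counts.
#' @param seed Integer seed.
#' @return A validated list of class `ca_population_config`.
#' @export
population_config <- function(n_neurons = 40, n_trials_per_stimulus = 28,
                              feature = c("color", "orientation"),
                              stimulus_angles = NULL,
                              baseline_rate = 10, tuning_amplitude = 20,
                              tuning_concentration = 1.5,
                              fraction_untuned = 0.3,
                              shared_dims = 3, shared_sd = 14, private_sd = 3,
                              adapt_gain = 0.967, adapt_shared_shrink = 0.7,
                              adapt_kappa_boost = 0.4, latency_shift_ms = 20,
                              window_ms = 200, seed = 1) {
  feature <- match.arg(feature)
  period <- if (feature == "color") 360 else 180
  if (is.null(stimulus_angles)) stimulus_angles <- seq(0, period - period / 16, length.out = 16)
  if (n_neurons < 1 || n_trials_per_stimulus < 1) {
    config_error("`n_neurons` and `n_trials_per_stimulus` must be positive integers")
  }
  steps <- diff(stimulus_angles)
  if (length(stimulus_angles) < 2 || any(steps <= 0) ||
      max(abs(steps - steps[1])) > 1e-9) {
    config_error("`stimulus_angles` must be strictly increasing and equally spaced")
  }
  if (shared_sd < 0 || private_sd < 0) config_error("`shared_sd` and `private_sd` must be non-negative")
  if (adapt_shared_shrink <= 0 || adapt_shared_shrink > 1) {
    config_error("`adapt_shared_shrink` must lie in (0, 1]")
  }
  if (fraction_untuned < 0 || fraction_untuned > 1) config_error("`fraction_untuned` must lie in [0, 1]")
  if (tuning_concentration < 0 || adapt_kappa_boost < 0) {
    config_error("`tuning_concentration` and `adapt_kappa_boost` must be non-negative")
  }
  if (latency_shift_ms < 0) config_error("`latency_shift_ms` must be non-negative")
  structure(list(
    n_neurons = as.integer(n_neurons),
    n_trials_per_stimulus = as.integer(n_trials_per_stimulus),
    feature = feature, period = period, stimulus_angles = stimulus_angles,
    baseline_rate = baseline_rate, tuning_amplitude = tuning_amplitude,
    tuning_concentration = tuning_concentration,
    fraction_untuned = fraction_untuned, shared_dims = as.integer(shared_dims),
    shared_sd = shared_sd, private_sd = private_sd, adapt_gain = adapt_gain,
    adapt_shared_shrink = adapt_shared_shrink,
    adapt_kappa_boost = adapt_kappa_boost,
    latency_shift_ms = latency_shift_ms, window_ms = window_ms,
    seed = as.integer(seed)
  ), class = "ca_population_config")
}

# mean-rate matrix (stimuli x neurons) for one condition
tuned_rates <- function(angles, prefs, kappa, baseline, amplitude, gain, period) {
  p_mult <- 360 / period
  m <- vapply(seq_along(prefs), function(j) {
    baseline + amplitude * exp(kappa[j] * (cos(p_mult * deg2rad(angles - prefs[j])) - 1))
  }, numeric(length(angles)))
  gain * matrix(m, nrow = length(angles))
}

draw_condition_counts <- function(angles_trial, rate_tbl, stimulus_angles,
                                  loadings, latent_sd, private_sd, window_s) {
  n_tr <- length(angles_trial)
  n <- nrow(loadings); d <- ncol(loadings)
  M <- rate_tbl[match(angles_trial, stimulus_angles), , drop = FALSE]
  L <- matrix(stats::rnorm(n_tr * d, sd = latent_sd), n_tr, d)
  E <- matrix(stats::rnorm(n_tr * n, sd = private_sd), n_tr, n)
  R <- pmax(M + L %*% t(loadings) + E, 0)
  round(R * window_s)
}

as_trial_table <- function(counts, angles_trial, condition, cfg) {
  colnames(counts) <- paste0("neuron_", seq_len(ncol(counts)))
  tbl <- tibble::tibble(
    trial_id = seq_along(angles_trial),
    condition = condition,
    stimulus_angle_deg = angles_trial
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(counts))
  attr(tbl, "window_ms") <- cfg$window_ms
  attr(tbl, "feature") <- cfg$feature
  attr(tbl, "period") <- cfg$period
  tbl
}

#' Generate a synthetic adaptation session (unadapted and adapted trials)
#'
#' Draws spike counts for every neuron, trial and stimulus under the two
#' conditions. Mean rates follow a normalized von Mises tuning curve
#' `baseline + amplitude * exp(kappa * (cos(p * (theta - mu)) - 1))` with
#' `p = 1` for colour and `p = 2` for 180-degree-periodic orientation;
#' trial-to-trial fluctuations are `loadings %*% latents + private noise`;
#' counts are truncated-at-zero integerized rates over the analysis
#' window. The adapted condition multiplies mean rates by `adapt_gain`,
#' shrinks the shared latent s.d. by `adapt_shared_shrink` and adds
#' `adapt_kappa_boost` to every neuron's concentration.
#'
#' @param config A [population_config()].
#' @return A list of class `ca_population` with elements `unadapt` and
#'   `adapt` (wide trial tables), `ground_truth` (per-neuron tibble of
#'   preferred angle, kappa per condition, untuned flag), `loadings`
#'   (neurons x latent dims, unit-norm columns), and `config`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "ca_population_config")) config <- do.call(population_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_neurons
    prefs <- stats::runif(n, 0, cfg$period)
    untuned <- stats::runif(n) < cfg$fraction_untuned
    kappa <- ifelse(untuned, 0, cfg$tuning_concentration)
    loadings <- matrix(stats::rnorm(n * cfg$shared_dims), n, cfg$shared_dims)
    # first latent dimension acts as a population-wide shared gain (all
    # positive loadings), producing positive mean noise correlations
    loadings[, 1] <- abs(loadings[, 1])
    loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
    angles_trial <- rep(cfg$stimulus_angles, each = cfg$n_trials_per_stimulus)
    w_s <- cfg$window_ms / 1000
    make_cond <- function(cond) {
      adapt <- cond == "adapt"
      kap <- kappa + if (adapt) cfg$adapt_kappa_boost else 0
      gain <- if (adapt) cfg$adapt_gain else 1
      lat_sd <- cfg$shared_sd * if (adapt) cfg$adapt_shared_shrink else 1
      rates <- tuned_rates(cfg$stimulus_angles, prefs, kap, cfg$baseline_rate,
                           cfg$tuning_amplitude, gain, cfg$period)
      cnt <- draw_condition_counts(angles_trial, rates, cfg$stimulus_angles,
                                   loadings, lat_sd, cfg$private_sd, w_s)
      as_trial_table(cnt, angles_trial, cond, cfg)
    }
    unadapt <- make_cond("unadapt")
    adapt <- make_cond("adapt")
    gt <- tibble::tibble(
      neuron = paste0("neuron_", seq_len(n)),
      preferred_deg = prefs,
      untuned = untuned,
      kappa_unadapt = kappa,
      kappa_adapt = kappa + cfg$adapt_kappa_boost,
      gain_adapt = cfg$adapt_gain
    )
    structure(list(unadapt = unadapt, adapt = adapt, ground_truth = gt,
                   loadings = loadings, config = cfg),
              class = "ca_population")
  })
}

#' @export
print.ca_population <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic %s-tuning session: %d neurons, %d stimuli x %d ",
                     "trials x 2 conditions (window %g ms, seed %d)\n"),
              cfg$feature, cfg$n_neurons, length(cfg$stimulus_angles),
              cfg$n_trials_per_stimulus, cfg$window_ms, cfg$seed))
  invisible(x)
}

#' Generate time-resolved synthetic trials for latency analyses
#'
#' Per-trial binned spike counts in which the tuned response switches on at
#' `onset_ms` after stimulus onset in the unadapted condition and at
#' `onset_ms + latency_shift_ms` in the adapted condition; before onset
#' the rate is the baseline. Counts are Poisson per bin. This mode is the
#' substrate for [sliding_tuning()] latency recovery.
#'
#' @param config A [population_config()].
#' @param epoch_ms Epoch length, ms. The epoch should include enough
#'   pre-onset baseline that early sliding windows carry little driven
#'   signal, otherwise every window is significant and latency
#'   differences cannot be resolved.
#' @param bin_ms Bin width, ms.
#' @param onset_ms Response onset in the unadapted condition, ms.
#' @return A list of class `ca_population_timecourse` with, per condition,
#'   a 3-d array `counts` (trials x bins x neurons) and the per-trial
#'   `angles_deg`; plus `bin_ms`, `ground_truth` and `config`.
#' @export
generate_population_timecourse <- function(config, epoch_ms = 400, bin_ms = 5,
                                           onset_ms = 50) {
  if (!inherits(config, "ca_population_config")) config <- do.call(population_config, config)
  cfg <- config
  n_bins <- as.integer(round(epoch_ms / bin_ms))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_neurons
    prefs <- stats::runif(n, 0, cfg$period)
    untuned <- stats::runif(n) < cfg$fraction_untuned
    kappa <- ifelse(untuned, 0, cfg$tuning_concentration)
    angles_trial <- rep(cfg$stimulus_angles, each = cfg$n_trials_per_stimulus)
    n_tr <- length(angles_trial)
    bin_s <- bin_ms / 1000
    t_mid <- (seq_len(n_bins) - 0.5) * bin_ms
    make_cond <- function(cond) {
      adapt <- cond == "adapt"
      onset <- onset_ms + if (adapt) cfg$latency_shift_ms else 0
      kap <- kappa + if (adapt) cfg$adapt_kappa_boost else 0
      gain <- if (adapt) cfg$adapt_gain else 1
      rates <- tuned_rates(cfg$stimulus_angles, prefs, kap, cfg$baseline_rate,
                           cfg$tuning_amplitude, gain, cfg$period)
      base <- gain * cfg$baseline_rate
      driven <- t_mid >= onset
      cnt <- array(0L, dim = c(n_tr, n_bins, n))
      for (j in seq_len(n)) {
        rate_tr <- rates[match(angles_trial, cfg$stimulus_angles), j]
        lam <- outer(rep(base, n_tr), as.numeric(!driven)) +
          outer(rate_tr, as.numeric(driven))
        cnt[, , j] <- stats::rpois(n_tr * n_bins, lam * bin_s)
      }
      list(counts = cnt, angles_deg = angles_trial, onset_ms = onset)
    }
    gt <- tibble::tibble(neuron = paste0("neuron_", seq_len(n)),
                         preferred_deg = prefs, untuned = untuned,
                         kappa_unadapt = kappa,
                         kappa_adapt = kappa + cfg$adapt_kappa_boost)
    structure(list(unadapt = make_cond("unadapt"), adapt = make_cond("adapt"),
                   bin_ms = bin_ms, epoch_ms = epoch_ms,
                   ground_truth = gt, config = cfg),
              class = "ca_population_timecourse")
  })
}
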