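neighbor_pairs <- function(angles) {
  a <- sort(unique(angles))
  cbind(a, c(a[-1], a[1]))
}

reattach_table_attrs <- function(tbl, template) {
  attr(tbl, "window_ms") <- attr(template, "window_ms")
  attr(tbl, "feature") <- attr(template, "feature")
  attr(tbl, "period") <- attr(template, "period")
  tbl
}

#' Configuration for a passive-fixation adaptation experiment
#'
#' @param population A [population_config()]; when `NULL` one is built
#'   with the session `seed` and any `...` arguments forwarded to
#'   [population_config()].
#' @param n_iterations_decode Decoder train/test iterations per stimulus
#'   pair.
#' @param train_fraction Decoder training fraction.
#' @param pc_n_reps,pc_var_fraction,pc_subsample_frac Projected-PC
#'   variance-ratio settings (see [pc_variance_ratio()]).
#' @param include_latency Also run the time-resolved tuning-latency
#'   analysis on a matched time-resolved synthetic session.
#' @param latency_epoch_ms,latency_bin_ms,latency_onset_ms Time-resolved
#'   epoch parameters.
#' @param alpha Significance level for tuning classification.
#' @param min_peak_rate Peak-rate exclusion threshold, spikes/s.
#' @param seed Session seed.
#' @param ... Forwarded to [population_config()] when `population` is
#'   `NULL`.
#' @return List of class `ca_fixation_config`.
#' @export
fixation_config <- function(population = NULL, n_iterations_decode = 500,
                            train_fraction = 0.7, pc_n_reps = 100,
                            pc_var_fraction = 0.9, pc_subsample_frac = 0.8,
                            include_latency = TRUE, latency_epoch_ms = 600,
                            latency_bin_ms = 5, latency_onset_ms = 250,
                            alpha = 0.05, min_peak_rate = 10, seed = 1, ...) {
  if (is.null(population)) population <- population_config(seed = seed, ...)
  structure(list(population = population,
                 n_iterations_decode = n_iterations_decode,
                 train_fraction = train_fraction, pc_n_reps = pc_n_reps,
                 pc_var_fraction = pc_var_fraction,
                 pc_subsample_frac = pc_subsample_frac,
                 include_latency = include_latency,
                 latency_epoch_ms = latency_epoch_ms,
                 latency_bin_ms = latency_bin_ms,
                 latency_onset_ms = latency_onset_ms,
                 alpha = alpha, min_peak_rate = min_peak_rate,
                 seed = as.integer(seed)),
            class = "ca_fixation_config")
}

#' Run a passive-fixation cross-feature adaptation session end to end
#'
#' Generates (or accepts) interleaved unadapted and adapted trials, then
#' runs the tuning analyses (selectivity index, Rayleigh significance,
#' preferred angle, tuning class), pairwise noise correlations, the
#' projected-PC variance ratio, linear-discriminant decoding of every
#' neighbouring stimulus pair in both conditions, and (optionally) the
#' sliding-window tuning-latency analysis, and tabulates the adaptation
#' contrasts: change in selectivity (dCSI), fraction of initially untuned
#' neurons that became tuned, change in peak firing rate, change in
#' preferred angle, change in tuning latency, decoder improvement and the
#' PC variance ratio.
#'
#' @param config A [fixation_config()].
#' @param population Optional pre-generated [generate_population()]
#'   result (overrides the generator).
#' @return Object of class `ca_session_report` with elements `summary`
#'   (one-row tibble), `tuning` (per-neuron tibble), `noise`, `pc_ratio`,
#'   `decoding` (per-pair tibble), `latency` (per-neuron tibble or
#'   `NULL`), `config`.
#' @export
run_fixation <- function(config = fixation_config(), population = NULL) {
  cfg <- config
  pop <- population %||% generate_population(cfg$population)
  pcfg <- pop$config
  alpha <- cfg$alpha
  with_seed(cfg$seed + 1000L, {
    tun_u <- population_tuning(pop$unadapt)
    tun_a <- population_tuning(pop$adapt)
    tun <- dplyr::inner_join(
      dplyr::rename(dplyr::select(tun_u, -"condition"),
                    csi_unadapt = "csi", p_unadapt = "p_value",
                    preferred_unadapt = "preferred_deg",
                    peak_rate_unadapt = "peak_rate"),
      dplyr::rename(dplyr::select(tun_a, -"condition"),
                    csi_adapt = "csi", p_adapt = "p_value",
                    preferred_adapt = "preferred_deg",
                    peak_rate_adapt = "peak_rate"),
      by = "neuron")
    tun$included <- pmax(tun$peak_rate_unadapt, tun$peak_rate_adapt) >= cfg$min_peak_rate
    inc <- tun[tun$included, ]
    delta_csi <- mean(inc$csi_adapt - inc$csi_unadapt, na.rm = TRUE)
    delta_csi_pct <- 100 * delta_csi / mean(inc$csi_unadapt, na.rm = TRUE)
    delta_fr_pct <- 100 * mean((inc$peak_rate_adapt - inc$peak_rate_unadapt) /
                                 inc$peak_rate_unadapt, na.rm = TRUE)
    untuned_before <- inc$p_unadapt >= alpha
    frac_newly_tuned <- if (any(untuned_before)) {
      mean(inc$p_adapt[untuned_before] < alpha)
    } else NA_real_
    both_sig <- inc$p_unadapt < alpha & inc$p_adapt < alpha
    delta_pref <- if (any(both_sig)) {
      mean(abs(circ_diff_deg(inc$preferred_adapt[both_sig],
                             inc$preferred_unadapt[both_sig], pcfg$period)))
    } else NA_real_
    nc_u <- noise_correlations(pop$unadapt)
    nc_a <- noise_correlations(pop$adapt)
    pc <- pc_variance_ratio(pop$unadapt, pop$adapt,
                            var_fraction = cfg$pc_var_fraction,
                            n_reps = cfg$pc_n_reps,
                            subsample_frac = cfg$pc_subsample_frac)
    pairs <- neighbor_pairs(pcfg$stimulus_angles)
    decoding <- purrr::map(seq_len(nrow(pairs)), function(k) {
      du <- lda_decode(pop$unadapt, stimulus_pair = pairs[k, ],
                       train_fraction = cfg$train_fraction,
                       n_iterations = cfg$n_iterations_decode)
      da <- lda_decode(pop$adapt, stimulus_pair = pairs[k, ],
                       train_fraction = cfg$train_fraction,
                       n_iterations = cfg$n_iterations_decode)
      tibble::tibble(angle_1 = pairs[k, 1], angle_2 = pairs[k, 2],
                     acc_unadapt = du$accuracy_above_chance,
                     acc_adapt = da$accuracy_above_chance,
                     delta = da$accuracy_above_chance - du$accuracy_above_chance)
    }) |> purrr::list_rbind()
    latency <- NULL
    delta_latency <- NA_real_
    if (isTRUE(cfg$include_latency)) {
      tc <- generate_population_timecourse(pcfg, epoch_ms = cfg$latency_epoch_ms,
                                           bin_ms = cfg$latency_bin_ms,
                                           onset_ms = cfg$latency_onset_ms)
      lat_one <- function(cond) {
        vapply(seq_len(pcfg$n_neurons), function(j) {
          tuning_latency(sliding_tuning(cond$counts[, , j], cond$angles_deg,
                                        bin_ms = tc$bin_ms,
                                        period = pcfg$period, alpha = alpha))
        }, numeric(1))
      }
      latency <- tibble::tibble(neuron = paste0("neuron_", seq_len(pcfg$n_neurons)),
                                latency_unadapt = lat_one(tc$unadapt),
                                latency_adapt = lat_one(tc$adapt))
      both <- is.finite(latency$latency_unadapt) & is.finite(latency$latency_adapt)
      if (any(both)) {
        delta_latency <- mean(latency$latency_adapt[both] -
                                latency$latency_unadapt[both])
      }
    }
    summary <- tibble::tibble(
      experiment = paste0("fixation-", pcfg$feature, "-test"),
      n_neurons = pcfg$n_neurons, n_included = sum(tun$included),
      delta_csi = delta_csi, delta_csi_pct = delta_csi_pct,
      frac_newly_tuned = frac_newly_tuned, delta_fr_pct = delta_fr_pct,
      delta_preferred_deg = delta_pref, delta_latency_ms = delta_latency,
      mean_rsc_unadapt = nc_u$mean_rsc, mean_rsc_adapt = nc_a$mean_rsc,
      pc_mean_ratio = pc$mean_ratio, pc_ratio_sd = pc$resample_sd,
      pc_ratio_p = pc$p_value,
      decode_unadapt = mean(decoding$acc_unadapt),
      decode_adapt = mean(decoding$acc_adapt),
      decode_delta = mean(decoding$delta),
      seed = cfg$seed
    )
    structure(list(experiment = summary$experiment, summary = summary,
                   tuning = tun, noise = list(unadapt = nc_u, adapt = nc_a),
                   pc_ratio = pc, decoding = decoding, latency = latency,
                   config = cfg),
              class = "ca_session_report")
  })
}

#' Configuration for a free-viewing adaptation experiment
#'
#' @param duration_s Session duration, seconds.
#' @param population A [population_config()] describing the recorded
#'   population (its `feature`/angles provide the test stimuli); built
#'   from `seed` when `NULL`.
#' @param test_angles The two test-stimulus angles (degrees on the
#'   feature circle; defaults to the neighbouring hue angles 45 and 67.5
#'   used with a grating adapter).
#' @param eye An [eye_trace_config()]; built from `duration_s` and `seed`
#'   when `NULL`.
#' @param rf_box Receptive-field bounding region (see
#'   [extract_pseudo_trials()]).
#' @param velocity_threshold Fixation-detection threshold, deg/s.
#' @param n_iterations_decode,train_fraction Decoder settings.
#' @param pc_n_reps,pc_var_fraction,pc_subsample_frac Projected-PC
#'   settings.
#' @param min_trials_per_condition Below this the report is marked
#'   underpowered.
#' @param seed Session seed.
#' @return List of class `ca_freeview_config`.
#' @export
freeview_config <- function(duration_s = 600, population = NULL,
                            test_angles = c(45, 67.5), eye = NULL,
                            rf_box = list(offset = c(1.5, -1.5), half = c(1, 1)),
                            velocity_threshold = 100,
                            n_iterations_decode = 500, train_fraction = 0.7,
                            pc_n_reps = 100, pc_var_fraction = 0.9,
                            pc_subsample_frac = 0.8,
                            min_trials_per_condition = 10, seed = 1) {
  if (is.null(population)) population <- population_config(seed = seed + 1L)
  if (is.null(eye)) eye <- eye_trace_config(duration_s = duration_s, seed = seed)
  structure(list(duration_s = duration_s, population = population,
                 test_angles = test_angles, eye = eye, rf_box = rf_box,
                 velocity_threshold = velocity_threshold,
                 n_iterations_decode = n_iterations_decode,
                 train_fraction = train_fraction, pc_n_reps = pc_n_reps,
                 pc_var_fraction = pc_var_fraction,
                 pc_subsample_frac = pc_subsample_frac,
                 min_trials_per_condition = min_trials_per_condition,
                 seed = as.integer(seed)),
            class = "ca_freeview_config")
}

# draw per-trial spike counts for extracted pseudo-trials from the tuned
# population model; the count window is each trial's own fixation duration
simulate_pseudo_trial_counts <- function(trials, pcfg) {
  with_seed(pcfg$seed, {
    n <- pcfg$n_neurons
    prefs <- stats::runif(n, 0, pcfg$period)
    untuned <- stats::runif(n) < pcfg$fraction_untuned
    kappa <- ifelse(untuned, 0, pcfg$tuning_concentration)
    loadings <- matrix(stats::rnorm(n * pcfg$shared_dims), n, pcfg$shared_dims)
    loadings[, 1] <- abs(loadings[, 1])
    loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
    cnt <- matrix(0, nrow(trials), n)
    for (i in seq_len(nrow(trials))) {
      adapt <- trials$condition[i] == "adapt"
      kap <- kappa + if (adapt) pcfg$adapt_kappa_boost else 0
      gain <- if (adapt) pcfg$adapt_gain else 1
      lat_sd <- pcfg$shared_sd * if (adapt) pcfg$adapt_shared_shrink else 1
      rates <- tuned_rates(trials$stimulus_angle_deg[i], prefs, kap,
                           pcfg$baseline_rate, pcfg$tuning_amplitude, gain,
                           pcfg$period)
      fluct <- as.vector(loadings %*% stats::rnorm(pcfg$shared_dims, sd = lat_sd)) +
        stats::rnorm(n, sd = pcfg$private_sd)
      cnt[i, ] <- round(pmax(rates[1, ] + fluct, 0) *
                          trials$test_duration_ms[i] / 1000)
    }
    colnames(cnt) <- paste0("neuron_", seq_len(n))
    cnt
  })
}

#' Run a free-viewing cross-feature adaptation session end to end
#'
#' Generates a synthetic free-viewing session (four-quadrant layout),
#' detects fixations from the eye-velocity trace, extracts
#' unadapted/adapted pseudo-trials, simulates the population's spike
#' counts during the test fixations, compares the eye-movement
#' covariates between conditions, decodes test1 versus test2 in each
#' condition, and computes the projected-PC variance ratio between
#' conditions.
#'
#' @param config A [freeview_config()].
#' @return Object of class `ca_session_report` with `summary`, `trials`,
#'   `fixations`, `covariates`, `decoders`, `pc_ratio`, `config`.
#' @export
run_freeview <- function(config = freeview_config()) {
  cfg <- config
  pcfg <- cfg$population
  session <- generate_eye_trace(cfg$eye)
  fx <- detect_fixations(session, velocity_threshold = cfg$velocity_threshold)
  trials <- extract_pseudo_trials(fx, session$layout, cfg$rf_box)
  underpowered <- FALSE
  if (nrow(trials) == 0L ||
      min(table(factor(trials$condition, c("unadapt", "adapt")))) <
        cfg$min_trials_per_condition) {
    underpowered <- TRUE
    rlang::warn("fewer pseudo-trials than `min_trials_per_condition`; report marked underpowered")
  }
  trials$stimulus_angle_deg <- cfg$test_angles[match(trials$test_stimulus,
                                                     c("test1", "test2"))]
  cnt <- simulate_pseudo_trial_counts(trials, pcfg)
  trials <- dplyr::bind_cols(trials, tibble::as_tibble(cnt))
  with_seed(cfg$seed + 2000L, {
    covariates <- covariate_comparison(trials)
    mk_table <- function(cond, values) {
      sub <- trials[trials$condition == cond, ]
      tbl <- dplyr::bind_cols(
        tibble::tibble(trial_id = sub$trial_id, condition = cond,
                       stimulus_angle_deg = sub$stimulus_angle_deg),
        tibble::as_tibble(values[trials$condition == cond, , drop = FALSE]))
      attr(tbl, "window_ms") <- 1000   # rates below are already per second
      attr(tbl, "period") <- pcfg$period
      tbl
    }
    rates <- cnt / (trials$test_duration_ms / 1000)
    decoders <- list(); deco_rows <- list()
    for (cond in c("unadapt", "adapt")) {
      sub_n <- min(table(factor(trials$stimulus_angle_deg[trials$condition == cond],
                                levels = cfg$test_angles)))
      if (!underpowered && sub_n >= cfg$min_trials_per_condition / 2) {
        d <- lda_decode(mk_table(cond, cnt), stimulus_pair = cfg$test_angles,
                        train_fraction = cfg$train_fraction,
                        n_iterations = cfg$n_iterations_decode)
        decoders[[cond]] <- d
        deco_rows[[cond]] <- tibble::tibble(condition = cond,
                                            acc_above_chance = d$accuracy_above_chance,
                                            se = d$se)
      }
    }
    decoding <- purrr::list_rbind(deco_rows)
    pc <- if (!underpowered) {
      pc_variance_ratio(mk_table("unadapt", rates), mk_table("adapt", rates),
                        var_fraction = cfg$pc_var_fraction,
                        n_reps = cfg$pc_n_reps,
                        subsample_frac = cfg$pc_subsample_frac)
    } else NULL
    decode_delta <- if (nrow(decoding) == 2L) {
      decoding$acc_above_chance[decoding$condition == "adapt"] -
        decoding$acc_above_chance[decoding$condition == "unadapt"]
    } else NA_real_
    summary <- tibble::tibble(
      experiment = "freeview",
      n_fixations = nrow(fx), n_trials = nrow(trials),
      n_unadapt = sum(trials$condition == "unadapt"),
      n_adapt = sum(trials$condition == "adapt"),
      underpowered = underpowered,
      decode_unadapt = if ("unadapt" %in% decoding$condition)
        decoding$acc_above_chance[decoding$condition == "unadapt"] else NA_real_,
      decode_adapt = if ("adapt" %in% decoding$condition)
        decoding$acc_above_chance[decoding$condition == "adapt"] else NA_real_,
      decode_delta = decode_delta,
      pc_mean_ratio = if (!is.null(pc)) pc$mean_ratio else NA_real_,
      seed = cfg$seed
    )
    structure(list(experiment = "freeview", summary = summary,
                   fixations = fx, trials = trials, covariates = covariates,
                   decoders = decoders, decoding = decoding, pc_ratio = pc,
                   config = cfg),
              class = "ca_session_report")
  })
}

#' Configuration for a natural-scene scanpath experiment
#'
#' @param n_images Number of (synthetic) scenes.
#' @param scene A [scene_config()] template; each image re-seeds it.
#' @param n_saccades Saccades per image.
#' @param saccade_model A [fit_saccade_model()]; when `NULL` a model is
#'   fitted to a gamma-amplitude, uniform-direction saccade sample
#'   (median amplitude around 4 degrees).
#' @param deg_to_px Pixels per degree.
#' @param window,stride Feature-map window and stride, pixels.
#' @param seed Session seed.
#' @return List of class `ca_scenes_config`.
#' @export
scenes_config <- function(n_images = 940,
                          scene = scene_config(image_size = c(160, 160),
                                               patch_size = 50,
                                               n_oriented_patches = 1,
                                               n_colored_patches = 1),
                          n_saccades = 300, saccade_model = NULL,
                          deg_to_px = 10, window = 50, stride = 10,
                          seed = 1) {
  structure(list(n_images = as.integer(n_images), scene = scene,
                 n_saccades = as.integer(n_saccades),
                 saccade_model = saccade_model, deg_to_px = deg_to_px,
                 window = window, stride = stride, seed = as.integer(seed)),
            class = "ca_scenes_config")
}

#' Run the natural-scene scanpath simulation end to end
#'
#' For every image: generate a patch-structured scene, compute its
#' sliding-window feature map, simulate a scanpath of pseudo-saccades
#' drawn from the saccade amplitude/direction model, label each fixated
#' patch from the feature map, and pool the iso-/cross-feature saccade
#' fractions across images.
#'
#' @param config A [scenes_config()].
#' @return Object of class `ca_session_report` with `summary` (includes
#'   the pooled percentages and the total transition count),
#'   `transitions` (a [cross_feature_fraction()] result) and `config`.
#' @export
run_scenes <- function(config = scenes_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    model <- cfg$saccade_model
    if (is.null(model)) {
      amp <- stats::rgamma(2000, shape = 3, scale = 1.5)
      dir <- stats::runif(2000, 0, 360)
      model <- fit_saccade_model(tibble::tibble(amplitude_deg = amp,
                                                direction_deg = dir))
    }
    scene_seeds <- sample.int(2^31 - 1, cfg$n_images)
    scanpaths <- vector("list", cfg$n_images)
    for (i in seq_len(cfg$n_images)) {
      sc_cfg <- cfg$scene
      sc_cfg$seed <- scene_seeds[i]
      sc <- generate_scene(sc_cfg)
      fmap <- feature_map(sc$image, window = cfg$window, stride = cfg$stride)
      scanpaths[[i]] <- simulate_scanpath(sc$image, model,
                                          n_saccades = cfg$n_saccades,
                                          deg_to_px = cfg$deg_to_px,
                                          feature_grid = fmap)
    }
    names(scanpaths) <- sprintf("image_%04d", seq_len(cfg$n_images))
    transitions <- cross_feature_fraction(scanpaths)
    p <- transitions$pooled
    summary <- tibble::tibble(
      experiment = "scenes", n_images = cfg$n_images,
      n_saccades_per_image = cfg$n_saccades,
      n_transitions = p$n_transitions,
      pct_iso = p$pct_iso, pct_cross = p$pct_cross, pct_other = p$pct_other,
      pct_cross_of_feature = p$pct_cross_of_feature,
      seed = cfg$seed
    )
    structure(list(experiment = "scenes", summary = summary,
                   transitions = transitions, config = cfg),
              class = "ca_session_report")
  })
}

#' @export
print.ca_session_report <- function(x, ...) {
  cat("Session report:", x$experiment, "\n")
  print(x$summary)
  invisible(x)
}
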