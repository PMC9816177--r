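test_that("selectivity index hits its analytic anchors", {
  # flat curve: symmetric cancellation
  expect_equal(selectivity_index(rep(10, 16), color_angles), 0, tolerance = 1e-12)
  # single nonzero response: perfectly selective
  expect_equal(selectivity_index(c(10, rep(0, 15)), color_angles), 1)
  # same anchors on the orientation (period 180) circle
  expect_equal(selectivity_index(rep(7, 16), orientation_angles, period = 180), 0,
               tolerance = 1e-12)
  expect_equal(selectivity_index(c(0, 0, 12, rep(0, 13)), orientation_angles,
                                 period = 180), 1)
})

test_that("selectivity index matches an independent evaluation of the vector-sum formula", {
  # von Mises tuning curve, kappa = 2, independent arithmetic oracle
  r <- 5 + 20 * exp(2 * (cos(pi / 180 * (color_angles - 90)) - 1))
  z <- sum(r * exp(1i * pi / 180 * color_angles))
  expect_equal(selectivity_index(r, color_angles), Mod(z) / sum(r),
               tolerance = 1e-12)
  # orientation: doubled angles
  ro <- 5 + 20 * exp(2 * (cos(2 * pi / 180 * (orientation_angles - 90)) - 1))
  zo <- sum(ro * exp(2i * pi / 180 * orientation_angles))
  expect_equal(selectivity_index(ro, orientation_angles, period = 180),
               Mod(zo) / sum(ro), tolerance = 1e-12)
})

test_that("selectivity index is scale invariant and decreases under an added baseline", {
  r <- c(2, 5, 20, 9, 3, 1, 1, 2, 4, 2, 1, 6, 3, 2, 1, 1)
  csi <- selectivity_index(r, color_angles)
  expect_equal(selectivity_index(3.7 * r, color_angles), csi, tolerance = 1e-12)
  expect_lt(selectivity_index(r + 5, color_angles), csi)
})

test_that("all-zero responses are flagged as undefined, distinct from zero", {
  expect_warning(out <- selectivity_index(rep(0, 16), color_angles),
                 "undefined")
  expect_true(is.na(out))
})

test_that("preferred angle recovers delta curves and is step-equivariant", {
  r <- c(0, 0, 0, 10, rep(0, 12))
  expect_equal(preferred_angle(r, color_angles), 67.5)
  # rotating the curve by one step shifts the preferred angle by one step
  r2 <- r[c(16, 1:15)]
  expect_equal(preferred_angle(r2, color_angles), 90)
  # noiseless von Mises at 90 degrees on the orientation circle
  ro <- 20 * exp(3 * (cos(2 * pi / 180 * (orientation_angles - 90)) - 1))
  expect_equal(preferred_angle(ro, orientation_angles, period = 180), 90,
               tolerance = 1e-9)
  expect_warning(out <- preferred_angle(rep(1, 16), color_angles), "undefined")
  expect_true(is.na(out))
})

test_that("population tuning recovers generated preferred angles for tuned neurons", {
  pop <- generate_population(population_config(
    n_neurons = 60, n_trials_per_stimulus = 30, tuning_concentration = 1.5,
    fraction_untuned = 0, adapt_kappa_boost = 0, seed = 7))
  pt <- population_tuning(pop$unadapt)
  err <- abs(crossadapt:::circ_diff_deg(pt$preferred_deg,
                                        pop$ground_truth$preferred_deg, 360))
  # within half the 22.5-degree stimulus step for at least 95% of neurons
  expect_gte(mean(err <= 11.25), 0.95)
})

test_that("sliding tuning finds immediate latency for a stationary tuned response", {
  pop <- generate_population_timecourse(
    population_config(n_neurons = 1, tuning_concentration = 3,
                      fraction_untuned = 0, n_trials_per_stimulus = 20, seed = 2),
    epoch_ms = 400, bin_ms = 5, onset_ms = 0)
  tc <- sliding_tuning(pop$unadapt$counts[, , 1], pop$unadapt$angles_deg,
                       bin_ms = 5)
  expect_equal(tuning_latency(tc), 0)
  expect_true(all(tc$significant))
})

test_that("sliding tuning recovers a generated latency shift between conditions", {
  # per-neuron latency estimates are heavy-tailed, so the recovered shift is
  # averaged over neurons and over three independent sessions
  shifts <- vapply(1:3, function(s) {
    cfg <- population_config(n_neurons = 20, tuning_concentration = 3,
                             fraction_untuned = 0, tuning_amplitude = 40,
                             n_trials_per_stimulus = 30,
                             adapt_kappa_boost = 0, adapt_gain = 1,
                             latency_shift_ms = 20, seed = s)
    tc <- generate_population_timecourse(cfg, epoch_ms = 600, bin_ms = 5,
                                         onset_ms = 250)
    lat <- function(cond) {
      vapply(1:20, function(j) {
        tuning_latency(sliding_tuning(cond$counts[, , j], cond$angles_deg,
                                      bin_ms = 5))
      }, numeric(1))
    }
    lu <- lat(tc$unadapt); la <- lat(tc$adapt)
    ok <- is.finite(lu) & is.finite(la)
    expect_gt(mean(ok), 0.8)
    mean(la[ok] - lu[ok])
  }, numeric(1))
  expect_lt(abs(mean(shifts) - 20), 5)
})

test_that("untuned neurons rarely reach corrected significance in sliding windows", {
  cfg <- population_config(n_neurons = 40, fraction_untuned = 1,
                           adapt_kappa_boost = 0, shared_sd = 0, seed = 9)
  tc <- generate_population_timecourse(cfg, epoch_ms = 400, bin_ms = 5,
                                       onset_ms = 50)
  lat <- vapply(1:40, function(j) {
    tuning_latency(sliding_tuning(tc$unadapt$counts[, , j],
                                  tc$unadapt$angles_deg, bin_ms = 5))
  }, numeric(1))
  expect_gte(mean(is.na(lat)), 0.95)
})

test_that("sliding tuning rejects a window longer than the epoch", {
  expect_error(sliding_tuning(matrix(1, 10, 20), rep(color_angles, length.out = 10),
                              bin_ms = 5, window_ms = 200),
               class = "crossadapt_config_error")
})

test_that("tuning classes follow significance and the peak-rate exclusion", {
  expect_equal(classify_tuning(0.01, 0.01, 20), "both")
  expect_equal(classify_tuning(0.01, 0.2, 20), "color-only")
  expect_equal(classify_tuning(0.2, 0.01, 20), "orientation-only")
  expect_equal(classify_tuning(0.2, 0.2, 20), "neither")
  # peak firing rate below 10 spikes/s is excluded regardless of significance
  expect_equal(classify_tuning(0.001, 0.001, 8), "excluded")
  # fully untuned population: about (1 - alpha) of neurons land in 'neither'
  pop <- generate_population(population_config(
    n_neurons = 300, fraction_untuned = 1, adapt_kappa_boost = 0,
    shared_sd = 0, baseline_rate = 20, seed = 11))
  pt <- population_tuning(pop$unadapt)
  cls <- classify_tuning(pt$p_value, rep(1, nrow(pt)), pt$peak_rate)
  expect_gt(mean(cls == "neither"), 0.9)
})
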