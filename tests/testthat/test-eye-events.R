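test_that("a constant-position trace yields one fixation spanning the trace", {
  tr <- tibble::tibble(t_ms = 0:999, x_deg = 1.5, y_deg = -2, pupil = 100)
  fx <- detect_fixations(tr)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$onset_ms, 0)
  expect_equal(fx$offset_ms, 999)
  expect_equal(fx$x, 1.5)
})

test_that("a pure high-velocity sweep yields no fixations", {
  tr <- tibble::tibble(t_ms = 0:499, x_deg = 0.3 * (0:499), y_deg = 0)  # 300 deg/s
  expect_equal(nrow(detect_fixations(tr)), 0L)
})

test_that("non-uniform sampling is rejected", {
  tr <- tibble::tibble(t_ms = c(0, 1, 3, 4), x_deg = 0, y_deg = 0)
  expect_error(detect_fixations(tr), class = "crossadapt_input_error")
})

test_that("detection recovers generator ground truth on clean traces", {
  es <- generate_eye_trace(eye_trace_config(duration_s = 20,
                                            microsaccade_rate_hz = 0, seed = 42))
  fx <- detect_fixations(es)
  truth <- es$fixations[es$fixations$duration_ms >= 50, ]
  expect_equal(nrow(fx), nrow(truth))
  expect_lte(max(abs(fx$onset_ms - truth$onset_ms)), 5)
  expect_lte(max(abs(fx$offset_ms - truth$offset_ms)), 5)
  expect_equal(fx$quadrant, truth$quadrant)
})

test_that("generated saccades exceed the threshold and fixation velocity stays below it", {
  es <- generate_eye_trace(eye_trace_config(duration_s = 10, seed = 7))
  tr <- es$trace
  n <- nrow(tr)
  vx <- (tr$x_deg[3:n] - tr$x_deg[1:(n - 2)]) / 0.002
  vy <- (tr$y_deg[3:n] - tr$y_deg[1:(n - 2)]) / 0.002
  speed <- c(0, sqrt(vx^2 + vy^2), 0)
  # saccadic portions reach well above threshold
  expect_gt(max(speed), 150)
  # within ground-truth fixations, speed stays below threshold
  for (i in seq_len(nrow(es$fixations))) {
    idx <- (es$fixations$onset_ms[i]:es$fixations$offset_ms[i]) + 1
    idx <- idx[idx > 1 & idx < n]
    expect_lt(max(speed[idx]), 100)
  }
})

test_that("lowering the velocity threshold never increases total fixation time", {
  es <- generate_eye_trace(eye_trace_config(duration_s = 15, seed = 8))
  tot <- vapply(c(120, 100, 60, 30), function(th) {
    sum(detect_fixations(es, velocity_threshold = th)$duration_ms)
  }, numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("pseudo-trials follow the gray/adapter-then-test definition", {
  lay <- quadrant_layout()
  fx <- tibble::tibble(
    fixation_id = 1:6,
    onset_ms = seq(0, 2500, by = 500), offset_ms = seq(300, 2800, by = 500),
    duration_ms = 300,
    x = c(10, 10, -10, 10, -10, 10),
    y = c(7, -7, 7, -7, 7, 7),
    mean_pupil = 100, microsaccade_count = 0L,
    microsaccade_peak_velocity = NA_real_)
  fx$quadrant <- quadrant_of(lay, fx$x, fx$y)
  expect_equal(fx$quadrant, c("gray", "test2", "adapter", "test2", "adapter", "gray"))
  tr <- extract_pseudo_trials(fx, lay, rf_box = list(offset = c(0, 0),
                                                     half = c(0.5, 0.5)))
  expect_equal(tr$condition, c("unadapt", "adapt"))
  expect_equal(tr$test_stimulus, c("test2", "test2"))
})

test_that("a gray-then-test1 sequence labels exactly one unadapted trial", {
  lay <- quadrant_layout()
  fx <- tibble::tibble(fixation_id = 1:2, onset_ms = c(0, 400),
                       offset_ms = c(300, 700), duration_ms = c(300, 300),
                       x = c(10, -10), y = c(7, -7), mean_pupil = 1,
                       microsaccade_count = 0L,
                       microsaccade_peak_velocity = NA_real_)
  fx$quadrant <- quadrant_of(lay, fx$x, fx$y)
  tr <- extract_pseudo_trials(fx, lay, rf_box = list(offset = c(0, 0),
                                                     half = c(0.5, 0.5)))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$condition, "unadapt")
  expect_equal(tr$test_stimulus, "test1")
})

test_that("a test fixation whose RF region straddles a boundary is excluded", {
  lay <- quadrant_layout()
  fx <- tibble::tibble(fixation_id = 1:2, onset_ms = c(0, 400),
                       offset_ms = c(300, 700), duration_ms = c(300, 300),
                       x = c(10, -1.5), y = c(7, -7), mean_pupil = 1,
                       microsaccade_count = 0L,
                       microsaccade_peak_velocity = NA_real_)
  fx$quadrant <- quadrant_of(lay, fx$x, fx$y)
  # rf box centered 1.5 deg right of gaze spans the vertical midline
  tr <- extract_pseudo_trials(fx, lay, rf_box = list(offset = c(1.5, 0),
                                                     half = c(1, 1)))
  expect_equal(nrow(tr), 0L)
})

test_that("trial extraction matches a hand-coded enumeration over the label sequence", {
  es <- generate_eye_trace(eye_trace_config(duration_s = 60, seed = 12))
  fx <- detect_fixations(es)
  rf <- list(offset = c(0, 0), half = c(0.1, 0.1))
  tr <- extract_pseudo_trials(fx, es$layout, rf)
  # oracle: scan consecutive quadrant pairs directly
  q <- fx$quadrant
  conf <- crossadapt:::rf_confined(es$layout, fx$x, fx$y, rf)
  expected <- 0
  for (i in seq_len(length(q) - 1)) {
    if (q[i] %in% c("gray", "adapter") && q[i + 1] %in% c("test1", "test2") &&
        conf[i + 1]) expected <- expected + 1
  }
  expect_equal(nrow(tr), expected)
})

test_that("covariate comparisons are near-null when conditions share distributions", {
  set.seed(31)
  n <- 60
  trials <- tibble::tibble(
    trial_id = 1:n,
    condition = rep(c("unadapt", "adapt"), each = n / 2),
    test_stimulus = sample(c("test1", "test2"), n, TRUE),
    adapter_duration_ms = rlnorm(n, log(250), 0.3),
    test_onset_ms = cumsum(rep(500, n)), test_offset_ms = cumsum(rep(500, n)) + 250,
    test_duration_ms = rlnorm(n, log(250), 0.3),
    mean_pupil = rnorm(n, 1000, 30),
    microsaccade_count = rpois(n, 2),
    microsaccade_peak_velocity = runif(n, 20, 60))
  cv <- covariate_comparison(trials)
  expect_equal(nrow(cv), 5L)
  expect_true(all(cv$p_value >= 0 & cv$p_value <= 1))
  # duplicated trials across conditions: the rank-sum statistic sits at its null center
  dup <- trials
  dup$condition <- rep(c("unadapt", "adapt"), times = n / 2)
  dup$adapter_duration_ms <- rep(trials$adapter_duration_ms[1:(n / 2)], each = 2)
  dup$test_duration_ms <- rep(trials$test_duration_ms[1:(n / 2)], each = 2)
  dup$mean_pupil <- rep(trials$mean_pupil[1:(n / 2)], each = 2)
  dup$microsaccade_count <- rep(trials$microsaccade_count[1:(n / 2)], each = 2)
  dup$microsaccade_peak_velocity <- rep(trials$microsaccade_peak_velocity[1:(n / 2)], each = 2)
  cv2 <- covariate_comparison(dup)
  expect_true(all(cv2$p_value[cv2$group1 == "unadapt"] > 0.9))
})

test_that("null covariates reject at about the nominal rate over repeats", {
  set.seed(77)
  rej <- replicate(200, {
    v1 <- rnorm(25); v2 <- rnorm(25)
    suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE)$p.value) < 0.05
  })
  ci <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * ci)
})

test_that("an injected duration shift is detected with power growing in n", {
  set.seed(55)
  power <- vapply(c(20, 120), function(n) {
    mean(replicate(60, {
      trials <- tibble::tibble(
        trial_id = 1:(2 * n),
        condition = rep(c("unadapt", "adapt"), each = n),
        test_stimulus = "test1",
        adapter_duration_ms = 250,
        test_onset_ms = 0, test_offset_ms = 1,
        test_duration_ms = c(rlnorm(n, log(250), 0.3), rlnorm(n, log(300), 0.3)),
        mean_pupil = 1, microsaccade_count = 0L,
        microsaccade_peak_velocity = NA_real_)
      cv <- suppressWarnings(covariate_comparison(trials))
      cv$p_value[cv$covariate == "test_duration_ms"] < 0.05
    }))
  }, numeric(1))
  expect_gt(power[2], power[1])
  expect_gt(power[2], 0.8)
})
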