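test_that("a duplicated neuron has unit noise correlation", {
  pop <- generate_population(population_config(n_neurons = 5,
                                               baseline_rate = 20, seed = 2))
  tbl <- pop$unadapt
  tbl$neuron_6 <- tbl$neuron_1
  attr(tbl, "window_ms") <- 200
  nc <- noise_correlations(tbl)
  expect_equal(nc$matrix["neuron_1", "neuron_6"], 1, tolerance = 1e-12)
})

test_that("independent neurons have near-zero mean noise correlation", {
  pop <- generate_population(population_config(
    n_neurons = 30, n_trials_per_stimulus = 200, stimulus_angles = c(45, 67.5),
    fraction_untuned = 1, shared_sd = 0, baseline_rate = 20, seed = 5))
  nc <- noise_correlations(pop$unadapt)
  expect_lt(abs(nc$mean_rsc), 2 / sqrt(200))
})

test_that("noise correlations equal a direct two-pass Pearson oracle on included trials", {
  pop <- generate_population(population_config(n_neurons = 8,
                                               baseline_rate = 25, seed = 7))
  tbl <- pop$unadapt
  nc <- noise_correlations(tbl, min_peak_rate = 0, z_max = 3)
  rates <- counts_matrix(tbl) / 0.2
  ang <- tbl$stimulus_angle_deg
  for (pair in list(c(1, 2), c(3, 8), c(4, 6))) {
    rs <- c()
    for (a in sort(unique(ang))) {
      x <- rates[ang == a, pair[1]]; y <- rates[ang == a, pair[2]]
      zx <- (x - mean(x)) / sd(x); zy <- (y - mean(y)) / sd(y)
      keep <- abs(zx) <= 3 & abs(zy) <= 3
      rs <- c(rs, pearson_oracle(x[keep], y[keep]))
    }
    expect_equal(nc$matrix[pair[1], pair[2]], mean(rs), tolerance = 1e-12)
  }
})

test_that("the noise-correlation matrix is symmetric with unit diagonal", {
  pop <- generate_population(population_config(n_neurons = 10, seed = 3))
  nc <- noise_correlations(pop$unadapt)
  expect_equal(nc$matrix, t(nc$matrix))
  expect_equal(unname(diag(nc$matrix)), rep(1, nrow(nc$matrix)))
  # low-rate neurons are excluded
  pop2 <- generate_population(population_config(n_neurons = 6,
                                                baseline_rate = 1,
                                                tuning_amplitude = 1,
                                                shared_sd = 0, private_sd = 0.5,
                                                seed = 4))
  expect_error(noise_correlations(pop2$unadapt), class = "crossadapt_input_error")
})

test_that("identical conditions give every PC variance ratio exactly 1", {
  pop <- generate_population(population_config(n_neurons = 15, seed = 6))
  pc <- pc_variance_ratio(pop$unadapt, pop$unadapt, n_reps = 10, seed = 1)
  expect_equal(unname(pc$ratios), rep(1, length(pc$ratios)), tolerance = 1e-9)
  expect_equal(pc$mean_ratio, 1, tolerance = 1e-9)
  expect_equal(pc$resample_sd, 0, tolerance = 1e-9)
})

test_that("the leading-PC ratio approaches the closed-form covariance ratio", {
  # one dominant shared dimension, shrink 0.5; oracle from the generator's
  # returned loadings: top-eigenvalue ratio of s^2*144*LL' + diag
  cfg <- population_config(n_neurons = 20, n_trials_per_stimulus = 300,
                           stimulus_angles = c(45, 67.5), fraction_untuned = 1,
                           adapt_kappa_boost = 0, adapt_gain = 1,
                           shared_dims = 1, shared_sd = 12, private_sd = 1,
                           adapt_shared_shrink = 0.5, window_ms = 1000, seed = 8)
  pop <- generate_population(cfg)
  lam <- function(s) max(eigen(s^2 * 144 * tcrossprod(pop$loadings) +
                                 diag(1, 20), symmetric = TRUE,
                               only.values = TRUE)$values)
  expected <- lam(1) / lam(0.5)
  pc <- pc_variance_ratio(pop$unadapt, pop$adapt, n_reps = 20, seed = 2)
  expect_lt(abs(pc$ratios[1] / expected - 1), 0.2)
})

test_that("swapping condition roles inverts each ratio on a fixed basis", {
  set.seed(9)
  U <- matrix(rnorm(200 * 6), 200, 6) %*% diag(c(3, 2, 1.5, 1, 1, 0.5))
  A <- matrix(rnorm(200 * 6), 200, 6)
  basis <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  r1 <- crossadapt:::project_variance(U, basis) /
    crossadapt:::project_variance(A, basis)
  r2 <- crossadapt:::project_variance(A, basis) /
    crossadapt:::project_variance(U, basis)
  expect_equal(r1, 1 / r2, tolerance = 1e-12)
})

test_that("pc_variance_ratio is invariant to trial order", {
  pop <- generate_population(population_config(n_neurons = 10, seed = 12))
  pc1 <- pc_variance_ratio(pop$unadapt, pop$adapt, n_reps = 5, seed = 3)
  shuf <- pop$unadapt[sample(nrow(pop$unadapt)), ]
  pc2 <- pc_variance_ratio(shuf, pop$adapt, n_reps = 5, seed = 3)
  expect_equal(pc1$ratios, pc2$ratios, tolerance = 1e-9)
})

test_that("equal-covariance conditions give mean ratio near 1 at large trial counts", {
  cfg <- population_config(n_neurons = 8, n_trials_per_stimulus = 400,
                           stimulus_angles = color_angles[1:4],
                           fraction_untuned = 1, adapt_kappa_boost = 0,
                           adapt_gain = 1, adapt_shared_shrink = 1, seed = 14)
  pop <- generate_population(cfg)
  pc <- pc_variance_ratio(pop$unadapt, pop$adapt, n_reps = 30, seed = 4)
  expect_lt(abs(pc$mean_ratio - 1), 0.05)
})

test_that("the decoder saturates for widely separated classes and matches MASS::lda when well conditioned", {
  pop <- generate_population(population_config(
    n_neurons = 20, n_trials_per_stimulus = 60, stimulus_angles = c(0, 180),
    tuning_concentration = 3, fraction_untuned = 0, tuning_amplitude = 60,
    private_sd = 3, shared_sd = 3, seed = 15))
  d <- lda_decode(pop$unadapt, n_iterations = 50, seed = 1)
  expect_gt(d$accuracy_above_chance, 45)
  # cross-check the discriminant machinery against MASS on easy data
  skip_if_not_installed("MASS")
  X <- counts_matrix(pop$unadapt)
  y <- factor(pop$unadapt$stimulus_angle_deg)
  fit <- MASS::lda(X, y)
  pred <- stats::predict(fit, X)$class
  ours <- crossadapt:::lda_fit_predict(X, y == levels(y)[2], X)
  expect_gt(mean((pred == levels(y)[2]) == ours), 0.98)
})

test_that("decoding requires two classes with enough trials", {
  pop <- null_two_class_population(n_neurons = 5, n_trials = 5, seed = 2)
  expect_error(lda_decode(pop$unadapt), class = "crossadapt_input_error")
  one <- pop$unadapt[pop$unadapt$stimulus_angle_deg == 45, ]
  expect_error(lda_decode(one), class = "crossadapt_input_error")
})

test_that("decoder accuracy is invariant to a common invertible affine transform", {
  pop <- generate_population(population_config(
    n_neurons = 10, n_trials_per_stimulus = 40, stimulus_angles = c(45, 67.5),
    tuning_concentration = 2, fraction_untuned = 0, seed = 16))
  tbl <- pop$unadapt
  d1 <- lda_decode(tbl, n_iterations = 40, seed = 5)
  X <- counts_matrix(tbl)
  set.seed(99)
  A <- diag(10) + 0.1 * matrix(rnorm(100), 10, 10)
  X2 <- X %*% A + 3
  tbl2 <- dplyr::bind_cols(tbl[1:3], tibble::as_tibble(`colnames<-`(X2, colnames(X))))
  d2 <- lda_decode(tbl2, n_iterations = 40, seed = 5)
  expect_lt(abs(d1$mean_accuracy - d2$mean_accuracy), 5)
})

test_that("reduced shared variability improves decoding on average across seeds", {
  deltas <- vapply(1:8, function(s) {
    pop <- generate_population(population_config(
      adapt_kappa_boost = 0, adapt_gain = 1, adapt_shared_shrink = 0.6,
      stimulus_angles = c(45, 67.5), n_trials_per_stimulus = 100, seed = s))
    du <- lda_decode(pop$unadapt, n_iterations = 50, seed = s)
    da <- lda_decode(pop$adapt, n_iterations = 50, seed = s)
    da$accuracy_above_chance - du$accuracy_above_chance
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("tidy and glance methods return the documented shapes", {
  pop <- generate_population(population_config(n_neurons = 10, seed = 17))
  pc <- pc_variance_ratio(pop$unadapt, pop$adapt, n_reps = 5, seed = 1)
  td <- tidy(pc)
  expect_true(all(c("pc", "ratio", "leading") %in% names(td)))
  expect_equal(nrow(glance(pc)), 1L)
  d <- lda_decode(pop$unadapt, stimulus_pair = c(45, 67.5),
                  n_iterations = 20, seed = 1)
  expect_equal(nrow(tidy(d)), 20L)
  expect_equal(glance(d)$n_iterations, 20L)
  nc <- noise_correlations(pop$unadapt)
  expect_true(all(c("neuron_i", "neuron_j", "r_sc") %in% names(tidy(nc))))
  expect_equal(nrow(glance(nc)), 1L)
})
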