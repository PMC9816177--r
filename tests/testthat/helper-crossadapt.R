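# shared fixture builders (all fixtures are generated in code)

color_angles <- seq(0, 337.5, by = 22.5)
orientation_angles <- seq(0, 168.75, by = 11.25)

# uniform RGB patch
uniform_rgb <- function(r, g, b, size = 50) {
  out <- array(0, c(size, size, 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

# achromatic sinusoidal grating whose brightness varies along `angle_deg`,
# i.e. whose Sobel orientation equals `angle_deg`
grating_rgb <- function(angle_deg, size = 50, period = 12, contrast = 0.8,
                        phase = 0) {
  a <- angle_deg * pi / 180
  g <- outer(seq_len(size), seq_len(size), function(r, c) {
    128 + contrast * 127 * sin(2 * pi / period * (c * cos(a) + r * sin(a)) + phase)
  })
  array(rep(g, 3), c(size, size, 3))
}

# independent oracle: direct two-pass Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# independent oracle: brute-force Holm step-down decisions at level alpha
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    i <- ord[k]
    if (p[i] <= alpha / (m - k + 1)) reject[i] <- TRUE else break
  }
  reject
}

# small two-stimulus null population: identical response distributions
# (independent neurons: the cleanest null for decoder calibration)
null_two_class_population <- function(n_neurons = 30, n_trials = 200, seed = 1) {
  generate_population(population_config(
    n_neurons = n_neurons, n_trials_per_stimulus = n_trials,
    stimulus_angles = c(45, 67.5), fraction_untuned = 1,
    adapt_kappa_boost = 0, adapt_gain = 1, adapt_shared_shrink = 1,
    shared_sd = 0, seed = seed))
}
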