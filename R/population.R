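#' Pairwise spike-count (noise) correlations
#'
#' Pearson correlations of trial-to-trial spike counts between pairs of
#' simultaneously recorded neurons at fixed stimulus, averaged across the
#' stimuli of a feature. Neurons with peak firing rates below
#' `min_peak_rate` (default 5 spikes/s) are dropped; within each stimulus,
#' trials in which the absolute z-scored rate of either neuron of a pair
#' exceeds `z_max` are excluded pairwise.
#'
#' @param data Wide trial table for one condition: `stimulus_angle_deg`
#'   plus `neuron_<k>` columns.
#' @param window_ms Analysis window (ms); taken from the table attribute
#'   when `NULL`.
#' @param min_peak_rate Peak-rate inclusion threshold, spikes/s.
#' @param z_max Pairwise trial-exclusion threshold on |z|.
#' @param min_trials Minimum included trials per stimulus for a pair.
#' @return An object of class `ca_noise_corr`: list with `matrix` (average
#'   pairwise correlation over stimuli, unit diagonal), `pairs` (tibble of
#'   upper-triangle pairs with `r_sc` and the number of stimuli
#'   contributing), `mean_rsc`, and `excluded_neurons`.
#' @export
noise_correlations <- function(data, window_ms = NULL, min_peak_rate = 5,
                               z_max = 3, min_trials = 3) {
  window_ms <- window_ms %||% attr(data, "window_ms")
  if (is.null(window_ms)) input_error("`window_ms` not supplied and not an attribute of `data`")
  w_s <- window_ms / 1000
  rates <- counts_matrix(data) / w_s
  angles <- data$stimulus_angle_deg
  uang <- sort(unique(angles))
  # peak rate = max across stimuli of the trial-averaged rate
  peak <- apply(vapply(uang, function(a) colMeans(rates[angles == a, , drop = FALSE]),
                       numeric(ncol(rates))), 1, max)
  keep <- peak >= min_peak_rate
  excluded <- colnames(rates)[!keep]
  rates <- rates[, keep, drop = FALSE]
  p <- ncol(rates)
  if (p < 2L) input_error("fewer than two neurons pass the peak-rate filter")
  acc <- matrix(0, p, p); nacc <- matrix(0L, p, p)
  for (a in uang) {
    x <- rates[angles == a, , drop = FALSE]
    if (nrow(x) < min_trials) next
    z <- scale(x)
    x[!is.na(z) & abs(z) > z_max] <- NA
    ok <- !is.na(x)
    npair <- crossprod(ok)
    cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    good <- is.finite(cc) & npair >= min_trials
    acc[good] <- acc[good] + cc[good]
    nacc[good] <- nacc[good] + 1L
  }
  avg <- ifelse(nacc > 0, acc / nacc, NA_real_)
  diag(avg) <- 1
  dimnames(avg) <- list(colnames(rates), colnames(rates))
  ut <- which(upper.tri(avg), arr.ind = TRUE)
  pairs <- tibble::tibble(
    neuron_i = colnames(rates)[ut[, 1]],
    neuron_j = colnames(rates)[ut[, 2]],
    r_sc = avg[ut],
    n_stimuli = nacc[ut]
  )
  structure(list(matrix = avg, pairs = pairs,
                 mean_rsc = mean(pairs$r_sc, na.rm = TRUE),
                 excluded_neurons = excluded),
            class = "ca_noise_corr")
}

#' @export
print.ca_noise_corr <- function(x, ...) {
  cat(sprintf("Noise correlations: %d neurons, %d pairs, mean r_sc = %.4f\n",
              nrow(x$matrix), nrow(x$pairs), x$mean_rsc))
  invisible(x)
}

# variance of the projections of each (own-mean-centered) condition on a basis
project_variance <- function(X, basis) {
  Xc <- sweep(X, 2, colMeans(X))
  proj <- Xc %*% basis
  apply(proj, 2, stats::var)
}

pc_ratio_once <- function(U, A, var_fraction) {
  Uc <- sweep(U, 2, colMeans(U))
  pr <- stats::prcomp(Uc, center = FALSE)
  var_u <- project_variance(U, pr$rotation)
  var_a <- project_variance(A, pr$rotation)
  cum <- cumsum(var_u) / sum(var_u)
  n90 <- which(cum >= var_fraction)[1]
  ratios <- var_u / var_a
  list(ratios = ratios, n90 = n90, mean_ratio = mean(ratios[seq_len(n90)]),
       var_u = var_u)
}

#' Projected principal-component variance ratio between conditions
#'
#' Quantifies the decorrelation of trial-by-trial population activity under
#' adaptation. Principal components are fitted to the unadapted
#' trials-by-neurons matrix; both conditions are then projected onto those
#' axes and the per-axis ratio of explained variance
#' (unadapted / adapted) is computed. The summary statistic is the mean
#' ratio over the leading components capturing `var_fraction` (default
#' 90\%) of the unadapted variance; a mean ratio above 1 indicates reduced
#' shared variability (decorrelation) after adaptation. The analysis is
#' repeated `n_reps` times on subsampled trials to obtain a resampling
#' s.d.; each condition is centered by its own per-neuron means so the
#' ratio reflects variance structure rather than mean-rate changes.
#'
#' Neurons whose unadapted response variance exceeds the across-neuron mean
#' by more than two standard deviations are removed so that single
#' high-variance outliers do not dominate the principal components.
#'
#' @param unadapt,adapt Wide trial tables (same neurons, same order) for
#'   the two conditions.
#' @param var_fraction Fraction of unadapted variance the leading
#'   components must capture.
#' @param n_reps Number of subsampled repeats for the error estimate.
#' @param subsample_frac Fraction of the smaller condition's trials used in
#'   each repeat. When both conditions have equal trial counts the same
#'   subsample indices are used in both, so identical inputs give a ratio
#'   of exactly 1 on every axis.
#' @param seed Optional seed for the subsampling.
#' @return An object of class `ca_pc_ratio`: list with `ratios` (full-data
#'   per-axis ratios), `n_pcs_90`, `mean_ratio` (mean over repeats),
#'   `resample_sd`, `rep_means`, `p_value` (one-sided Wilcoxon signed-rank
#'   test of the leading ratios against 1), `var_explained`, and
#'   `dropped_neurons`.
#' @export
pc_variance_ratio <- function(unadapt, adapt, var_fraction = 0.9,
                              n_reps = 100, subsample_frac = 0.8,
                              seed = NULL) {
  U <- counts_matrix(unadapt); A <- counts_matrix(adapt)
  if (!identical(colnames(U), colnames(A))) {
    input_error("`unadapt` and `adapt` must contain the same neurons in the same order")
  }
  v <- apply(U, 2, stats::var)
  drop <- v > mean(v) + 2 * stats::sd(v)
  drop[is.na(drop)] <- FALSE
  dropped <- colnames(U)[drop]
  U <- U[, !drop, drop = FALSE]; A <- A[, !drop, drop = FALSE]
  nU <- nrow(U); nA <- nrow(A)
  n_min <- min(nU, nA)
  n_sub <- max(3L, floor(subsample_frac * n_min))
  if (n_sub <= ncol(U)) {
    rlang::warn("fewer subsampled trials than neurons; principal components limited by trial count")
  }
  full <- pc_ratio_once(U, A, var_fraction)
  rep_means <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      iu <- sample.int(nU, n_sub)
      ia <- if (nU == nA) iu else sample.int(nA, n_sub)
      pc_ratio_once(U[iu, , drop = FALSE], A[ia, , drop = FALSE], var_fraction)$mean_ratio
    }, numeric(1))
  })
  lead <- full$ratios[seq_len(full$n90)]
  p <- if (length(lead) >= 1 && stats::sd(lead) > 0) {
    suppressWarnings(stats::wilcox.test(lead, mu = 1, alternative = "greater")$p.value)
  } else if (all(lead == 1)) 1 else NA_real_
  structure(list(ratios = full$ratios, n_pcs_90 = full$n90,
                 mean_ratio = mean(rep_means), resample_sd = stats::sd(rep_means),
                 rep_means = rep_means, mean_ratio_full = full$mean_ratio,
                 p_value = p,
                 var_explained = full$var_u / sum(full$var_u),
                 var_fraction = var_fraction, n_reps = n_reps,
                 dropped_neurons = dropped),
            class = "ca_pc_ratio")
}

#' @export
print.ca_pc_ratio <- function(x, ...) {
  cat(sprintf(paste0("Projected-PC variance ratio (unadapt/adapt): mean = %.4f ",
                     "(+/- %.4f over %d subsampled repeats), %d PCs capture %.0f%% variance\n"),
              x$mean_ratio, x$resample_sd, x$n_reps, x$n_pcs_90,
              100 * x$var_fraction))
  invisible(x)
}

# Ledoit-Wolf shrinkage of a covariance matrix toward scaled identity,
# estimated from rows already centered (class means removed)
lw_cov <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 <= 0) return(S + diag(1e-8 * max(mu, 1), p))
  xs <- rowSums(Xc^2)
  cross <- rowSums((Xc %*% S) * Xc)
  b2bar <- (sum(xs^2) - 2 * sum(cross) + n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2bar, d2)
  rho <- b2 / d2
  (1 - rho) * S + rho * diag(mu, p) + diag(1e-8 * max(mu, 1), p)
}

lda_fit_predict <- function(Xtr, ytr, Xte) {
  m0 <- colMeans(Xtr[!ytr, , drop = FALSE])
  m1 <- colMeans(Xtr[ytr, , drop = FALSE])
  Xc <- Xtr
  Xc[!ytr, ] <- sweep(Xtr[!ytr, , drop = FALSE], 2, m0)
  Xc[ytr, ] <- sweep(Xtr[ytr, , drop = FALSE], 2, m1)
  S <- lw_cov(Xc)
  w <- solve(S, m1 - m0)
  thr <- sum(w * (m1 + m0)) / 2
  as.vector(Xte %*% w) > thr
}

#' Cross-validated linear-discriminant decoding of a stimulus pair
#'
#' Trains a linear discriminant (pooled covariance with Ledoit-Wolf
#' shrinkage toward scaled identity, so sessions with more neurons than
#' trials remain well conditioned) to classify two neighbouring stimuli
#' from population spike counts. Each iteration draws a stratified random
#' 70/30 train/test split; accuracy is averaged over `n_iterations`
#' repeats and reported above the 50\% chance level. The standard error
#' uses the Nadeau-Bengio correction for the overlap of repeated random
#' splits, `sd * sqrt(1/K + n_test/n_train)`.
#'
#' @param data Wide trial table; rows are trials of the two stimuli.
#' @param stimulus_pair Length-2 vector of `stimulus_angle_deg` values to
#'   decode; `NULL` uses the two angles present in `data`.
#' @param train_fraction Fraction of trials per class used for training.
#' @param n_iterations Number of random splits.
#' @param seed Optional seed for the splits.
#' @return An object of class `ca_decoder`: list with `accuracies`
#'   (percent, per iteration), `mean_accuracy`, `accuracy_above_chance`,
#'   `se`, `chance = 50`, and split sizes.
#' @export
lda_decode <- function(data, stimulus_pair = NULL, train_fraction = 0.7,
                       n_iterations = 500, seed = NULL) {
  if (!is.null(stimulus_pair)) {
    data <- data[data$stimulus_angle_deg %in% stimulus_pair, , drop = FALSE]
  }
  labs <- sort(unique(data$stimulus_angle_deg))
  if (length(labs) != 2L) input_error("decoding requires exactly two stimulus classes")
  X <- counts_matrix(data)
  y <- data$stimulus_angle_deg == labs[2]
  n0 <- sum(!y); n1 <- sum(y)
  if (min(n0, n1) < 10L) input_error("need at least 10 trials per class")
  ntr0 <- floor(train_fraction * n0); ntr1 <- floor(train_fraction * n1)
  idx0 <- which(!y); idx1 <- which(y)
  acc <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(k) {
      tr <- c(sample(idx0, ntr0), sample(idx1, ntr1))
      te <- setdiff(seq_along(y), tr)
      pred <- lda_fit_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
      mean(pred == y[te]) * 100
    }, numeric(1))
  })
  n_test <- (n0 - ntr0) + (n1 - ntr1)
  se <- stats::sd(acc) * sqrt(1 / n_iterations + n_test / (ntr0 + ntr1))
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 accuracy_above_chance = mean(acc) - 50, se = se,
                 chance = 50, train_fraction = train_fraction,
                 n_iterations = n_iterations, n_train = ntr0 + ntr1,
                 n_test = n_test, stimulus_pair = labs),
            class = "ca_decoder")
}

#' @export
print.ca_decoder <- function(x, ...) {
  cat(sprintf(paste0("LDA decoder (%g vs %g deg): accuracy %.2f%% ",
                     "(%.2f%% above chance, s.e. %.2f, %d iterations)\n"),
              x$stimulus_pair[1], x$stimulus_pair[2], x$mean_accuracy,
              x$accuracy_above_chance, x$se, x$n_iterations))
  invisible(x)
}
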