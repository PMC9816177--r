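#' Tidy a projected-PC variance-ratio result
#'
#' @param x A `ca_pc_ratio` from [pc_variance_ratio()].
#' @param ... Unused.
#' @return Tibble with one row per principal component: `pc`, `ratio`
#'   (unadapt/adapt variance along the axis), `var_explained`
#'   (unadapted), `cum_var_explained`, and `leading` (whether the axis
#'   belongs to the set capturing the target variance fraction).
#' @export
tidy.ca_pc_ratio <- function(x, ...) {
  tibble::tibble(
    pc = seq_along(x$ratios),
    ratio = x$ratios,
    var_explained = x$var_explained,
    cum_var_explained = cumsum(x$var_explained),
    leading = seq_along(x$ratios) <= x$n_pcs_90
  )
}

#' @rdname tidy.ca_pc_ratio
#' @export
glance.ca_pc_ratio <- function(x, ...) {
  tibble::tibble(mean_ratio = x$mean_ratio, resample_sd = x$resample_sd,
                 n_pcs_90 = x$n_pcs_90, p_value = x$p_value,
                 n_reps = x$n_reps)
}

#' Tidy a decoder result
#'
#' @param x A `ca_decoder` from [lda_decode()].
#' @param ... Unused.
#' @return `tidy()`: one row per train/test iteration with `iteration`
#'   and `accuracy` (percent). `glance()`: one-row summary.
#' @export
tidy.ca_decoder <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' @rdname tidy.ca_decoder
#' @export
glance.ca_decoder <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 accuracy_above_chance = x$accuracy_above_chance,
                 se = x$se, chance = x$chance,
                 n_iterations = x$n_iterations,
                 n_train = x$n_train, n_test = x$n_test)
}

#' Tidy a noise-correlation result
#'
#' @param x A `ca_noise_corr` from [noise_correlations()].
#' @param ... Unused.
#' @return `tidy()`: one row per neuron pair. `glance()`: one-row
#'   summary.
#' @export
tidy.ca_noise_corr <- function(x, ...) x$pairs

#' @rdname tidy.ca_noise_corr
#' @export
glance.ca_noise_corr <- function(x, ...) {
  tibble::tibble(mean_rsc = x$mean_rsc, n_pairs = nrow(x$pairs),
                 n_neurons = nrow(x$matrix),
                 n_excluded = length(x$excluded_neurons))
}

#' One-row summary of a session report
#'
#' @param x A `ca_session_report` from [run_fixation()],
#'   [run_freeview()] or [run_scenes()].
#' @param ... Unused.
#' @return The report's `summary` tibble.
#' @export
glance.ca_session_report <- function(x, ...) x$summary
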