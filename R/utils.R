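deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

config_error <- function(msg) rlang::abort(msg, class = "crossadapt_config_error")
input_error <- function(msg) rlang::abort(msg, class = "crossadapt_input_error")

#' Evaluate code with a temporarily seeded random number generator
#'
#' Seeds the RNG for the duration of `code` and restores the previous RNG
#' state afterwards, so that seeded generators do not disturb the caller's
#' random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# columns holding per-neuron spike counts in a wide trial table
neuron_cols <- function(data) grep("^neuron_", names(data), value = TRUE)

#' Extract the trials-by-neurons count matrix from a trial table
#'
#' @param data A wide trial table with `neuron_<k>` columns.
#' @return Numeric matrix, one row per trial, one column per neuron.
#' @export
counts_matrix <- function(data) {
  cols <- neuron_cols(data)
  if (length(cols) == 0L) input_error("no `neuron_<k>` columns found in trial table")
  as.matrix(data[cols])
}

# centered moving average with truncated edges (window must be odd)
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# signed circular difference a - b mapped into (-period/2, period/2]
circ_diff_deg <- function(a, b, period = 360) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}
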