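#' Fit an empirical saccade amplitude/direction model
#'
#' Bins observed saccade amplitudes (0.5-degree bins) and directions
#' (10-degree bins over `[0, 360)`) into normalized histograms. Sampling
#' draws a bin proportionally to its mass, then uniformly within the bin.
#'
#' @param saccades Data frame with columns `amplitude_deg` and
#'   `direction_deg`.
#' @param amplitude_bin,direction_bin Bin widths, degrees.
#' @return Object of class `ca_saccade_model`.
#' @export
fit_saccade_model <- function(saccades, amplitude_bin = 0.5, direction_bin = 10) {
  if (is.null(saccades) || nrow(saccades) < 1L) {
    rlang::abort("at least one saccade is required to fit the model",
                 class = "crossadapt_estimation_error")
  }
  amp <- saccades$amplitude_deg
  dir <- saccades$direction_deg %% 360
  if (any(amp < 0)) input_error("amplitudes must be non-negative")
  amp_breaks <- seq(0, (max(amp) %/% amplitude_bin + 1) * amplitude_bin,
                    by = amplitude_bin)
  amp_counts <- tabulate(pmin(findInterval(amp, amp_breaks, left.open = FALSE),
                              length(amp_breaks) - 1L),
                         nbins = length(amp_breaks) - 1L)
  dir_breaks <- seq(0, 360, by = direction_bin)
  dir_counts <- tabulate(pmin(floor(dir / direction_bin) + 1L,
                              length(dir_breaks) - 1L),
                         nbins = length(dir_breaks) - 1L)
  structure(list(amplitude_breaks = amp_breaks,
                 amplitude_prob = amp_counts / sum(amp_counts),
                 direction_breaks = dir_breaks,
                 direction_prob = dir_counts / sum(dir_counts),
                 n = nrow(saccades)),
            class = "ca_saccade_model")
}

#' Sample saccades from a fitted model
#'
#' @param model A [fit_saccade_model()].
#' @param n Number of saccades.
#' @param seed Optional seed.
#' @return Tibble with `amplitude_deg` and `direction_deg`.
#' @export
sample_saccades <- function(model, n, seed = NULL) {
  with_seed(seed, {
    bi <- sample.int(length(model$amplitude_prob), n, replace = TRUE,
                     prob = model$amplitude_prob)
    amp <- stats::runif(n, model$amplitude_breaks[bi], model$amplitude_breaks[bi + 1])
    bj <- sample.int(length(model$direction_prob), n, replace = TRUE,
                     prob = model$direction_prob)
    dir <- stats::runif(n, model$direction_breaks[bj], model$direction_breaks[bj + 1])
    tibble::tibble(amplitude_deg = amp, direction_deg = dir)
  })
}

#' Simulate a scanpath over an image and label the fixated patches
#'
#' Generates `n_saccades` consecutive pseudo-saccades from a random (or
#' given) starting point: each saccade samples amplitude and direction
#' independently from the model; landing points outside the image are
#' re-sampled (up to `max_retries`, then clipped to the image). Each
#' fixation's patch (side `patch_size`, matched to the mean receptive
#' field size) is classified as oriented/colored/neither — either directly
#' with [classify_patch()], or, when `feature_grid` (a [feature_map()] of
#' the image) is supplied, by looking up the nearest window of the grid.
#'
#' @param image H x W x 3 array (or brightness matrix).
#' @param model A [fit_saccade_model()].
#' @param n_saccades Number of saccades; a scanpath has `n_saccades + 1`
#'   fixations.
#' @param start `"random"` or `c(x, y)` pixel coordinates.
#' @param deg_to_px Pixels per degree of visual angle.
#' @param patch_size Side of the classified patch, pixels.
#' @inheritParams classify_patch
#' @param feature_grid Optional precomputed [feature_map()] for fast
#'   label lookup.
#' @param seed Optional seed.
#' @param max_retries Re-sampling attempts for out-of-bounds landings.
#' @return Tibble of class `ca_scanpath` with `fixation_id`, `x`, `y`
#'   (pixels; x = column, y = row) and `label`.
#' @export
simulate_scanpath <- function(image, model, n_saccades = 300,
                              start = "random", deg_to_px = 10,
                              patch_size = 50, criteria = color_criteria(),
                              p_threshold = 0.05, feature_grid = NULL,
                              seed = NULL, max_retries = 20) {
  dm <- dim(image)
  h <- dm[1]; w <- dm[2]
  if (h < 3 || w < 3) config_error("image extent is degenerate")
  with_seed(seed, {
    xs <- numeric(n_saccades + 1); ys <- numeric(n_saccades + 1)
    if (identical(start, "random")) {
      xs[1] <- stats::runif(1, 1, w); ys[1] <- stats::runif(1, 1, h)
    } else {
      xs[1] <- start[1]; ys[1] <- start[2]
    }
    if (n_saccades > 0) {
      # buffered sampling: one vectorized draw feeds the whole walk
      buf <- sample_saccades(model, max(2L * n_saccades, 64L))
      bi <- 0L
      next_sac <- function() {
        bi <<- bi + 1L
        if (bi > nrow(buf)) {
          buf <<- sample_saccades(model, nrow(buf))
          bi <<- 1L
        }
        c(buf$amplitude_deg[bi], buf$direction_deg[bi])
      }
      for (k in seq_len(n_saccades)) {
        for (try in seq_len(max_retries + 1L)) {
          s <- next_sac()
          nx <- xs[k] + s[1] * deg_to_px * cos(deg2rad(s[2]))
          ny <- ys[k] + s[1] * deg_to_px * sin(deg2rad(s[2]))
          if (nx >= 1 && nx <= w && ny >= 1 && ny <= h) break
        }
        xs[k + 1] <- min(max(nx, 1), w)
        ys[k + 1] <- min(max(ny, 1), h)
      }
    }
    labels <- if (!is.null(feature_grid)) {
      stride <- attr(feature_grid, "stride")
      nr <- max(feature_grid$win_row); nc <- max(feature_grid$win_col)
      c1r <- feature_grid$center_row[1]; c1c <- feature_grid$center_col[1]
      ri <- pmin(pmax(round((ys - c1r) / stride) + 1, 1), nr)
      ci <- pmin(pmax(round((xs - c1c) / stride) + 1, 1), nc)
      feature_grid$label[match(paste(ri, ci), paste(feature_grid$win_row, feature_grid$win_col))]
    } else {
      half <- patch_size %/% 2
      vapply(seq_along(xs), function(k) {
        r0 <- min(max(round(ys[k]) - half, 1), h - patch_size + 1)
        c0 <- min(max(round(xs[k]) - half, 1), w - patch_size + 1)
        rows <- r0:(r0 + patch_size - 1); cols <- c0:(c0 + patch_size - 1)
        patch <- if (length(dm) == 3L) image[rows, cols, , drop = FALSE] else image[rows, cols]
        classify_patch(patch, criteria, p_threshold)
      }, character(1))
    }
    out <- tibble::tibble(fixation_id = seq_along(xs), x = xs, y = ys,
                          label = labels)
    class(out) <- c("ca_scanpath", class(out))
    out
  })
}

#' Saccade transitions of a scanpath
#'
#' @param scanpath A [simulate_scanpath()] result.
#' @return Tibble with `from` and `to` patch labels, one row per saccade.
#' @export
scanpath_transitions <- function(scanpath) {
  n <- nrow(scanpath)
  if (n < 2L) return(tibble::tibble(from = character(), to = character()))
  tibble::tibble(from = scanpath$label[-n], to = scanpath$label[-1])
}

tally_transitions <- function(from, to) {
  feat <- c("oriented", "colored")
  is_feat <- from %in% feat & to %in% feat
  n_iso <- sum(is_feat & from == to)
  n_cross <- sum(is_feat & from != to)
  n_other <- sum(!is_feat)
  c(n_transitions = length(from), n_iso = n_iso, n_cross = n_cross,
    n_other = n_other)
}

#' Iso- versus cross-feature saccade fractions
#'
#' Tallies, per scanpath and pooled, the saccade transitions between
#' classified patches: cross-feature (colored -> oriented or oriented ->
#' colored), iso-feature (colored -> colored or oriented -> oriented),
#' and other (any transition touching a `"neither"` patch). Percentages
#' are reported over all transitions, and the cross-feature percentage is
#' additionally reported over feature-to-feature transitions only (the
#' two candidate denominators).
#'
#' @param scanpaths A single scanpath, a list of scanpaths, or a tibble
#'   with a `scanpath_id` column plus `label` per fixation in order.
#' @return List of class `ca_transition_summary` with `by_scanpath`
#'   (tibble) and `pooled` (one-row tibble with counts and percentages).
#' @export
cross_feature_fraction <- function(scanpaths) {
  if (inherits(scanpaths, "ca_scanpath")) scanpaths <- list(scanpaths)
  if (is.data.frame(scanpaths)) {
    scanpaths <- split(scanpaths, scanpaths$scanpath_id)
  }
  rows <- purrr::imap(scanpaths, function(sp, id) {
    tr <- scanpath_transitions(sp)
    cnt <- tally_transitions(tr$from, tr$to)
    tibble::tibble(scanpath_id = as.character(id), !!!as.list(cnt))
  }) |> purrr::list_rbind()
  pooled_counts <- colSums(rows[c("n_transitions", "n_iso", "n_cross", "n_other")])
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  add_pct <- function(df) {
    dplyr::mutate(df,
      pct_iso = pct(.data$n_iso, .data$n_transitions),
      pct_cross = pct(.data$n_cross, .data$n_transitions),
      pct_other = pct(.data$n_other, .data$n_transitions),
      pct_cross_of_feature = pct(.data$n_cross, .data$n_iso + .data$n_cross))
  }
  by_scanpath <- add_pct(rows)
  pooled <- add_pct(tibble::as_tibble(as.list(pooled_counts)))
  if (pooled$n_transitions == 0) {
    rlang::warn("no saccade transitions; fractions undefined")
  }
  structure(list(by_scanpath = by_scanpath, pooled = pooled),
            class = "ca_transition_summary")
}

#' @export
print.ca_transition_summary <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(paste0("Saccade transitions (n = %d, %d scanpaths): %.1f%% iso-, ",
                     "%.1f%% cross-feature, %.1f%% other\n"),
              p$n_transitions, nrow(x$by_scanpath), p$pct_iso, p$pct_cross,
              p$pct_other))
  invisible(x)
}
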