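#' Configuration for synthetic patch-structured scenes
#'
#' Scenes stand in for natural images: a gray or pink-noise (1/f)
#' background on which non-overlapping square patches are placed — either
#' achromatic sinusoidal gratings (oriented patches) or uniformly coloured
#' fields away from black/white/gray (coloured patches). The ground-truth
#' label, position and parameters of every patch are recorded.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param patch_size Patch side, pixels.
#' @param n_oriented_patches,n_colored_patches Patch counts.
#' @param grating_spatial_period Grating period, pixels.
#' @param grating_orientations Orientations (degrees, `[0, 180)`) sampled
#'   for oriented patches; `NULL` draws uniformly.
#' @param patch_hues List/matrix of RGB triplets (0-255) sampled for
#'   coloured patches.
#' @param background `"gray"` or `"pink-noise"`.
#' @param contrast Grating contrast in `(0, 1]`.
#' @param seed Integer seed.
#' @return List of class `ca_scene_config`.
#' @export
scene_config <- function(image_size = c(240, 240), patch_size = 50,
                         n_oriented_patches = 3, n_colored_patches = 3,
                         grating_spatial_period = 12,
                         grating_orientations = NULL,
                         patch_hues = NULL,
                         background = c("gray", "pink-noise"),
                         contrast = 0.8, seed = 1) {
  background <- match.arg(background)
  if (patch_size > min(image_size)) config_error("patches must fit inside the image")
  if (n_oriented_patches < 0 || n_colored_patches < 0) {
    config_error("patch counts must be non-negative")
  }
  if (is.null(patch_hues)) {
    patch_hues <- rbind(c(200, 60, 60), c(60, 180, 60), c(60, 60, 200),
                        c(200, 160, 40), c(170, 60, 170))
  }
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 n_oriented_patches = as.integer(n_oriented_patches),
                 n_colored_patches = as.integer(n_colored_patches),
                 grating_spatial_period = grating_spatial_period,
                 grating_orientations = grating_orientations,
                 patch_hues = patch_hues, background = background,
                 contrast = contrast, seed = as.integer(seed)),
            class = "ca_scene_config")
}

pink_noise_background <- function(h, w, mean = 128, sd = 15) {
  fr <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fc <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  f <- sqrt(outer(fr^2, rep(1, w)) + outer(rep(1, h), fc^2))
  f[1, 1] <- 1
  spec <- stats::fft(matrix(stats::rnorm(h * w), h, w)) / f
  img <- Re(stats::fft(spec, inverse = TRUE)) / (h * w)
  img <- (img - mean(img)) / stats::sd(img) * sd + mean
  pmin(pmax(img, 0), 255)
}

place_patches <- function(n, size, h, w, occupied, max_tries = 200) {
  placed <- list()
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- sample.int(h - size + 1, 1)
      c0 <- sample.int(w - size + 1, 1)
      cand <- c(r0, c0, r0 + size - 1, c0 + size - 1)
      clash <- any(vapply(occupied, function(o) {
        cand[1] <= o[3] && cand[3] >= o[1] && cand[2] <= o[4] && cand[4] >= o[2]
      }, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      rlang::abort("could not place non-overlapping patches after bounded retries",
                   class = "crossadapt_placement_error")
    }
    occupied[[length(occupied) + 1]] <- cand
    placed[[k]] <- cand
  }
  list(placed = placed, occupied = occupied)
}

#' Generate a synthetic patch-structured scene
#'
#' @param config A [scene_config()].
#' @return List of class `ca_scene` with `image` (H x W x 3 array, values
#'   0-255), `patches` (ground-truth tibble: `patch_id`, `type`, `row0`,
#'   `col0`, `size`, `orientation_deg`, `r`, `g`, `b`), and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "ca_scene_config")) config <- do.call(scene_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    h <- cfg$image_size[1]; w <- cfg$image_size[2]
    bg <- if (cfg$background == "gray") matrix(128, h, w) else pink_noise_background(h, w)
    img <- array(rep(bg, 3), dim = c(h, w, 3))
    # sequential placement can paint itself into a corner; restart the whole
    # layout a few times before giving up
    placed <- NULL
    for (restart in 1:10) {
      placed <- tryCatch({
        po <- place_patches(cfg$n_oriented_patches, cfg$patch_size, h, w, list())
        pc <- place_patches(cfg$n_colored_patches, cfg$patch_size, h, w,
                            po$occupied)
        list(po = po, pc = pc)
      }, crossadapt_placement_error = function(e) NULL)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) {
      rlang::abort("could not place non-overlapping patches after bounded retries",
                   class = "crossadapt_placement_error")
    }
    po <- placed$po; pc <- placed$pc
    recs <- list()
    for (k in seq_along(po$placed)) {
      b <- po$placed[[k]]
      ang <- if (is.null(cfg$grating_orientations)) stats::runif(1, 0, 180) else
        sample(rep(cfg$grating_orientations, 2), 1)
      rows <- b[1]:b[3]; cols <- b[2]:b[4]
      # brightness varies along direction `ang`, so the Sobel orientation
      # of the patch equals `ang`
      phase <- stats::runif(1, 0, 2 * pi)
      gr <- outer(rows, cols, function(r, cc) {
        128 + cfg$contrast * 127 *
          sin(2 * pi / cfg$grating_spatial_period *
                (cc * cos(deg2rad(ang)) + r * sin(deg2rad(ang))) + phase)
      })
      for (ch in 1:3) img[rows, cols, ch] <- gr
      recs[[length(recs) + 1]] <- tibble::tibble(
        type = "oriented", row0 = b[1], col0 = b[2], size = cfg$patch_size,
        orientation_deg = ang, r = NA_real_, g = NA_real_, b = NA_real_)
    }
    for (k in seq_along(pc$placed)) {
      b <- pc$placed[[k]]
      hue <- cfg$patch_hues[sample.int(nrow(cfg$patch_hues), 1), ]
      rows <- b[1]:b[3]; cols <- b[2]:b[4]
      for (ch in 1:3) img[rows, cols, ch] <- hue[ch]
      recs[[length(recs) + 1]] <- tibble::tibble(
        type = "colored", row0 = b[1], col0 = b[2], size = cfg$patch_size,
        orientation_deg = NA_real_, r = hue[1], g = hue[2], b = hue[3])
    }
    patches <- if (length(recs)) {
      dplyr::mutate(purrr::list_rbind(recs), patch_id = dplyr::row_number(),
                    .before = 1)
    } else {
      tibble::tibble(patch_id = integer(), type = character(), row0 = integer(),
                     col0 = integer(), size = integer(),
                     orientation_deg = numeric(), r = numeric(), g = numeric(),
                     b = numeric())
    }
    structure(list(image = img, patches = patches, config = cfg),
              class = "ca_scene")
  })
}

#' @export
print.ca_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene %d x %d px: %d oriented, %d colored patches (%s background)\n",
              dim(x$image)[1], dim(x$image)[2],
              sum(x$patches$type == "oriented"), sum(x$patches$type == "colored"),
              x$config$background))
  invisible(x)
}
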