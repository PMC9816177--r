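#' Write and read wide trial tables as CSV with a JSON metadata sidecar
#'
#' The CSV carries `trial_id`, `condition`, `stimulus_angle_deg` and the
#' `neuron_<k>` count columns; the sidecar (`<path>.json`) records the
#' analysis window, feature, period and seed so a round trip restores
#' the table attributes.
#'
#' @param data Wide trial table.
#' @param path CSV path.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path, seed = NULL) {
  utils::write.csv(data, path, row.names = FALSE)
  meta <- list(window_ms = attr(data, "window_ms"),
               feature = attr(data, "feature"),
               period = attr(data, "period"),
               seed = seed)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tbl, "window_ms") <- meta$window_ms
    attr(tbl, "feature") <- meta$feature
    attr(tbl, "period") <- meta$period
  }
  tbl
}

#' Write and read eye traces as CSV
#'
#' @param trace Tibble with `t_ms`, `x_deg`, `y_deg`, `pupil` (or a
#'   `ca_eye_session`, whose ground truth is written alongside as JSON).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_eye_trace <- function(trace, path) {
  if (inherits(trace, "ca_eye_session")) {
    jsonlite::write_json(trace$fixations, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    trace <- trace$trace
  }
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a synthetic scene as PNG plus JSON ground truth
#'
#' @param scene A [generate_scene()] result.
#' @param path PNG path; ground truth goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$image / 255, path)
  jsonlite::write_json(scene$patches, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image file as an H x W x 3 array on the 0-255 scale
#'
#' @param path PNG path.
#' @return Numeric array, values in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img * 255
}

#' Write a feature map as CSV
#'
#' @param fmap A [feature_map()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(fmap, path) {
  utils::write.csv(
    fmap[c("win_row", "win_col", "center_row", "center_col", "osi",
           "mean_orientation_deg", "label")],
    path, row.names = FALSE)
  invisible(path)
}
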