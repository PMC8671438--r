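#' Multi-channel image field
#'
#' A named collection of co-registered 2D grayscale channels (matrices of
#' intensities in \[0, 1\]) sharing one pixel size. Typical channel names are
#' `"FL"` (fluorescence), `"BF"` (bright-field) and `"NUC"` (nucleus stain).
#'
#' @param channels named list of numeric matrices, all the same dimension.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @return An object of class `image_field`: a list with elements `channels`
#'   and `pixel_size`.
#' @export
image_field <- function(channels, pixel_size = 1) {
  assert_that(is.list(channels) && length(channels) >= 1 &&
                !is.null(names(channels)) && all(nzchar(names(channels))),
              "channels must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  assert_that(all(vapply(channels, is.matrix, logical(1))),
              "every channel must be a matrix")
  assert_that(length(unique(vapply(dims, paste, character(1), collapse = "x"))) == 1,
              "all channels must share the same dimensions")
  assert_that(is.numeric(pixel_size) && pixel_size > 0, "pixel_size must be > 0")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_field")
}

field_dim <- function(field) dim(field$channels[[1]])

#' @export
print.image_field <- function(x, ...) {
  d <- field_dim(x)
  cat(sprintf("<image_field> %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Marker set
#'
#' Per-cell anchor positions (one marker per cell, usually a nucleus
#' centroid), stored as a data frame with columns `id`, `row`, `col`
#' (1-based pixel coordinates) and a `pixel_size` attribute in um/pixel.
#'
#' @param points data frame with columns `row`, `col` and optionally `id`.
#' @param pixel_size micrometres per pixel.
#' @return A `marker_set` data frame.
#' @export
marker_set <- function(points = data.frame(row = numeric(0), col = numeric(0)),
                       pixel_size = 1) {
  assert_that(is.data.frame(points) && all(c("row", "col") %in% names(points)),
              "points must be a data frame with columns row, col")
  if (is.null(points$id)) points$id <- seq_len(nrow(points))
  points <- points[, c("id", "row", "col")]
  assert_that(!anyDuplicated(points$id), "marker ids must be unique")
  if (nrow(points) > 1) {
    assert_that(!anyDuplicated(points[, c("row", "col")]),
                "no two markers may share the identical pixel")
  }
  structure(points, class = c("marker_set", "data.frame"), pixel_size = pixel_size)
}

marker_pixel_size <- function(m) {
  ps <- attr(m, "pixel_size")
  if (is.null(ps)) 1 else ps
}

#' Number of markers in a set
#' @param m a [marker_set()].
#' @return integer count.
#' @export
n_markers <- function(m) nrow(m)
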