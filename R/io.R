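# File formats: grayscale TIFF for images and masks, 16-bit TIFF for label
# maps, CSV for markers and training histories, JSON for reports, YAML for
# pipeline configuration.

#' Read a multi-channel field from per-channel TIFFs
#'
#' @param paths named character vector of TIFF paths; names become channel
#'   names. Integer TIFFs are scaled to \[0, 1\] by their dtype range.
#' @param pixel_size micrometres per pixel.
#' @return an [image_field()].
#' @export
read_field <- function(paths, pixel_size = 1) {
  assert_that(length(paths) >= 1 && !is.null(names(paths)),
              "paths must be a named vector of TIFF files")
  chans <- lapply(paths, function(p) {
    assert_that(file.exists(p), paste0("file not found: ", p))
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3) m <- m[, , 1]   # drop extra planes
    m
  })
  dims <- vapply(chans, function(m) paste(dim(m), collapse = "x"), character(1))
  assert_that(length(unique(dims)) == 1, "channel TIFFs have mismatched sizes")
  image_field(chans, pixel_size = pixel_size)
}

#' Write a grayscale image to TIFF
#' @param image matrix in \[0, 1\].
#' @param path output file.
#' @param bits 8, 16 or 32 bits per sample.
#' @export
write_image <- function(image, path, bits = 16) {
  tiff::writeTIFF(clip01(image), path, bits.per.sample = bits)
  invisible(path)
}

#' Write / read a binary mask as 8-bit TIFF (0/255)
#' @param mask 0/1 matrix.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write / read an instance label map as 16-bit TIFF
#'
#' Label ids (< 65536) are stored in the 16-bit sample values; the round
#' trip is exact.
#'
#' @param labels integer matrix, 0 = background.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  assert_that(max(labels) < 65536, "label ids must fit in 16 bits")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read markers as CSV (`id,row,col`, 1-based pixels)
#' @param markers a [marker_set()].
#' @param path file path.
#' @param pixel_size micrometres per pixel attached on reading.
#' @export
write_markers_csv <- function(markers, path) {
  write.csv(as.data.frame(markers)[, c("id", "row", "col")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path, pixel_size = 1) {
  df <- read.csv(path)
  marker_set(df, pixel_size = pixel_size)
}

#' Write a scene to a directory
#'
#' Per-channel grayscale TIFFs (`FL.tif`, `BF.tif`, `NUC.tif`), the ground
#' truth as 16-bit `labels.tif`, and the true anchors as `centers.csv`.
#'
#' @param scene a `synthetic_scene`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_scene <- function(scene, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scene$channels$channels))
    write_image(scene$channels$channels[[nm]],
                file.path(outdir, paste0(nm, ".tif")))
  write_labels(scene$labels, file.path(outdir, "labels.tif"))
  write_markers_csv(scene$centers, file.path(outdir, "centers.csv"))
  invisible(outdir)
}

#' Write an evaluation report as JSON
#' @param eval a `seg_eval` from [mean_iou()].
#' @param path file path.
#' @export
write_eval_json <- function(eval, path) {
  jsonlite::write_json(list(mean_iou = eval$mean_iou,
                            per_cell_iou = eval$per_cell_iou),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a training history as CSV
#' @param history data frame of per-epoch loss terms.
#' @param path file path.
#' @export
write_history_csv <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
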