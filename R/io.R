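## Text/PNG input-output helpers. Pixel coordinates are 0-based, row-major
## with the origin at the top-left corner in exported tables; in-memory
## matrices follow R's 1-based column-major convention.

#' Read a grayscale base image from PNG
#'
#' Multi-channel images are converted to grayscale by averaging the color
#' channels.
#'
#' @param path PNG file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_base_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img
}

#' Write a grayscale image to PNG
#'
#' @param image Numeric matrix; values are clipped to `[0, 1]`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Export per-voxel wavefront timing as TSV
#'
#' Writes voxel id (0-based), coordinates, onset/offset/duration and an
#' optional region label per voxel; region labels replace atlas lookup and
#' are supplied as a user table.
#'
#' @param course A `max_course`.
#' @param coords Voxels x 3 coordinate matrix (mm).
#' @param path Output TSV path.
#' @param regions Optional character vector of per-voxel region labels.
#' @return The path, invisibly.
#' @export
export_course_tsv <- function(course, coords, path, regions = NULL) {
  stopifnot(inherits(course, "max_course"))
  df <- data.frame(voxel_id = seq_len(nrow(coords)) - 1L,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   onset_ms = course$onset_ms, offset_ms = course$offset_ms,
                   duration_ms = course$duration_ms,
                   region_label = if (is.null(regions)) NA_character_ else regions)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a representational-complexity map as TSV
#'
#' @param map A `complexity_map`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
export_complexity_tsv <- function(map, path) {
  stopifnot(inherits(map, "complexity_map"))
  nw <- ncol(map$counts)
  df <- data.frame(voxel_id = rep(seq_len(nrow(map$counts)) - 1L, nw),
                   window_idx = rep(seq_len(nw), each = nrow(map$counts)),
                   count = as.vector(map$counts))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
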