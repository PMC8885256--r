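# Readers and writers: CSV feature tables (header required, "." decimal) and
# grayscale PNG/TIFF images flattened to per-pixel intensity features.

#' Read a delimited feature table
#'
#' Reads a comma-separated table with a header row. All feature columns must
#' be numeric; an optional label column is split out for evaluation only and
#' is never passed to the clusterer.
#'
#' @param path Path to a CSV file.
#' @param label_column Optional name of the class-label column.
#' @return A list with `features` (tibble of numeric columns) and `labels`
#'   (vector, or `NULL` when no label column was requested).
#' @export
read_features <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop_invalid_data("File not found: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) < 1L || ncol(tab) < 1L) stop_invalid_data("Empty table: ", path)
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(tab)) {
      stop_contract("Label column '", label_column, "' not found in ", path, ".")
    }
    labels <- tab[[label_column]]
    tab <- tab[setdiff(names(tab), label_column)]
  }
  for (nm in names(tab)) {
    if (!is.numeric(tab[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[nm]]))))[1L]
      stop_invalid_data("Non-numeric feature cell at row ",
                        ifelse(is.na(bad), 1L, bad), ", column '", nm, "'.")
    }
  }
  if (ncol(tab) < 1L) stop_invalid_data("No feature columns left in ", path, ".")
  list(features = tab, labels = labels)
}

#' Write a feature table
#'
#' @param data Data frame to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Read a grayscale image as per-pixel intensity features
#'
#' Reads PNG or TIFF; color images are converted by Rec. 709 luminance.
#' Intensities are on `[0, 1]`, pixels in row-major order; the image shape is
#' kept so a label image can be reconstructed after clustering.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A tibble with columns `row`, `col`, `intensity`, carrying the
#'   image dimensions in attribute `shape`.
#' @export
read_grayscale <- function(path) {
  if (!file.exists(path)) stop_invalid_data("File not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid_data("Unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    img <- if (ch >= 3L) {
      0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    } else {
      img[, , 1L]
    }
  }
  if (length(img) == 0L) stop_invalid_data("Zero-size image: ", path)
  img <- pmin(pmax(img, 0), 1)
  out <- tibble::tibble(
    row = rep(seq_len(nrow(img)), each = ncol(img)),
    col = rep(seq_len(ncol(img)), times = nrow(img)),
    intensity = as.numeric(t(img))
  )
  attr(out, "shape") <- dim(img)
  out
}

#' Write a label image
#'
#' Maps integer cluster labels to equally spaced gray levels and writes a
#' grayscale PNG.
#'
#' @param labels Integer vector of cluster labels in row-major pixel order.
#' @param shape `c(height, width)`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, shape, path) {
  q <- max(labels)
  gray <- if (q == 1L) rep(1, length(labels)) else (labels - 1) / (q - 1)
  img <- matrix(0, shape[1L], shape[2L])
  img[cbind(rep(seq_len(shape[1L]), each = shape[2L]),
            rep(seq_len(shape[2L]), times = shape[1L]))] <- gray
  png::writePNG(img, path)
  invisible(path)
}
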