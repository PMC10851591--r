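#' Read an RGB photomicrograph from TIFF or PNG
#'
#' Returns intensities on the 0..255 scale regardless of on-disk depth.
#' Grayscale files are rejected; an alpha channel, if present, is dropped.
#'
#' @param path file path ending in .tif/.tiff or .png.
#' @return numeric \code{H x W x 3} array in [0, 255].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 2L)
    stop("expected an RGB image, got a single-channel file: ", path,
         call. = FALSE)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round_half_up(img * 255)
}

#' Write an RGB image (values 0..255) as TIFF or PNG
#' @param image numeric \code{H x W x 3} array in [0, 255].
#' @param path destination path; format chosen from the extension.
#' @export
write_rgb_image <- function(image, path) {
  check_rgb(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    png = png::writePNG(scaled, path),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write a DAB map for visual inspection
#'
#' The inverted DAB intensity goes to an 8-bit grayscale TIFF and the tissue
#' mask to a black/white PNG.
#'
#' @param x a \code{dab_map}.
#' @param intensity_path,mask_path destination files (TIFF and PNG).
#' @export
write_dab_map <- function(x, intensity_path, mask_path = NULL) {
  stopifnot(inherits(x, "dab_map"))
  tiff::writeTIFF(x$intensity / 255, intensity_path, bits.per.sample = 8L)
  if (!is.null(mask_path)) png::writePNG(x$tissue * 1.0, mask_path)
  invisible(intensity_path)
}

#' Read a DAB intensity map from an 8-bit grayscale TIFF
#'
#' @param intensity_path grayscale TIFF written by \code{\link{write_dab_map}}
#'   (or any 8-bit grayscale image on the 0..255 scale).
#' @param mask_path optional black/white PNG tissue mask; when absent every
#'   pixel is treated as tissue.
#' @return a \code{dab_map}.
#' @export
read_dab_map <- function(intensity_path, mask_path = NULL) {
  m <- tiff::readTIFF(intensity_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  intensity <- round_half_up(m * 255)
  tissue <- if (is.null(mask_path)) {
    matrix(TRUE, nrow(intensity), ncol(intensity))
  } else {
    p <- png::readPNG(mask_path)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p > 0.5
  }
  new_dab_map(intensity, tissue)
}
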