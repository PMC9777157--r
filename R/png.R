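#' Read and write 8-bit grayscale PNG images
#'
#' Minimal PNG I/O for single-channel 8-bit images (the format the phantom
#' generator emits and the pipeline consumes). `write_png` clamps values to
#' 0-255 and rounds; `read_png` returns an integer matrix in 0-255.
#'
#' @param img integer or numeric matrix of pixel values (rows = image rows).
#' @param path file path.
#' @return `read_png`: an integer matrix; `write_png`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_png(matrix(0:255, 16, 16), f)
#' img <- read_png(f)
#' @export
write_png <- function(img, path) {
  if (!is.matrix(img)) stop_kneedhl("'img' must be a matrix", "kneedhl_invalid_input")
  storage.mode(img) <- "double"
  write_png_gray8_cpp(matrix(as.integer(round(clip255(img))), nrow(img), ncol(img)), path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  if (!file.exists(path)) {
    stop_kneedhl(sprintf("PNG file not found: '%s'", path), "kneedhl_io_error")
  }
  read_png_gray8_cpp(path.expand(path))
}
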