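#' Grayscale intensity image
#'
#' The unit of all image arithmetic in this package: a 2-D grid of
#' intensities stored as doubles in \eqn{[0, 1]}, together with the bit
#' depth `n` of its integer file representation (`2^n - 1` levels).
#' Height is the number of rows, width the number of columns.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`.
#' @param bit_depth bits per pixel of the integer representation
#'   (default 8).
#' @return An object of class `echo_image`: the pixel matrix with a
#'   `bit_depth` attribute.
#' @examples
#' img <- echo_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
echo_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1] and contain no NA",
         call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || is.na(bit_depth) || bit_depth < 1L) {
    stop("`bit_depth` must be a single positive integer", call. = FALSE)
  }
  structure(unclass(pixels), bit_depth = bit_depth, class = "echo_image")
}

#' @export
print.echo_image <- function(x, ...) {
  cat(sprintf("<echo_image> %d x %d pixels, %d-bit\n",
              nrow(x), ncol(x), bit_depth(x)))
  cat(sprintf("  intensity range [%.4f, %.4f], mean %.4f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
as.matrix.echo_image <- function(x, ...) {
  y <- unclass(x)
  attr(y, "bit_depth") <- NULL
  y
}

#' Bit depth of an image
#'
#' @param x an [echo_image] (or a plain matrix, for which the default of
#'   8 bits is returned).
#' @return Integer number of bits per pixel.
#' @export
bit_depth <- function(x) {
  bd <- attr(x, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

# Coerce matrix or echo_image input to a plain matrix, validating range.
as_pixel_matrix <- function(x, arg = "image") {
  if (inherits(x, "echo_image")) return(as.matrix(x))
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be an echo_image or numeric matrix", arg),
         call. = FALSE)
  }
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
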